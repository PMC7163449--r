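#' Classify a mutation record by its ref/alt alleles
#'
#' \code{"SNV"} when both alleles are single bases; \code{"insertion"} when
#' the alternate strictly extends the reference (the reference is a prefix
#' or suffix of the alternate, including an empty reference);
#' \code{"deletion"} for the symmetric net loss; \code{"indel"} for complex
#' substitutions that are neither. COSMIC-style \code{"-"} placeholders are
#' treated as empty alleles.
#'
#' @param ref,alt Character vectors of equal length (allele strings).
#' @return Character vector of classes.
#' @examples
#' classifyMutationRecord("G", "A")            # SNV
#' classifyMutationRecord("CAT", "C")          # deletion
#' classifyMutationRecord("TGTG", "TGTGGTG")   # insertion
#' @export
classifyMutationRecord <- function(ref, alt) {
  ref <- toupper(ifelse(is.na(ref) | ref == "-", "", ref))
  alt <- toupper(ifelse(is.na(alt) | alt == "-", "", alt))
  if (length(ref) != length(alt))
    stop("ref and alt must have equal length")
  if (any(!nzchar(ref) & !nzchar(alt)))
    stop("ref and alt cannot both be empty")
  mapply(function(r, a) {
    nr <- nchar(r); na_ <- nchar(a)
    if (nr == 1L && na_ == 1L && r != a) return("SNV")
    if (na_ > nr && (startsWith(a, r) || endsWith(a, r))) return("insertion")
    if (nr > na_ && (startsWith(r, a) || endsWith(r, a))) return("deletion")
    "indel"
  }, ref, alt, USE.NAMES = FALSE)
}

.emptyCatalog <- function() {
  data.frame(gene = character(0), chrom = character(0), pos = integer(0),
             ref = character(0), alt = character(0),
             mutation_class = character(0), stringsAsFactors = FALSE)
}

#' Load a mutation catalog
#'
#' Reads a COSMIC-like TSV (columns \code{gene}, \code{chrom}, \code{pos},
#' \code{ref}, \code{alt}; 1-based positions) or a VCF (multiallelic rows
#' are split per alternate allele; a \code{GENE=} INFO tag supplies the gene
#' label when present). Malformed rows are skipped with a message giving
#' their line numbers; more than 10\% malformed rows is an error. Duplicate
#' \code{(gene, chrom, pos, ref, alt)} records are removed (with a message)
#' unless \code{dedup = FALSE} — COSMIC lists recurrences, and the default
#' denominator is unique mutations.
#'
#' @param path File path.
#' @param format \code{"cosmic_tsv"} or \code{"vcf"}.
#' @param exons Optional [GenomicRanges::GRanges] mask (e.g. from
#'   [readGeneModels()]); only records whose position overlaps it are kept.
#' @param dedup Drop duplicate records (default \code{TRUE}).
#' @return data.frame with columns \code{gene}, \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{mutation_class}.
#' @export
loadCatalog <- function(path, format = c("cosmic_tsv", "vcf"), exons = NULL,
                        dedup = TRUE) {
  format <- match.arg(format)
  if (format == "cosmic_tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
    need <- c("gene", "chrom", "pos", "ref", "alt")
    if (!all(need %in% names(tab)))
      stop("catalog TSV must have columns: ", paste(need, collapse = ", "))
    pos <- suppressWarnings(as.integer(tab$pos))
    bad <- is.na(pos) | !nzchar(tab$chrom) |
      (!nzchar(tab$ref) & !nzchar(tab$alt))
    if (any(bad)) {
      if (mean(bad) > 0.10)
        stop(sum(bad), " of ", length(bad), " catalog rows are malformed")
      message("skipping ", sum(bad), " malformed row(s): lines ",
              paste(which(bad) + 1L, collapse = ","))
    }
    cat_ <- data.frame(gene = tab$gene[!bad], chrom = tab$chrom[!bad],
                       pos = pos[!bad], ref = toupper(tab$ref[!bad]),
                       alt = toupper(tab$alt[!bad]),
                       stringsAsFactors = FALSE)
  } else {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    info <- vcfR::extract.info(v, "GENE")
    gene <- if (is.null(info)) rep(NA_character_, nrow(fix)) else info
    alts <- strsplit(fix$ALT, ",", fixed = TRUE)
    idx <- rep(seq_len(nrow(fix)), lengths(alts))
    cat_ <- data.frame(
      gene = ifelse(is.na(gene[idx]), "", gene[idx]),
      chrom = fix$CHROM[idx],
      pos = as.integer(fix$POS[idx]),
      ref = toupper(fix$REF[idx]),
      alt = toupper(unlist(alts)),
      stringsAsFactors = FALSE)
  }
  if (dedup) {
    key <- with(cat_, paste(gene, chrom, pos, ref, alt, sep = "\r"))
    if (anyDuplicated(key)) {
      message("removed ", sum(duplicated(key)), " duplicate record(s)")
      cat_ <- cat_[!duplicated(key), , drop = FALSE]
    }
  }
  if (!is.null(exons)) {
    gr <- GenomicRanges::GRanges(cat_$chrom,
      IRanges::IRanges(cat_$pos, cat_$pos))
    keep <- IRanges::overlapsAny(gr, exons)
    cat_ <- cat_[keep, , drop = FALSE]
  }
  if (!nrow(cat_)) return(.emptyCatalog())
  cat_$mutation_class <- classifyMutationRecord(cat_$ref, cat_$alt)
  rownames(cat_) <- NULL
  cat_
}

#' Write a catalog TSV
#'
#' Companion writer for [loadCatalog()]'s \code{cosmic_tsv} format
#' (write-then-read round-trips identically).
#'
#' @param catalog data.frame with \code{gene}, \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}.
#' @param path Output path.
#' @export
writeCatalog <- function(catalog, path) {
  utils::write.table(catalog[, c("gene", "chrom", "pos", "ref", "alt")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract the SNV context window from a genome
#'
#' Reads the reference window around a 1-based position from a genome
#' ([Biostrings::DNAStringSet] or FASTA path), checks that the genome base
#' matches the catalog's reference allele, and substitutes the alternate
#' base. Windows running off a sequence end are padded with \code{N} and
#' flagged truncated.
#'
#' @param genome \code{DNAStringSet} or path to a FASTA file.
#' @param chrom Sequence name.
#' @param pos 1-based position.
#' @param ref,alt Single-base alleles.
#' @param radius Window radius in bases; defaults to
#'   [contextRadius()] over the default nucleases.
#' @param gene Optional gene label carried into the context.
#' @param checkRef Error when the genome base differs from \code{ref}
#'   (default \code{TRUE}).
#' @return An [SnvContext-class].
#' @export
extractContext <- function(genome, chrom, pos, ref, alt,
                           radius = contextRadius(defaultNucleases()),
                           gene = "", checkRef = TRUE) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  stopifnot(is(genome, "DNAStringSet"))
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (!chrom %in% names(genome))
    stop("chromosome '", chrom, "' not found in genome")
  chromSeq <- genome[[chrom]]
  L <- length(chromSeq)
  pos <- as.integer(pos)
  if (pos < 1L || pos > L)
    stop("position ", chrom, ":", pos, " outside the sequence (length ",
         L, ")")
  gbase <- as.character(Biostrings::subseq(chromSeq, pos, pos))
  if (checkRef && gbase != toupper(ref))
    stop("reference mismatch at ", chrom, ":", pos, " (genome ", gbase,
         ", catalog ", ref, ")")
  lo <- pos - radius
  hi <- pos + radius
  padL <- max(0L, 1L - lo)
  padR <- max(0L, hi - L)
  win <- as.character(Biostrings::subseq(chromSeq, max(1L, lo), min(L, hi)))
  win <- paste0(strrep("N", padL), win, strrep("N", padR))
  SnvContext(win, offset = radius + 1L, altBase = alt, gene = gene,
             chrom = chrom, pos = pos, truncated = padL > 0L || padR > 0L)
}

# half-up rounding to `digits` decimals (R's round() is banker's)
roundHalfUp <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Summarize a mutation catalog: per-gene editability statistics
#'
#' Runs the editability scan for every SNV record against every nuclease
#' and aggregates the statistics a mutation-catalog survey reports:
#' the mutation-class breakdown over all records, per-gene
#' per-nuclease counts and percentages of editable SNVs with their
#' strand-category partition (S / AS / S+AS), the any-nuclease union
#' percentage, and the genes whose any-nuclease percentage exceeds 50.
#' Non-SNV records contribute to the class breakdown only.
#'
#' Percentages are reported to one decimal place, half-up.
#'
#' @param catalog data.frame from [loadCatalog()] (or with the same
#'   columns).
#' @param genome \code{DNAStringSet} or FASTA path.
#' @param nucleases Named list of [Nuclease-class] objects (default
#'   [defaultNucleases()]).
#' @param strict Passed to [editability()].
#' @param checkRef Passed to [extractContext()].
#' @return List with elements \code{perGene} (data.frame: \code{gene},
#'   \code{n_snv}, and per nuclease \code{n_editable_*}, \code{pct_*},
#'   \code{n_S_*}, \code{n_AS_*}, \code{n_SAS_*}, plus \code{n_any}/
#'   \code{pct_any}), \code{overall} (named vector of overall percentages
#'   per nuclease and \code{any}), \code{classPct} (mutation-class
#'   percentages over all records), \code{genesOver50} (character), and
#'   \code{n_snv_total}.
#' @export
summarizeCatalog <- function(catalog, genome, nucleases = defaultNucleases(),
                             strict = FALSE, checkRef = TRUE) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (is.null(names(nucleases)))
    names(nucleases) <- vapply(nucleases, nucleaseName, character(1))
  if (is.null(catalog$mutation_class))
    catalog$mutation_class <- classifyMutationRecord(catalog$ref,
                                                     catalog$alt)
  classPct <- roundHalfUp(100 * table(factor(catalog$mutation_class,
    levels = c("SNV", "deletion", "insertion", "indel"))) / nrow(catalog))
  classPct <- stats::setNames(as.numeric(classPct), names(classPct))

  snvs <- catalog[catalog$mutation_class == "SNV", , drop = FALSE]
  if (!nrow(snvs)) {
    warning("catalog contains no SNV records; editability summary is empty")
    return(list(perGene = data.frame(), overall = numeric(0),
                classPct = classPct, genesOver50 = character(0),
                n_snv_total = 0L))
  }
  radius <- contextRadius(nucleases)
  nn <- names(nucleases)
  ed <- matrix(FALSE, nrow(snvs), length(nn), dimnames = list(NULL, nn))
  sc <- matrix("none", nrow(snvs), length(nn), dimnames = list(NULL, nn))
  for (i in seq_len(nrow(snvs))) {
    ctx <- extractContext(genome, snvs$chrom[i], snvs$pos[i], snvs$ref[i],
                          snvs$alt[i], radius = radius,
                          gene = snvs$gene[i], checkRef = checkRef)
    for (nu in nn) {
      call <- editability(ctx, nucleases[[nu]], strict = strict)
      ed[i, nu] <- isEditable(call)
      sc[i, nu] <- strandCategory(call)
    }
  }
  anyEd <- rowSums(ed) > 0L

  geneLevels <- sort(unique(snvs$gene))
  perGene <- data.frame(gene = geneLevels, stringsAsFactors = FALSE)
  perGene$n_snv <- as.integer(table(factor(snvs$gene,
                                           levels = geneLevels)))
  for (nu in nn) {
    byg <- function(v) vapply(geneLevels, function(g)
      sum(v[snvs$gene == g]), numeric(1))
    nEd <- byg(ed[, nu])
    perGene[[paste0("n_editable_", nu)]] <- as.integer(nEd)
    perGene[[paste0("pct_", nu)]] <- roundHalfUp(100 * nEd / perGene$n_snv)
    perGene[[paste0("n_S_", nu)]] <- as.integer(byg(sc[, nu] == "S"))
    perGene[[paste0("n_AS_", nu)]] <- as.integer(byg(sc[, nu] == "AS"))
    perGene[[paste0("n_SAS_", nu)]] <-
      as.integer(byg(sc[, nu] == "S_plus_AS"))
  }
  nAny <- vapply(geneLevels, function(g)
    sum(anyEd[snvs$gene == g]), numeric(1))
  perGene$n_any <- as.integer(nAny)
  perGene$pct_any <- roundHalfUp(100 * nAny / perGene$n_snv)
  rownames(perGene) <- NULL

  overall <- c(
    stats::setNames(vapply(nn, function(nu)
      roundHalfUp(100 * sum(ed[, nu]) / nrow(snvs)), numeric(1)), nn),
    any = roundHalfUp(100 * sum(anyEd) / nrow(snvs)))
  list(perGene = perGene, overall = overall, classPct = classPct,
       genesOver50 = perGene$gene[perGene$pct_any > 50],
       n_snv_total = nrow(snvs))
}
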