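# Seeded generators for every input the pipeline consumes. One user-facing
# seed fans out to fixed per-generator offsets so that adding a generator
# never perturbs the streams of the existing ones. All generators save and
# restore the caller's RNG state.

SEED_OFFSETS <- c(genome = 11L, catalog = 23L, reads = 37L, variants = 53L)

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a random genome
#'
#' Bases are drawn i.i.d. with the requested GC content; for sequences of
#' 10 kb and more the realised GC fraction is within ~2% of the target
#' (binomial concentration). Deterministic for a fixed seed.
#'
#' @param length Sequence length in bases.
#' @param gc Target GC content in (0, 1); 0 and 1 give AT-only / GC-only.
#' @param seed Integer seed.
#' @param name Sequence name.
#' @return [Biostrings::DNAStringSet] of one sequence.
#' @export
genGenome <- function(length, gc = 0.5, seed = 1L, name = "chr1") {
  stopifnot(length >= 1L, gc >= 0, gc <= 1)
  .withSeed(seed + SEED_OFFSETS[["genome"]], {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    s <- paste(sample(names(p), length, replace = TRUE, prob = p),
               collapse = "")
    out <- Biostrings::DNAStringSet(s)
    names(out) <- name
    out
  })
}

# ---------------------------------------------------------------------------
# Independent first-principles editability labeler. This duplicates none of
# the production scanner's code on purpose: it has its own degeneracy map
# and walks every candidate window with plain loops, so that agreement
# between the two is a genuine two-route check.
# ---------------------------------------------------------------------------
.BRUTE_IUPAC <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
                  S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT",
                  D = "AGT", H = "ACT", V = "ACG", N = "ACGTN")

.bruteRevComp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

.brutePamOk <- function(window, pam) {
  if (nchar(window) != nchar(pam)) return(FALSE)
  for (k in seq_len(nchar(pam))) {
    b <- substr(window, k, k)
    allowed <- strsplit(.BRUTE_IUPAC[[substr(pam, k, k)]], "")[[1]]
    if (!(b %in% allowed)) return(FALSE)
  }
  TRUE
}

# is the SNV at 1-based position `pos` of mutant string `mut` editable?
# checks, on each strand, every PAM placement whose protospacer-or-PAM span
# could cover the SNV, and asks whether the SNV falls in the seed or PAM.
.bruteEditableStrand <- function(mut, pos, pam, side, spacerLen, seedLen) {
  plen <- nchar(pam)
  L <- nchar(mut)
  for (pamStart in seq_len(L - plen + 1L)) {
    if (!.brutePamOk(substr(mut, pamStart, pamStart + plen - 1L), pam))
      next
    pamEnd <- pamStart + plen - 1L
    if (side == "3prime") {
      protoStart <- pamStart - spacerLen; protoEnd <- pamStart - 1L
      seedLo <- pamStart - seedLen; seedHi <- pamStart - 1L
    } else {
      protoStart <- pamEnd + 1L; protoEnd <- pamEnd + spacerLen
      seedLo <- pamEnd + 1L; seedHi <- pamEnd + seedLen
    }
    if (protoStart < 1L || protoEnd > L) next   # truncated protospacer
    if ((pos >= seedLo && pos <= seedHi) ||
        (pos >= pamStart && pos <= pamEnd))
      return(TRUE)
  }
  FALSE
}

#' Label an SNV editable/not by exhaustive first-principles search
#'
#' Standalone brute-force labeler used to attach ground truth to synthetic
#' catalogs. It shares no matching code with [findPamSites()] /
#' [editability()]; agreement between the two code paths is part of the
#' package's validation suite.
#'
#' @param flankRef Reference window (string).
#' @param offset 1-based SNV position within the window.
#' @param altBase Alternate base.
#' @param nuclease A [Nuclease-class] (only its geometry fields are read).
#' @return Logical.
#' @export
bruteLabelEditable <- function(flankRef, offset, altBase, nuclease) {
  mut <- toupper(flankRef)
  substr(mut, offset, offset) <- toupper(altBase)
  pam <- pamConsensus(nuclease)
  side <- pamSide(nuclease)
  sp <- spacerLength(nuclease)
  sd <- seedLength(nuclease)
  if (.bruteEditableStrand(mut, offset, pam, side, sp, sd)) return(TRUE)
  L <- nchar(mut)
  .bruteEditableStrand(.bruteRevComp(mut), L - offset + 1L, pam, side,
                       sp, sd)
}

#' Plant an SNV catalog with known editability truth
#'
#' Samples SNVs on a genome, labels each editable/not with the independent
#' brute-force labeler, and rejection-samples until the catalog holds
#' exactly \code{round(n * fraction)} editable and the rest non-editable
#' variants. Positions are unique; genes are assigned round-robin from
#' \code{genes} so per-gene statistics are exercised.
#'
#' @param genome [Biostrings::DNAStringSet] (single sequence used).
#' @param n Number of SNVs.
#' @param fraction Target editable fraction in [0, 1].
#' @param nuclease A [Nuclease-class].
#' @param seed Integer seed.
#' @param genes Gene label pool.
#' @param maxTries Sampling budget before giving up.
#' @return List: \code{catalog} (data.frame \code{gene}, \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}) and \code{truth} (logical vector,
#'   editable by construction).
#' @export
plantSnvCatalog <- function(genome, n = 300L, fraction = 0.5,
                            nuclease = spCas9(), seed = 1L,
                            genes = paste0("GENE", 1:5),
                            maxTries = 500L * n) {
  stopifnot(is(genome, "DNAStringSet"), fraction >= 0, fraction <= 1)
  chrom <- names(genome)[1]
  seqStr <- as.character(genome[[1]])
  L <- nchar(seqStr)
  radius <- contextRadius(nuclease)
  nEd <- as.integer(round(n * fraction))
  nNot <- n - nEd
  .withSeed(seed + SEED_OFFSETS[["catalog"]], {
    used <- integer(0)
    rows <- vector("list", n)
    truth <- logical(n)
    got <- 0L; gotEd <- 0L; gotNot <- 0L; tries <- 0L
    while (got < n) {
      tries <- tries + 1L
      if (tries > maxTries)
        stop("could not reach editable fraction ", fraction, " after ",
             maxTries, " tries")
      pos <- sample.int(L - 2L * radius, 1L) + radius
      if (pos %in% used) next
      ref <- substr(seqStr, pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      win <- substr(seqStr, pos - radius, pos + radius)
      lab <- bruteLabelEditable(win, radius + 1L, alt, nuclease)
      if (lab && gotEd >= nEd) next
      if (!lab && gotNot >= nNot) next
      got <- got + 1L
      if (lab) gotEd <- gotEd + 1L else gotNot <- gotNot + 1L
      used <- c(used, pos)
      rows[[got]] <- data.frame(
        gene = genes[(got - 1L) %% length(genes) + 1L],
        chrom = chrom, pos = pos, ref = ref, alt = alt,
        stringsAsFactors = FALSE)
      truth[got] <- lab
    }
    ord <- sample.int(n)
    catalog <- do.call(rbind, rows)[ord, , drop = FALSE]
    rownames(catalog) <- NULL
    list(catalog = catalog, truth = truth[ord])
  })
}

.parseSpectrumLabel <- function(label) {
  kind <- substr(label, 1L, 1L)
  len <- suppressWarnings(as.integer(substring(label, 2L)))
  if (!kind %in% c("I", "D", "S") || is.na(len) || len < 1L)
    stop("malformed spectrum label '", label,
         "' (expected e.g. I1, D2, S3)")
  list(kind = kind, len = len)
}

#' Simulate amplicon reads from an outcome spectrum
#'
#' Draws each read's outcome from a labelled spectrum (e.g.
#' \code{c(I1 = 0.6, D2 = 0.2)}; the probability remainder is unmodified),
#' applies the event at the cut site of the amplicon reference, then adds
#' i.i.d. substitution errors at \code{baseError} per base. Insertions add
#' random bases immediately 3' of the cut; deletions remove a run spanning
#' the cut; substitutions mutate a run starting 3' of the cut. The
#' per-read truth table records the intended outcome.
#'
#' @param amp An [AmpliconRef-class].
#' @param spectrum Named numeric of outcome probabilities (sum <= 1).
#' @param n Number of reads.
#' @param baseError Per-base substitution error rate.
#' @param seed Integer seed.
#' @return List: \code{reads} (named character vector), \code{qualities}
#'   (Phred+33 strings, constant Q40), \code{truth} (data.frame
#'   \code{read}, \code{label}, \code{modified}).
#' @export
simAmpliconReads <- function(amp, spectrum = c(I1 = 0.6, D2 = 0.2),
                             n = 2000L, baseError = 0.001, seed = 1L) {
  stopifnot(is(amp, "AmpliconRef"), sum(spectrum) <= 1 + 1e-12,
            all(spectrum >= 0))
  for (lab in names(spectrum)) .parseSpectrumLabel(lab)
  refSeq <- amp@sequence
  cut <- amp@cutAfter
  bases <- c("A", "C", "G", "T")
  .withSeed(seed + SEED_OFFSETS[["reads"]], {
    labels <- sample(c(names(spectrum), "unmodified"), n, replace = TRUE,
                     prob = c(spectrum, 1 - sum(spectrum)))
    reads <- character(n)
    for (i in seq_len(n)) {
      s <- refSeq
      if (labels[i] != "unmodified") {
        ev <- .parseSpectrumLabel(labels[i])
        if (ev$kind == "I") {
          ins <- paste(sample(bases, ev$len, replace = TRUE),
                       collapse = "")
          s <- paste0(substr(s, 1L, cut), ins,
                      substring(s, cut + 1L))
        } else if (ev$kind == "D") {
          from <- cut - ev$len %/% 2L + 1L
          s <- paste0(substr(s, 1L, from - 1L),
                      substring(s, from + ev$len))
        } else {
          for (k in seq_len(ev$len)) {
            p <- cut + k
            old <- substr(s, p, p)
            substr(s, p, p) <- sample(setdiff(bases, old), 1L)
          }
        }
      }
      if (baseError > 0) {
        nerr <- stats::rbinom(1L, nchar(s), baseError)
        if (nerr > 0L) {
          at <- sample.int(nchar(s), nerr)
          for (p in at) {
            old <- substr(s, p, p)
            substr(s, p, p) <- sample(setdiff(bases, old), 1L)
          }
        }
      }
      reads[i] <- s
    }
    ids <- sprintf("read%04d", seq_len(n))
    names(reads) <- ids
    list(reads = reads,
         qualities = stats::setNames(strrep("I", nchar(reads)), ids),
         truth = data.frame(read = ids, label = labels,
                            modified = labels != "unmodified",
                            stringsAsFactors = FALSE))
  })
}

#' Write reads to a FASTQ file
#'
#' @param reads Named character vector of read sequences.
#' @param path Output path.
#' @param qualities Optional named Phred+33 strings (default constant Q40).
#' @export
writeFastq <- function(reads, path, qualities = NULL) {
  if (is.null(qualities)) qualities <- strrep("I", nchar(reads))
  ids <- names(reads) %||% paste0("read", seq_along(reads))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", reads, "\n+\n", qualities), con)
  invisible(path)
}

#' Simulate paired treated/control variant tables
#'
#' Generates a shared background of variants present in both samples plus
#' treated-unique indels, placed either well away from every supplied
#' off-target site or inside one, so that background subtraction and
#' site intersection can be validated against construction truth.
#'
#' @param nShared Background variants present in both tables.
#' @param nUnique Treated-only indels.
#' @param sites Optional [GenomicRanges::GRanges] of predicted sites.
#' @param chromLength Virtual chromosome length (default 50000).
#' @param chrom Chromosome name (default taken from \code{sites} or
#'   \code{"chr1"}).
#' @param uniquePlacement \code{"away"} (>= 500 bp from every site) or
#'   \code{"inside"} (within a site interval).
#' @param seed Integer seed.
#' @return List: \code{treated}, \code{control} (data.frames \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}, \code{abundance}),
#'   \code{truthKeys} (character keys \code{chrom:pos:ref:alt} of the
#'   treated-unique rows).
#' @export
simVariantTables <- function(nShared = 5L, nUnique = 3L, sites = NULL,
                             chromLength = 50000L, chrom = NULL,
                             uniquePlacement = c("away", "inside"),
                             seed = 1L) {
  uniquePlacement <- match.arg(uniquePlacement)
  stopifnot(nShared >= 0L, nUnique >= 0L)
  if (is.null(chrom))
    chrom <- if (!is.null(sites) && length(sites))
      as.character(GenomicRanges::seqnames(sites))[1] else "chr1"
  bases <- c("A", "C", "G", "T")
  .withSeed(seed + SEED_OFFSETS[["variants"]], {
    randIndel <- function(pos) {
      anchor <- sample(bases, 1L)
      len <- sample.int(5L, 1L)
      extra <- paste(sample(bases, len, replace = TRUE), collapse = "")
      if (stats::runif(1) < 0.5)
        c(ref = anchor, alt = paste0(anchor, extra))       # insertion
      else
        c(ref = paste0(anchor, extra), alt = anchor)       # deletion
    }
    mkRow <- function(pos, indel) {
      if (indel) al <- randIndel(pos)
      else {
        r <- sample(bases, 1L)
        al <- c(ref = r, alt = sample(setdiff(bases, r), 1L))
      }
      data.frame(chrom = chrom, pos = pos, ref = al[["ref"]],
                 alt = al[["alt"]],
                 abundance = sample.int(10L, 1L),
                 stringsAsFactors = FALSE)
    }
    awayFromSites <- function(pos) {
      if (is.null(sites) || !length(sites)) return(TRUE)
      all(abs(pos - GenomicRanges::start(sites)) > 500L &
          abs(pos - GenomicRanges::end(sites)) > 500L)
    }
    sharedPos <- integer(0)
    while (length(sharedPos) < nShared) {
      p <- sample.int(chromLength, 1L)
      if (awayFromSites(p) && !(p %in% sharedPos))
        sharedPos <- c(sharedPos, p)
    }
    shared <- do.call(rbind, lapply(sharedPos, function(p)
      mkRow(p, indel = stats::runif(1) < 0.5)))
    uniqPos <- integer(0)
    while (length(uniqPos) < nUnique) {
      p <- if (uniquePlacement == "inside" && !is.null(sites) &&
               length(sites)) {
        s <- sites[sample.int(length(sites), 1L)]
        sample(seq(GenomicRanges::start(s), GenomicRanges::end(s)), 1L)
      } else sample.int(chromLength, 1L)
      ok <- if (uniquePlacement == "away") awayFromSites(p) else TRUE
      if (ok && !(p %in% c(sharedPos, uniqPos)))
        uniqPos <- c(uniqPos, p)
    }
    uniq <- if (nUnique > 0L)
      do.call(rbind, lapply(uniqPos, function(p) mkRow(p, indel = TRUE)))
    else NULL
    treated <- rbind(shared, uniq)
    if (!is.null(treated)) {
      treated <- treated[order(treated$pos), , drop = FALSE]
      rownames(treated) <- NULL
    } else treated <- mkRow(1L, FALSE)[0, ]
    control <- if (!is.null(shared)) shared else mkRow(1L, FALSE)[0, ]
    truthKeys <- if (nUnique > 0L)
      paste(chrom, uniq$pos, uniq$ref, uniq$alt, sep = ":") else character(0)
    list(treated = treated, control = control, truthKeys = truthKeys)
  })
}

#' Write a variant table as a minimal VCF
#'
#' Emits a VCFv4.2 file with the abundance in an \code{AB} INFO tag;
#' [readVariantTable()] reads it back.
#'
#' @param variants data.frame with \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt} and optionally \code{abundance}.
#' @param path Output path.
#' @export
writeVariantTable <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AB,Number=1,Type=Integer,Description=\"Supporting reads\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants)) {
    ab <- variants$abundance %||% rep(1L, nrow(variants))
    writeLines(paste(variants$chrom, variants$pos, ".", variants$ref,
                     variants$alt, ".", "PASS", paste0("AB=", ab),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a variant table from a VCF
#'
#' @param path VCF file.
#' @return data.frame with \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{abundance} (NA when no \code{AB} tag is present).
#' @export
readVariantTable <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (!nrow(fix))
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      abundance = integer(0)))
  ab <- suppressWarnings(as.integer(vcfR::extract.info(v, "AB")))
  data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
             ref = toupper(fix$REF), alt = toupper(fix$ALT),
             abundance = ab, stringsAsFactors = FALSE)
}
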