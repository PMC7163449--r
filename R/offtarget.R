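#' Enumerate candidate off-target sites by PAM-anchored mismatch search
#'
#' Exhaustively scans both strands of a genome for windows that carry a
#' consensus-matching PAM and differ from the query spacer by at most
#' \code{maxMismatch} bases. Windows containing \code{N} accumulate
#' mismatches at those positions and never satisfy the PAM. Sites are
#' returned once each, sorted by (mismatch count, chromosome, start).
#'
#' @param genome [Biostrings::DNAStringSet] or FASTA path.
#' @param spacer Query spacer sequence (length must equal the nuclease's
#'   spacer length), written 5'..3' in guide orientation.
#' @param nuclease A [Nuclease-class].
#' @param maxMismatch Maximum spacer mismatches (default 4, the usual
#'   genome-wide search depth for a 20-nt Cas9 spacer).
#' @param relaxPam For an NGG nuclease, widen the PAM to NRG (default
#'   \code{FALSE}).
#' @return [GenomicRanges::GRanges] of protospacer intervals (1-based) with
#'   metadata columns \code{site_seq} and \code{pam_seq} (guide
#'   orientation) and \code{mismatch_count}.
#' @export
enumerateOffTargets <- function(genome, spacer, nuclease, maxMismatch = 4L,
                                relaxPam = FALSE) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  stopifnot(is(genome, "DNAStringSet"), is(nuclease, "Nuclease"),
            maxMismatch >= 0L)
  names(genome) <- sub("\\s.*$", "", names(genome))
  spacer <- toupper(spacer)
  .checkDna(spacer, "spacer")
  sp <- spacerLength(nuclease)
  if (nchar(spacer) != sp)
    stop("spacer length ", nchar(spacer), " does not match the nuclease (",
         sp, ")")
  nuc <- nuclease
  if (relaxPam && pamConsensus(nuclease) == "NGG")
    nuc <- Nuclease(nucleaseName(nuclease), "NRG", pamSide(nuclease),
                    sp, seedLength(nuclease))
  spChars <- strsplit(spacer, "")[[1]]

  res <- list()
  for (chrom in names(genome)) {
    seq <- as.character(genome[[chrom]])
    sites <- findPamSites(seq, nuc, "both")
    sites <- sites[!sites$truncated, , drop = FALSE]
    if (!nrow(sites)) next
    chars <- strsplit(seq, "")[[1]]
    rcChars <- strsplit(revComp(seq), "")[[1]]
    L <- nchar(seq)
    mm <- integer(nrow(sites))
    fwd <- sites$strand == "+"
    # guide-orientation spacer positions: forward sites read proto_start..
    # proto_end left to right; reverse sites read the revcomp, i.e. forward
    # position proto_end maps to spacer position 1
    for (j in seq_len(sp)) {
      posF <- sites$proto_start + j - 1L
      posRcStart <- L - sites$proto_end + 1L
      posR <- posRcStart + j - 1L
      obs <- ifelse(fwd, chars[pmax(posF, 1L)], rcChars[pmax(posR, 1L)])
      mm <- mm + as.integer(obs != spChars[j])
    }
    keep <- mm <= maxMismatch
    if (!any(keep)) next
    s <- sites[keep, , drop = FALSE]
    siteSeq <- vapply(seq_len(nrow(s)), function(i) {
      x <- substring(seq, s$proto_start[i], s$proto_end[i])
      if (s$strand[i] == "-") revComp(x) else x
    }, character(1))
    res[[chrom]] <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(s$proto_start, s$proto_end),
      strand = s$strand,
      site_seq = siteSeq, pam_seq = s$pam, mismatch_count = mm[keep])
  }
  if (!length(res))
    return(GenomicRanges::GRanges(site_seq = character(0),
                                  pam_seq = character(0),
                                  mismatch_count = integer(0)))
  gr <- unlist(GenomicRanges::GRangesList(res), use.names = FALSE)
  ord <- order(S4Vectors::mcols(gr)$mismatch_count,
               as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr))
  gr[ord]
}

#' Subtract control background from treated variants
#'
#' Removes treated-sample variants whose \code{(chrom, pos, ref, alt)} key
#' also occurs in the control sample, leaving treatment-unique calls.
#' Input order is preserved; the operation is idempotent.
#'
#' @param treated,control data.frames with columns \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt} (extra columns pass through).
#' @return The treated rows absent from control.
#' @export
subtractBackground <- function(treated, control) {
  key <- function(d) paste(d$chrom, d$pos, toupper(d$ref), toupper(d$alt),
                           sep = "\r")
  out <- treated[!(key(treated) %in% key(control)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect variants with predicted off-target sites
#'
#' Matches variants to predicted sites whose interval, widened by
#' \code{slop} bases on each side, contains the variant. A variant spanning
#' several sites is reported once per site.
#'
#' @param variants data.frame with \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}.
#' @param sites [GenomicRanges::GRanges] from [enumerateOffTargets()] (or
#'   any site intervals).
#' @param slop Extra bases on each side of every site (default 25).
#' @return data.frame of matched pairs: the variant columns plus
#'   \code{site_index}, \code{site_chrom}, \code{site_start},
#'   \code{site_end}, \code{mismatch_count} (NA when the sites carry no
#'   mismatch annotation). 0 rows when nothing matches.
#' @export
intersectOffTargets <- function(variants, sites, slop = 25L) {
  stopifnot(slop >= 0L)
  if (!nrow(variants) || !length(sites)) {
    return(cbind(variants[0, , drop = FALSE],
                 data.frame(site_index = integer(0),
                            site_chrom = character(0),
                            site_start = integer(0), site_end = integer(0),
                            mismatch_count = integer(0))))
  }
  vgr <- GenomicRanges::GRanges(
    variants$chrom,
    IRanges::IRanges(variants$pos,
                     variants$pos + pmax(nchar(variants$ref) - 1L, 0L)))
  wide <- GenomicRanges::resize(sites,
    GenomicRanges::width(sites) + 2L * slop, fix = "center")
  hits <- suppressWarnings(GenomicRanges::findOverlaps(vgr, wide,
                                                       ignore.strand = TRUE))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  mm <- S4Vectors::mcols(sites)$mismatch_count
  out <- cbind(
    variants[qi, , drop = FALSE],
    data.frame(site_index = si,
               site_chrom = as.character(GenomicRanges::seqnames(sites))[si],
               site_start = GenomicRanges::start(sites)[si],
               site_end = GenomicRanges::end(sites)[si],
               mismatch_count = if (is.null(mm))
                 rep(NA_integer_, length(si)) else mm[si]))
  rownames(out) <- NULL
  out
}

#' Classify an indel by its ref/alt alleles
#'
#' Insertion when the reference is a prefix or suffix of the alternate,
#' deletion in the symmetric case, otherwise complex. The net length change
#' is \code{nchar(alt) - nchar(ref)} regardless of kind.
#'
#' @param ref,alt Character vectors of equal length; \code{ref != alt}
#'   element-wise.
#' @return data.frame with \code{kind} (\code{insertion}/\code{deletion}/
#'   \code{complex}) and \code{net_length} (signed integer).
#' @examples
#' classifyIndel("TGTG", "TGTGGTG")          # insertion, +3
#' classifyIndel("AACAACAACAA", "AACAACAA")  # deletion, -3
#' @export
classifyIndel <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(ref == alt)) stop("ref and alt must differ")
  kind <- mapply(function(r, a) {
    if (nchar(a) > nchar(r) && (startsWith(a, r) || endsWith(a, r)))
      "insertion"
    else if (nchar(r) > nchar(a) && (startsWith(r, a) || endsWith(r, a)))
      "deletion"
    else "complex"
  }, ref, alt, USE.NAMES = FALSE)
  data.frame(kind = kind, net_length = nchar(alt) - nchar(ref))
}

#' Read exon gene models from a BED file
#'
#' Expects BED records named by gene, one exon per record (BED is 0-based
#' half-open on disk; the returned [GenomicRanges::GRanges] follows the
#' 1-based closed convention).
#'
#' @param path BED file.
#' @return \code{GRanges} of exons with a \code{name} metadata column.
#' @export
readGeneModels <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(gr$name) || any(is.na(gr$name)))
    stop("gene-model BED records must carry a gene name")
  gr
}

#' Annotate indels with exon/intron status and frameshift ("reframed") call
#'
#' A variant position overlapping an exon of any model is exonic; inside a
#' gene body (the range of a gene's exons) but outside its exons, intronic;
#' otherwise intergenic. An exonic indel is reframed (frameshifting) when
#' its net length change is not a multiple of 3; exonic in-frame and
#' intronic indels are "no"; intergenic or unannotated positions are NA.
#' Complex substitutions are assessed from their net length like other
#' indels.
#'
#' @param variants data.frame with \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}.
#' @param models Exon \code{GRanges} from [readGeneModels()].
#' @return The input with added columns \code{kind}, \code{net_length},
#'   \code{model_gene}, \code{region} (\code{exon}/\code{intron}/
#'   \code{intergenic}), \code{reframed} (\code{"yes"}/\code{"no"}/NA).
#' @export
annotateReframe <- function(variants, models) {
  cls <- classifyIndel(variants$ref, variants$alt)
  vgr <- GenomicRanges::GRanges(variants$chrom,
    IRanges::IRanges(variants$pos, variants$pos))
  exHit <- suppressWarnings(GenomicRanges::findOverlaps(vgr, models,
                                                        ignore.strand = TRUE))
  bodies <- unlist(GenomicRanges::reduce(
    GenomicRanges::split(models, models$name), min.gapwidth = 1e9))
  bodyHit <- suppressWarnings(GenomicRanges::findOverlaps(vgr, bodies,
                                                          ignore.strand = TRUE))
  n <- nrow(variants)
  region <- rep("intergenic", n)
  gene <- rep(NA_character_, n)
  bq <- S4Vectors::queryHits(bodyHit)
  region[bq] <- "intron"
  gene[bq] <- names(bodies)[S4Vectors::subjectHits(bodyHit)][
    match(bq, S4Vectors::queryHits(bodyHit))]
  eq <- S4Vectors::queryHits(exHit)
  region[eq] <- "exon"
  gene[eq] <- models$name[S4Vectors::subjectHits(exHit)][
    match(eq, S4Vectors::queryHits(exHit))]
  reframed <- rep(NA_character_, n)
  frameshift <- cls$net_length %% 3L != 0L
  reframed[region == "exon"] <- ifelse(frameshift[region == "exon"],
                                       "yes", "no")
  reframed[region == "intron"] <- "no"
  out <- cbind(variants, cls,
               data.frame(model_gene = gene, region = region,
                          reframed = reframed, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
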