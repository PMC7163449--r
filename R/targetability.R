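#' Minimal flank radius for a set of nucleases
#'
#' The window that guarantees every protospacer+PAM span containing the SNV
#' fits without truncation extends \code{spacerLength + pamLength - 1} bases
#' on each side of the variant; over a set of nucleases the maximum is taken.
#'
#' @param nucleases A [Nuclease-class] or list of them.
#' @return Integer radius in bases.
#' @export
contextRadius <- function(nucleases) {
  if (is(nucleases, "Nuclease")) nucleases <- list(nucleases)
  max(vapply(nucleases, function(n)
    spacerLength(n) + nchar(pamConsensus(n)) - 1L, integer(1)))
}

#' Enumerate protospacers covering an SNV on the mutant allele
#'
#' Scans both strands of the mutant-allele window for PAM matches and
#' returns every guide candidate whose protospacer-or-PAM span covers the
#' variant. The scan runs on the mutant allele because the guide must
#' recognise the mutant; a PAM created by the variant qualifies, a PAM
#' destroyed by it does not.
#'
#' Each candidate is annotated with:
#' \describe{
#'   \item{snv_in}{\code{"seed"}, \code{"pam"} or \code{"distal"} (in the
#'     protospacer but PAM-distal of the seed).}
#'   \item{snv_to_pam_distance}{0 when the SNV sits inside the PAM;
#'     otherwise the 1-based distance from the PAM-proximal protospacer end
#'     (1 = the base adjacent to the PAM). Seed membership is equivalent to
#'     \code{1 <= distance <= seedLength}.}
#'   \item{wt_mismatch_count}{Number of positions at which the wild-type
#'     allele escapes recognition: protospacer positions where the
#'     reference window differs from the guide, plus PAM positions where
#'     the reference base violates the consensus. A variant at a fully
#'     degenerate PAM position (the N of NGG) therefore contributes 0.}
#' }
#'
#' @param ctx An [SnvContext-class].
#' @param nuclease A [Nuclease-class].
#' @return data.frame of candidates (possibly 0 rows): \code{nuclease},
#'   \code{strand}, \code{protospacer}, \code{pam} (both in guide
#'   orientation, mutant-allele bases), \code{snv_in},
#'   \code{snv_to_pam_distance}, \code{wt_mismatch_count}, plus the forward
#'   window coordinates of the protospacer and PAM.
#' @export
enumerateProtospacers <- function(ctx, nuclease) {
  stopifnot(is(ctx, "SnvContext"), is(nuclease, "Nuclease"))
  L <- nchar(flankAlt(ctx))
  need <- 2L * contextRadius(nuclease) + 1L
  if (L < need)
    stop("context window too short: ", L, " < ", need,
         " nt required for ", nucleaseName(nuclease))
  snvPos <- snvOffset(ctx)
  sites <- findPamSites(flankAlt(ctx), nuclease, "both")
  sites <- sites[!sites$truncated, , drop = FALSE]
  empty <- data.frame(
    nuclease = character(0), strand = character(0),
    protospacer = character(0), pam = character(0), snv_in = character(0),
    snv_to_pam_distance = integer(0), wt_mismatch_count = integer(0),
    proto_start = integer(0), proto_end = integer(0),
    pam_start = integer(0), pam_end = integer(0), stringsAsFactors = FALSE)
  if (!nrow(sites)) return(empty)

  spanLo <- pmin(sites$proto_start, sites$start)
  spanHi <- pmax(sites$proto_end, sites$end)
  sites <- sites[snvPos >= spanLo & snvPos <= spanHi, , drop = FALSE]
  if (!nrow(sites)) return(empty)

  altChars <- strsplit(flankAlt(ctx), "")[[1]]
  refChars <- strsplit(flankRef(ctx), "")[[1]]
  pat <- pamConsensus(nuclease)
  patChars <- strsplit(pat, "")[[1]]
  plen <- length(patChars)

  rows <- lapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    inPam <- snvPos >= s$start & snvPos <= s$end
    inSeed <- snvPos >= s$seed_start & snvPos <= s$seed_end
    # PAM-proximal protospacer boundary is the one nearest the PAM
    proximal <- if (s$start < s$proto_start) s$proto_start else s$proto_end
    dist <- if (inPam) 0L else abs(snvPos - proximal) + 1L
    protoFwd <- paste(altChars[s$proto_start:s$proto_end], collapse = "")
    proto <- if (s$strand == "+") protoFwd else revComp(protoFwd)
    # wild-type mismatches: literal in the protospacer, consensus-violating
    # in the PAM (a wild-type base still satisfying the consensus is not
    # discriminating)
    mm <- sum(altChars[s$proto_start:s$proto_end] !=
              refChars[s$proto_start:s$proto_end])
    wtPamFwd <- paste(refChars[s$start:s$end], collapse = "")
    wtPamGuide <- if (s$strand == "+") wtPamFwd else revComp(wtPamFwd)
    wtPamChars <- strsplit(wtPamGuide, "")[[1]]
    mm <- mm + sum(!mapply(function(p, b) b %in% IUPAC_SETS[[p]],
                           patChars, wtPamChars))
    data.frame(
      nuclease = nucleaseName(nuclease), strand = s$strand,
      protospacer = proto, pam = s$pam,
      snv_in = if (inSeed) "seed" else if (inPam) "pam" else "distal",
      snv_to_pam_distance = dist, wt_mismatch_count = mm,
      proto_start = s$proto_start, proto_end = s$proto_end,
      pam_start = s$start, pam_end = s$end, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call allele-specific editability of an SNV
#'
#' An SNV is editable by a nuclease when at least one protospacer on the
#' mutant allele carries the variant in its seed window or inside the PAM.
#' With \code{strict = TRUE}, candidates whose wild-type mismatch count is
#' zero (the variant sits at a fully degenerate PAM position and the guide
#' cannot discriminate the alleles) are additionally excluded.
#'
#' @param ctx An [SnvContext-class].
#' @param nuclease A [Nuclease-class].
#' @param strict Require at least one discriminating mismatch against the
#'   wild-type allele (default \code{FALSE}).
#' @return An [EditabilityCall-class]. Its \code{guides} slot holds all
#'   covering candidates with a logical \code{qualifying} column.
#' @examples
#' call <- editability(krasG12SContext(), spCas9())
#' isEditable(call)
#' @export
editability <- function(ctx, nuclease, strict = FALSE) {
  g <- enumerateProtospacers(ctx, nuclease)
  qual <- g$snv_in %in% c("seed", "pam")
  if (strict) qual <- qual & g$wt_mismatch_count >= 1L
  g$qualifying <- qual
  strands <- unique(g$strand[qual])
  cat_ <- if (!any(qual)) "none"
    else if (setequal(strands, "+")) "S"
    else if (setequal(strands, "-")) "AS"
    else "S_plus_AS"
  new("EditabilityCall", snv = ctx, nuclease = nucleaseName(nuclease),
      editable = any(qual), strandCategory = cat_, guides = g)
}

#' Rank the qualifying guides of an editability call
#'
#' Orders qualifying guides by ascending SNV-to-PAM distance (the closer
#' the variant sits to the PAM, the stronger the allele discrimination),
#' breaking ties by strand (sense first) and then lexicographically by
#' protospacer, so the ordering is a total order.
#'
#' @param call An [EditabilityCall-class].
#' @return data.frame of qualifying guides in rank order; 0 rows when the
#'   call is not editable.
#' @export
rankGuides <- function(call) {
  stopifnot(is(call, "EditabilityCall"))
  g <- call@guides[call@guides$qualifying, , drop = FALSE]
  if (!nrow(g)) return(g)
  g <- g[order(g$snv_to_pam_distance, g$strand != "+", g$protospacer), ,
         drop = FALSE]
  rownames(g) <- NULL
  g
}

# human KRAS coding sequence, codons 1-25 (exon 1). Codon 12 (GGT) starts at
# c.34; c.34G>A gives the G12S substitution adjacent to the TGG PAM at
# c.36-38.
KRAS_CDS_5PRIME <-
  "ATGACTGAATATAAACTTGTGGTAGTTGGAGCTGGTGGCGTAGGCAAGAGTGCCTTGACGATACAGCTAATTCAG"

#' KRAS G12S positive-control context
#'
#' Builds the [SnvContext-class] for the KRAS c.34G>A (G12S) variant from
#' the coding-strand sequence of KRAS exon 1. This is the classic
#' allele-specific target: the variant lies in the seed window of an
#' SpCas9 protospacer ending at the TGG PAM at c.36-38.
#'
#' @param radius Window radius in bases around c.34; limited by the exon-1
#'   sequence carried in the package (default 26, enough for all three
#'   default nucleases).
#' @return An [SnvContext-class] for c.34G>A.
#' @examples
#' isEditable(editability(krasG12SContext(), spCas9()))
#' @export
krasG12SContext <- function(radius = 26L) {
  pos <- 34L
  lo <- pos - radius
  hi <- pos + radius
  if (lo < 1L || hi > nchar(KRAS_CDS_5PRIME))
    stop("radius exceeds the packaged KRAS exon-1 sequence")
  SnvContext(substr(KRAS_CDS_5PRIME, lo, hi), offset = radius + 1L,
             altBase = "A", gene = "KRAS", chrom = "KRAS_CDS", pos = pos)
}
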