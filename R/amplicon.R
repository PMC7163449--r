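#' Construct an AmpliconRef
#'
#' Locates (or accepts) the protospacer interval on the forward strand of an
#' amplicon reference and derives the PAM interval, cut position and
#' quantification window. For 3'-PAM nucleases (Cas9 family) the blunt cut
#' is placed 3 bp 5' of the PAM (between protospacer positions 17/18 for a
#' 20-nt spacer); for 5'-PAM nucleases (Cpf1 family) a nominal cut after
#' protospacer position 18 is used. The protospacer must lie on the forward
#' strand of the supplied reference; reverse-complement the amplicon
#' otherwise.
#'
#' @param sequence Amplicon reference sequence.
#' @param nuclease A [Nuclease-class] (default [spCas9()]).
#' @param protospacerStart 1-based start of the protospacer on the
#'   reference; alternatively supply \code{guide} to locate it.
#' @param guide Protospacer sequence to locate on the forward strand
#'   (must occur exactly once with a consensus-matching PAM).
#' @param window Half-width of the quantification window around the cut
#'   (default 10 bp on each side).
#' @param cutAfter Override the cut position (1-based; cut falls between
#'   \code{cutAfter} and \code{cutAfter + 1}).
#' @return An [AmpliconRef-class].
#' @export
ampliconRef <- function(sequence, nuclease = spCas9(),
                        protospacerStart = NULL, guide = NULL,
                        window = 10L, cutAfter = NULL) {
  sequence <- toupper(sequence)
  .checkDna(sequence)
  sp <- spacerLength(nuclease)
  plen <- nchar(pamConsensus(nuclease))
  L <- nchar(sequence)
  if (is.null(protospacerStart)) {
    if (is.null(guide))
      stop("supply either 'protospacerStart' or 'guide'")
    guide <- toupper(guide)
    if (nchar(guide) != sp)
      stop("guide length does not match the nuclease spacer length")
    hits <- which(vapply(seq_len(L - sp + 1L), function(i)
      substr(sequence, i, i + sp - 1L) == guide, logical(1)))
    # keep hits whose adjacent PAM matches the consensus
    hits <- hits[vapply(hits, function(i) {
      pamIv <- if (pamSide(nuclease) == "3prime")
        c(i + sp, i + sp + plen - 1L) else c(i - plen, i - 1L)
      pamIv[1] >= 1L && pamIv[2] <= L &&
        iupacMatch(pamConsensus(nuclease),
                   substr(sequence, pamIv[1], pamIv[2]))
    }, logical(1))]
    if (length(hits) != 1L)
      stop("guide with valid PAM found ", length(hits),
           " times on the forward strand (need exactly 1)")
    protospacerStart <- hits
  }
  protoIv <- IRanges::IRanges(protospacerStart, protospacerStart + sp - 1L)
  pamIv <- if (pamSide(nuclease) == "3prime")
    IRanges::IRanges(IRanges::end(protoIv) + 1L,
                     IRanges::end(protoIv) + plen)
  else
    IRanges::IRanges(IRanges::start(protoIv) - plen,
                     IRanges::start(protoIv) - 1L)
  if (IRanges::start(pamIv) < 1L || IRanges::end(pamIv) > L)
    stop("PAM interval outside the amplicon")
  obs <- substr(sequence, IRanges::start(pamIv), IRanges::end(pamIv))
  if (!iupacMatch(pamConsensus(nuclease), obs))
    warning("observed PAM '", obs, "' does not match consensus '",
            pamConsensus(nuclease), "'")
  if (is.null(cutAfter)) {
    cutAfter <- if (pamSide(nuclease) == "3prime")
      IRanges::end(protoIv) - 3L
    else IRanges::start(protoIv) + 17L
  }
  qw <- IRanges::IRanges(max(1L, cutAfter - window + 1L),
                         min(L, cutAfter + window))
  new("AmpliconRef", sequence = sequence, protospacer = protoIv,
      pam = pamIv, cutAfter = as.integer(cutAfter), quantWindow = qw)
}

#' Global alignment of a read against an amplicon reference
#'
#' Needleman-Wunsch global alignment via
#' [Biostrings::pairwiseAlignment()] with affine gap penalties (a gap of
#' length g costs \code{gapOpen + g * gapExt}). Defaults: match +5,
#' mismatch -4, gap open 10, gap extend 1 — standard DNA scoring under
#' which a single substitution is preferred over a pair of 1-bp gaps.
#'
#' @param reads Character vector or [Biostrings::DNAStringSet] of reads.
#' @param ref Reference sequence (string).
#' @param scoring Named list with \code{match}, \code{mismatch},
#'   \code{gapOpen}, \code{gapExt}.
#' @return List with \code{score} (numeric), \code{alnRead} and
#'   \code{alnRef} (gapped alignment strings, one per read).
#' @export
alignGlobal <- function(reads, ref, scoring = list(match = 5,
                        mismatch = -4, gapOpen = 10, gapExt = 1)) {
  if (is.character(reads)) reads <- Biostrings::DNAStringSet(toupper(reads))
  if (any(Biostrings::width(reads) == 0L) || nchar(ref) == 0L)
    stop("empty read or reference")
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    reads, Biostrings::DNAString(toupper(ref)), type = "global",
    substitutionMatrix = mat, gapOpening = scoring$gapOpen,
    gapExtension = scoring$gapExt)
  list(score = Biostrings::score(aln),
       alnRead = as.character(Biostrings::alignedPattern(aln)),
       alnRef = as.character(Biostrings::alignedSubject(aln)))
}

#' Call editing events from a gapped alignment
#'
#' Walks the alignment columns and emits one event per maximal run: a run
#' of gaps in the read is a deletion (D), a run of gaps in the reference an
#' insertion (I), a run of mismatching bases a substitution (S). Events are
#' kept only when they overlap the quantification window, and positions are
#' reported both on the reference (1-based) and relative to the PAM
#' (\code{pam_rel = 0} at the first PAM base — the N of NGG — negative
#' into the protospacer).
#'
#' When a read quality string is supplied, substitution runs whose minimum
#' base quality falls below \code{minQual} are discarded as likely
#' sequencing error rather than editing.
#'
#' @param alnRead,alnRef Gapped alignment strings (equal length).
#' @param amp An [AmpliconRef-class].
#' @param qual Optional Phred+33 quality string for the (ungapped) read.
#' @param minQual Minimum base quality for substitution runs (default 20).
#' @return data.frame with columns \code{kind} (\code{I}/\code{D}/\code{S}),
#'   \code{length}, \code{ref_start}, \code{pam_rel}.
#' @export
callEvents <- function(alnRead, alnRef, amp, qual = NULL, minQual = 20L) {
  stopifnot(is(amp, "AmpliconRef"), nchar(alnRead) == nchar(alnRef))
  rd <- strsplit(alnRead, "")[[1]]
  rf <- strsplit(alnRef, "")[[1]]
  qv <- if (!is.null(qual)) utf8ToInt(qual) - 33L else NULL
  n <- length(rd)
  kind <- character(n)
  refPos <- integer(n)   # ref position of (or immediately 5' of) the column
  readPos <- integer(n)
  rp <- 0L; dp <- 0L
  for (i in seq_len(n)) {
    if (rf[i] != "-") rp <- rp + 1L
    if (rd[i] != "-") dp <- dp + 1L
    refPos[i] <- rp
    readPos[i] <- dp
    kind[i] <- if (rf[i] == "-") "I"
      else if (rd[i] == "-") "D"
      else if (rd[i] != rf[i]) "S"
      else "M"
  }
  runs <- rle(kind)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  qs <- IRanges::start(amp@quantWindow)
  qe <- IRanges::end(amp@quantWindow)
  pamStart <- IRanges::start(amp@pam)
  out <- list()
  for (k in seq_along(runs$values)) {
    v <- runs$values[k]
    if (v == "M") next
    i0 <- starts[k]; i1 <- ends[k]
    len <- runs$lengths[k]
    if (v == "I") {
      anchor <- refPos[i0]           # insertion after this ref base
      inWin <- anchor >= qs - 1L && anchor <= qe
      start1 <- anchor
    } else {
      start1 <- refPos[i0]
      end1 <- refPos[i1]
      inWin <- start1 <= qe && end1 >= qs
    }
    if (!inWin) next
    if (v == "S" && !is.null(qv)) {
      rq <- qv[readPos[i0]:readPos[i1]]
      if (min(rq) < minQual) next
    }
    out[[length(out) + 1L]] <- data.frame(
      kind = v, length = len, ref_start = start1,
      pam_rel = start1 - pamStart, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(kind = character(0), length = integer(0),
                      ref_start = integer(0), pam_rel = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Classify a read from its editing events
#'
#' A read with no events in the quantification window is unmodified; with
#' events of a single kind it is I, D or S and labelled by the kind plus
#' the total bases changed (e.g. \code{I1}, \code{D2}); with two or more
#' distinct kinds it is a combination (\code{C}).
#'
#' @param events data.frame from [callEvents()].
#' @return List with \code{category} (\code{unmodified}/\code{I}/\code{D}/
#'   \code{S}/\code{C}), \code{label}, and \code{total_bp} changed.
#' @export
classifyRead <- function(events) {
  if (!nrow(events))
    return(list(category = "unmodified", label = "unmodified",
                total_bp = 0L))
  kinds <- unique(events$kind)
  total <- sum(events$length)
  if (length(kinds) >= 2L)
    list(category = "C", label = "C", total_bp = total)
  else
    list(category = kinds, label = paste0(kinds, total), total_bp = total)
}

#' Profile amplicon reads: align, call events, classify
#'
#' End-to-end per-read analysis: global alignment against the amplicon
#' reference, event calling inside the quantification window, and outcome
#' classification. Reads whose alignment score falls below
#' \code{minScoreFrac} of the perfect-match score are dropped (and
#' counted), since they cannot be interpreted across the window.
#'
#' @param reads Character vector or [Biostrings::DNAStringSet].
#' @param amp An [AmpliconRef-class].
#' @param scoring See [alignGlobal()].
#' @param minScoreFrac Score floor as a fraction of the perfect score
#'   (default 0.3).
#' @param qualities Optional character vector of Phred+33 quality strings.
#' @param minQual See [callEvents()].
#' @return List of class \code{ampliconProfile}: \code{outcomes}
#'   (data.frame: \code{read}, \code{category}, \code{label},
#'   \code{total_bp}), \code{events} (data.frame with a \code{read}
#'   column), \code{n_dropped}, \code{n_total}.
#' @export
profileAmplicon <- function(reads, amp, scoring = list(match = 5,
                            mismatch = -4, gapOpen = 10, gapExt = 1),
                            minScoreFrac = 0.3, qualities = NULL,
                            minQual = 20L) {
  stopifnot(is(amp, "AmpliconRef"))
  if (is.character(reads)) reads <- Biostrings::DNAStringSet(toupper(reads))
  if (!length(reads)) stop("no reads supplied")
  ids <- names(reads) %||% paste0("read", seq_along(reads))
  aln <- alignGlobal(reads, amp@sequence, scoring)
  floor_ <- minScoreFrac * scoring$match * nchar(amp@sequence)
  keep <- aln$score >= floor_
  outcomes <- vector("list", sum(keep))
  events <- vector("list", sum(keep))
  j <- 0L
  for (i in which(keep)) {
    j <- j + 1L
    ev <- callEvents(aln$alnRead[i], aln$alnRef[i], amp,
                     qual = qualities[i], minQual = minQual)
    cl <- classifyRead(ev)
    outcomes[[j]] <- data.frame(read = ids[i], category = cl$category,
                                label = cl$label, total_bp = cl$total_bp,
                                stringsAsFactors = FALSE)
    if (nrow(ev)) {
      ev$read <- ids[i]
      events[[j]] <- ev
    }
  }
  out <- list(
    outcomes = do.call(rbind, outcomes),
    events = if (length(ev <- Filter(Negate(is.null), events)))
      do.call(rbind, ev)
    else data.frame(kind = character(0), length = integer(0),
                    ref_start = integer(0), pam_rel = integer(0),
                    read = character(0), stringsAsFactors = FALSE),
    n_dropped = sum(!keep),
    n_total = length(reads))
  class(out) <- "ampliconProfile"
  out
}

#' @export
print.ampliconProfile <- function(x, ...) {
  cat("ampliconProfile: ", nrow(x$outcomes), " reads analysed (",
      x$n_dropped, " dropped of ", x$n_total, "); efficiency ",
      signif(editingEfficiency(x), 3), "\n", sep = "")
  print(utils::head(sort(table(x$outcomes$label), decreasing = TRUE), 10))
  invisible(x)
}

#' Editing-outcome spectra
#'
#' Aggregates per-read outcomes into the three standard spectra: outcome
#' labels (I1, D2, S2, C, ...), total-length-change histogram, and
#' event-position histogram relative to the PAM. Label and length
#' frequencies are computed over modified reads by default (so the printed
#' classes sum to 1); set \code{overModified = FALSE} to use all reads as
#' the denominator.
#'
#' @param profile An \code{ampliconProfile} from [profileAmplicon()].
#' @param overModified Use modified reads as the denominator (default
#'   \code{TRUE}).
#' @return List: \code{labelFreq}, \code{categoryFreq} (named numeric),
#'   \code{lengthHist}, \code{positionHist} (data.frames of counts and
#'   frequencies), \code{n_modified}, \code{n_reads}.
#' @export
buildSpectra <- function(profile, overModified = TRUE) {
  oc <- profile$outcomes
  mod <- oc[oc$category != "unmodified", , drop = FALSE]
  if (!nrow(mod)) {
    warning("all reads unmodified; spectra are empty")
    return(list(labelFreq = numeric(0), categoryFreq = numeric(0),
                lengthHist = data.frame(), positionHist = data.frame(),
                n_modified = 0L, n_reads = nrow(oc)))
  }
  denom <- if (overModified) nrow(mod) else nrow(oc)
  lf <- table(mod$label)
  labelFreq <- sort(stats::setNames(as.numeric(lf) / denom, names(lf)),
                    decreasing = TRUE)
  cf <- table(factor(mod$category, levels = c("I", "D", "S", "C")))
  categoryFreq <- stats::setNames(as.numeric(cf) / denom, names(cf))
  lh <- table(mod$total_bp)
  lengthHist <- data.frame(length_bp = as.integer(names(lh)),
                           count = as.integer(lh),
                           freq = as.numeric(lh) / denom)
  ev <- profile$events
  ph <- table(ev$pam_rel)
  positionHist <- data.frame(pam_rel = as.integer(names(ph)),
                             count = as.integer(ph),
                             freq = as.numeric(ph) / nrow(ev))
  list(labelFreq = labelFreq, categoryFreq = categoryFreq,
       lengthHist = lengthHist, positionHist = positionHist,
       n_modified = nrow(mod), n_reads = nrow(oc))
}

#' Editing efficiency
#'
#' Fraction of analysed reads carrying at least one editing event in the
#' quantification window.
#'
#' @param profile An \code{ampliconProfile}.
#' @return Numeric in [0, 1].
#' @export
editingEfficiency <- function(profile) {
  mean(profile$outcomes$category != "unmodified")
}

#' Read amplicon reads from a FASTQ file
#'
#' @param path FASTQ file.
#' @return List with \code{reads} ([Biostrings::DNAStringSet]) and
#'   \code{qualities} (character vector of Phred+33 strings).
#' @export
readAmpliconReads <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  list(reads = x,
       qualities = as.character(S4Vectors::mcols(x)$qualities))
}
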