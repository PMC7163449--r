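# Vectorised PAM scanning. Sequences are handled as character vectors of
# single letters; for each pattern position the set of admissible letters is
# intersected across all candidate windows at once, which keeps the scan
# O(L * |pam|) without compiled code.

# returns 1-based start positions of windows of seqChars matching pattern
.scanStarts <- function(seqChars, pattern) {
  L <- length(seqChars)
  pc <- strsplit(pattern, "")[[1]]
  plen <- length(pc)
  if (L < plen) return(integer(0))
  n <- L - plen + 1L
  ok <- rep(TRUE, n)
  for (j in seq_len(plen)) {
    allowed <- IUPAC_SETS[[pc[j]]]
    ok <- ok & (seqChars[j:(j + n - 1L)] %in% allowed)
  }
  which(ok)
}

# protospacer/seed intervals (1-based, on the same coordinates as pamStart)
# for a PAM occupying [pamStart, pamStart + plen - 1]
.guideGeometry <- function(pamStart, plen, pamSide, spacerLen, seedLen) {
  pamEnd <- pamStart + plen - 1L
  if (pamSide == "3prime") {
    protoStart <- pamStart - spacerLen
    protoEnd <- pamStart - 1L
    seedStart <- pamStart - seedLen
    seedEnd <- pamStart - 1L
  } else {
    protoStart <- pamEnd + 1L
    protoEnd <- pamEnd + spacerLen
    seedStart <- pamEnd + 1L
    seedEnd <- pamEnd + seedLen
  }
  list(protoStart = protoStart, protoEnd = protoEnd,
       seedStart = seedStart, seedEnd = seedEnd, pamEnd = pamEnd)
}

# mirror a 1-based interval from revcomp coordinates back to forward
.mirror <- function(a, b, L) c(L - b + 1L, L - a + 1L)

#' Find PAM sites on a sequence
#'
#' Scans a DNA sequence for windows matching a nuclease's PAM consensus on
#' the forward and/or reverse strand, and reports each site with its
#' protospacer and seed intervals mapped to forward coordinates (1-based,
#' closed, IRanges-style). Windows containing \code{N} never match unless
#' the consensus itself has \code{N} at that position.
#'
#' Sites whose protospacer would extend past either end of the sequence are
#' still reported but flagged \code{truncated}; downstream editability calls
#' exclude them by default.
#'
#' @param seq DNA string (alphabet ACGTN).
#' @param nuclease A [Nuclease-class].
#' @param strands \code{"both"} (default), \code{"forward"} or
#'   \code{"reverse"}.
#' @return data.frame with one row per site: \code{start}, \code{end} (PAM
#'   interval in forward coordinates), \code{strand} (\code{"+"}/\code{"-"}),
#'   \code{pam} (observed PAM bases in guide orientation),
#'   \code{proto_start}, \code{proto_end}, \code{seed_start},
#'   \code{seed_end} (forward coordinates; for reverse-strand sites the
#'   PAM-proximal protospacer end is the boundary nearest the PAM), and
#'   \code{truncated}.
#' @examples
#' sp <- Nuclease("SpCas9", "NGG", "3prime", 20, 8)
#' findPamSites("TTTACGGAGG", sp)
#' @export
findPamSites <- function(seq, nuclease, strands = c("both", "forward",
                                                    "reverse")) {
  strands <- match.arg(strands)
  stopifnot(is(nuclease, "Nuclease"))
  seq <- toupper(seq)
  .checkDna(seq)
  pat <- pamConsensus(nuclease)
  plen <- nchar(pat)
  if (nchar(seq) < plen)
    stop("sequence shorter than the PAM consensus")
  L <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  side <- pamSide(nuclease)
  sp <- spacerLength(nuclease)
  sd <- seedLength(nuclease)

  rows <- list()
  if (strands %in% c("both", "forward")) {
    st <- .scanStarts(chars, pat)
    if (length(st)) {
      g <- .guideGeometry(st, plen, side, sp, sd)
      rows[[length(rows) + 1L]] <- data.frame(
        start = st, end = g$pamEnd, strand = "+",
        pam = substring(seq, st, g$pamEnd),
        proto_start = g$protoStart, proto_end = g$protoEnd,
        seed_start = g$seedStart, seed_end = g$seedEnd,
        truncated = g$protoStart < 1L | g$protoEnd > L,
        stringsAsFactors = FALSE)
    }
  }
  if (strands %in% c("both", "reverse")) {
    rcSeq <- revComp(seq)
    rcChars <- strsplit(rcSeq, "")[[1]]
    st <- .scanStarts(rcChars, pat)
    if (length(st)) {
      g <- .guideGeometry(st, plen, side, sp, sd)
      # map every interval from revcomp coordinates to forward coordinates
      pamF <- rbind(L - g$pamEnd + 1L, L - st + 1L)
      protoF <- rbind(L - g$protoEnd + 1L, L - g$protoStart + 1L)
      seedF <- rbind(L - g$seedEnd + 1L, L - g$seedStart + 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        start = pamF[1L, ], end = pamF[2L, ], strand = "-",
        pam = substring(rcSeq, st, g$pamEnd),
        proto_start = protoF[1L, ], proto_end = protoF[2L, ],
        seed_start = seedF[1L, ], seed_end = seedF[2L, ],
        truncated = protoF[1L, ] < 1L | protoF[2L, ] > L,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), pam = character(0),
                      proto_start = integer(0), proto_end = integer(0),
                      seed_start = integer(0), seed_end = integer(0),
                      truncated = logical(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
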