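# Degeneracy sets for the IUPAC nucleotide codes. A subject 'N' (unknown
# base, e.g. an assembly gap) is deliberately NOT a member of any set except
# pattern 'N': unknown bases must never create phantom PAM matches.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"),
  N = c("A", "C", "G", "T", "N")
)

.checkDna <- function(seq, what = "seq") {
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop("'", what, "' contains letters outside {A,C,G,T,N}: ",
         paste(bad, collapse = ","))
  invisible(TRUE)
}

#' Match a DNA string against an IUPAC degenerate pattern
#'
#' Position-wise comparison of a subject DNA string (alphabet ACGTN) with an
#' equal-length IUPAC pattern. Each subject base must belong to the
#' degeneracy set of the corresponding pattern code. A subject \code{N}
#' matches only a pattern \code{N}, so unknown bases cannot satisfy a PAM
#' consensus.
#'
#' @param pattern IUPAC string (e.g. \code{"NGG"}, \code{"TTTV"}).
#' @param subject DNA string of the same length, or a character vector of
#'   such strings.
#' @return Logical, one element per subject.
#' @examples
#' iupacMatch("NGG", "AGG")
#' iupacMatch("TTTV", c("TTTG", "TTTT"))
#' @export
iupacMatch <- function(pattern, subject) {
  pattern <- toupper(pattern)
  pc <- strsplit(pattern, "")[[1]]
  if (!all(pc %in% names(IUPAC_SETS)))
    stop("'pattern' contains non-IUPAC code(s): ",
         paste(setdiff(pc, names(IUPAC_SETS)), collapse = ","))
  subject <- toupper(subject)
  if (any(nchar(subject) != nchar(pattern)))
    stop("pattern and subject must have equal lengths")
  vapply(subject, function(s) {
    .checkDna(s, "subject")
    sc <- strsplit(s, "")[[1]]
    all(mapply(function(p, b) b %in% IUPAC_SETS[[p]], pc, sc))
  }, logical(1), USE.NAMES = FALSE)
}

#' Reverse complement of a DNA string
#'
#' Thin character-vector wrapper around
#' [Biostrings::reverseComplement()]; accepts and returns plain strings over
#' ACGTN.
#'
#' @param seq DNA string or character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @examples
#' revComp("ACGT")   # palindromic
#' revComp("AAA")
#' @export
revComp <- function(seq) {
  seq <- toupper(seq)
  for (s in seq) .checkDna(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}
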