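#' Load a nuclease registry from a TSV file
#'
#' The registry is a plain-text TSV with columns \code{name}, \code{pam},
#' \code{pam_side} (\code{3prime}/\code{5prime}), \code{spacer_len} and
#' \code{seed_len}. The packaged default registry describes SpCas9 (PAM NGG,
#' 3' of a 20-nt spacer), SaCas9 (NNGRRT, 3' of a 21-nt spacer) and LbCpf1
#' (TTTV, 5' of a 23-nt spacer). Seed lengths are conservative lower bounds
#' from the characterisation literature (8 nt for the Cas9s, 6 nt for
#' LbCpf1); shipping them as data rather than code means they can be
#' adjusted without touching the scanner.
#'
#' @param path Registry TSV; defaults to the packaged registry.
#' @return Named list of [Nuclease-class] objects.
#' @examples
#' nucleaseRegistry()
#' @export
nucleaseRegistry <- function(path = system.file("extdata", "nucleases.tsv",
                                                package = "crisprAllele")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "pam", "pam_side", "spacer_len", "seed_len")
  if (!all(need %in% names(tab)))
    stop("registry must have columns: ", paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(tab)), function(i)
    Nuclease(tab$name[i], tab$pam[i], tab$pam_side[i],
             tab$spacer_len[i], tab$seed_len[i]))
  names(out) <- tab$name
  out
}

#' Default nucleases
#'
#' Convenience accessors for the three enzymes in the packaged registry.
#'
#' @return A [Nuclease-class] ([spCas9()], [saCas9()], [lbCpf1()]) or the
#'   full named list ([defaultNucleases()]).
#' @examples
#' spCas9()
#' @export
defaultNucleases <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- nucleaseRegistry()
    cache
  }
})

#' @rdname defaultNucleases
#' @export
spCas9 <- function() defaultNucleases()[["SpCas9"]]

#' @rdname defaultNucleases
#' @export
saCas9 <- function() defaultNucleases()[["SaCas9"]]

#' @rdname defaultNucleases
#' @export
lbCpf1 <- function() defaultNucleases()[["LbCpf1"]]
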