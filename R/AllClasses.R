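#' @import methods
NULL

#' Nuclease class
#'
#' Describes the targeting geometry of a CRISPR nuclease: its PAM consensus
#' (IUPAC degenerate string), which side of the protospacer the PAM sits on,
#' the protospacer (spacer) length, and the seed length. The seed is the
#' PAM-proximal portion of the protospacer where single mismatches abolish
#' cleavage, and is therefore the window that confers allele discrimination.
#'
#' @slot name Character label, e.g. \code{"SpCas9"}.
#' @slot pam PAM consensus as an IUPAC string, e.g. \code{"NGG"},
#'   \code{"NNGRRT"}, \code{"TTTV"}.
#' @slot pamSide Either \code{"3prime"} (PAM follows the protospacer, Cas9
#'   family) or \code{"5prime"} (PAM precedes it, Cpf1/Cas12a family).
#' @slot spacerLength Integer protospacer length in bases.
#' @slot seedLength Integer seed length in bases, counted from the
#'   PAM-proximal end of the protospacer. Must be between 1 and
#'   \code{spacerLength}.
#'
#' @seealso [Nuclease()], [nucleaseRegistry()], [findPamSites()]
#' @export
setClass("Nuclease",
  representation(
    name = "character",
    pam = "character",
    pamSide = "character",
    spacerLength = "integer",
    seedLength = "integer"
  )
)

setValidity("Nuclease", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@pam) != 1L || !nzchar(object@pam))
    msg <- c(msg, "'pam' must be a single non-empty IUPAC string")
  else {
    bad <- setdiff(strsplit(object@pam, "")[[1]], names(IUPAC_SETS))
    if (length(bad))
      msg <- c(msg, paste0("'pam' contains non-IUPAC code(s): ",
                           paste(bad, collapse = ",")))
  }
  if (!object@pamSide %in% c("3prime", "5prime"))
    msg <- c(msg, "'pamSide' must be \"3prime\" or \"5prime\"")
  if (length(object@spacerLength) != 1L || is.na(object@spacerLength) ||
      object@spacerLength < 1L)
    msg <- c(msg, "'spacerLength' must be a positive integer")
  if (length(object@seedLength) != 1L || is.na(object@seedLength) ||
      object@seedLength < 1L || object@seedLength > object@spacerLength)
    msg <- c(msg, "'seedLength' must be in [1, spacerLength]")
  if (length(msg)) msg else TRUE
})

#' Construct a Nuclease
#'
#' @param name Label for the enzyme.
#' @param pam PAM consensus (IUPAC string).
#' @param pamSide \code{"3prime"} or \code{"5prime"}.
#' @param spacerLength Protospacer length in bases.
#' @param seedLength Seed length in bases (PAM-proximal).
#' @return A [Nuclease-class] object.
#' @examples
#' Nuclease("SpCas9", "NGG", "3prime", 20, 8)
#' @export
Nuclease <- function(name, pam, pamSide = c("3prime", "5prime"),
                     spacerLength, seedLength) {
  pamSide <- match.arg(pamSide)
  new("Nuclease", name = as.character(name), pam = toupper(pam),
      pamSide = pamSide, spacerLength = as.integer(spacerLength),
      seedLength = as.integer(seedLength))
}

#' @describeIn Nuclease-class PAM consensus string.
#' @param object,x A \code{Nuclease}.
#' @export
setGeneric("pamConsensus", function(x) standardGeneric("pamConsensus"))
#' @rdname Nuclease-class
#' @export
setMethod("pamConsensus", "Nuclease", function(x) x@pam)

#' @rdname Nuclease-class
#' @export
setGeneric("pamSide", function(x) standardGeneric("pamSide"))
#' @rdname Nuclease-class
#' @export
setMethod("pamSide", "Nuclease", function(x) x@pamSide)

#' @rdname Nuclease-class
#' @export
setGeneric("spacerLength", function(x) standardGeneric("spacerLength"))
#' @rdname Nuclease-class
#' @export
setMethod("spacerLength", "Nuclease", function(x) x@spacerLength)

#' @rdname Nuclease-class
#' @export
setGeneric("seedLength", function(x) standardGeneric("seedLength"))
#' @rdname Nuclease-class
#' @export
setMethod("seedLength", "Nuclease", function(x) x@seedLength)

#' @rdname Nuclease-class
#' @param value Replacement seed length.
#' @export
setGeneric("seedLength<-", function(x, value) standardGeneric("seedLength<-"))
#' @rdname Nuclease-class
#' @export
setMethod("seedLength<-", "Nuclease", function(x, value) {
  x@seedLength <- as.integer(value)
  validObject(x)
  x
})

#' @rdname Nuclease-class
#' @export
setGeneric("nucleaseName", function(x) standardGeneric("nucleaseName"))
#' @rdname Nuclease-class
#' @export
setMethod("nucleaseName", "Nuclease", function(x) x@name)

setMethod("show", "Nuclease", function(object) {
  cat("Nuclease: ", object@name, "\n",
      "  PAM ", object@pam, " (", object@pamSide, " of a ",
      object@spacerLength, "-nt spacer), seed ", object@seedLength,
      " nt\n", sep = "")
})

#' SnvContext class
#'
#' A single-nucleotide variant together with the reference-allele and
#' mutant-allele sequence windows centred on it. Targetability scanning is
#' performed on the mutant-allele window (the guide must recognise the
#' mutant), while the reference window supplies the wild-type mismatch
#' accounting.
#'
#' Coordinates inside the window are 1-based (the usual R/IRanges
#' convention): \code{snvOffset(x)} gives the 1-based position of the variant
#' base within \code{flankRef(x)}/\code{flankAlt(x)}.
#'
#' @slot gene Gene label (may be \code{""}).
#' @slot chrom Chromosome/sequence label.
#' @slot pos 1-based genomic position of the variant.
#' @slot refBase,altBase Single reference/alternate bases (must differ).
#' @slot flankRef,flankAlt Equal-length windows carrying the reference and
#'   alternate base respectively at \code{offset}.
#' @slot offset 1-based position of the variant inside the windows.
#' @slot truncated \code{TRUE} when the window ran off a sequence end and was
#'   padded with \code{N}.
#' @seealso [SnvContext()], [editability()], [extractContext()]
#' @export
setClass("SnvContext",
  representation(
    gene = "character",
    chrom = "character",
    pos = "integer",
    refBase = "character",
    altBase = "character",
    flankRef = "character",
    flankAlt = "character",
    offset = "integer",
    truncated = "logical"
  )
)

setValidity("SnvContext", function(object) {
  msg <- character()
  if (nchar(object@refBase) != 1L || nchar(object@altBase) != 1L)
    msg <- c(msg, "refBase/altBase must be single bases")
  if (identical(object@refBase, object@altBase))
    msg <- c(msg, "refBase and altBase must differ")
  if (nchar(object@flankRef) != nchar(object@flankAlt))
    msg <- c(msg, "flankRef and flankAlt must have equal length")
  o <- object@offset
  if (is.na(o) || o < 1L || o > nchar(object@flankRef))
    msg <- c(msg, "offset outside the window")
  else {
    if (substr(object@flankRef, o, o) != object@refBase)
      msg <- c(msg, "flankRef does not carry refBase at offset")
    if (substr(object@flankAlt, o, o) != object@altBase)
      msg <- c(msg, "flankAlt does not carry altBase at offset")
  }
  bad <- setdiff(strsplit(paste0(object@flankRef, object@flankAlt), "")[[1]],
                 c("A", "C", "G", "T", "N"))
  if (length(bad))
    msg <- c(msg, paste0("windows contain non-ACGTN letters: ",
                         paste(unique(bad), collapse = ",")))
  if (length(msg)) msg else TRUE
})

#' Construct an SnvContext
#'
#' @param flankRef Reference-allele window (uppercase ACGTN).
#' @param offset 1-based position of the variant inside the window.
#' @param altBase Alternate base.
#' @param gene,chrom,pos Optional annotation (gene label, chromosome,
#'   1-based genomic position).
#' @param truncated Whether the window was N-padded at a sequence end.
#' @return An [SnvContext-class] object. \code{flankAlt} is derived by
#'   substituting \code{altBase} at \code{offset}.
#' @examples
#' ctx <- SnvContext("AAAGGGCCCTTT", offset = 6, altBase = "A")
#' flankAlt(ctx)
#' @export
SnvContext <- function(flankRef, offset, altBase, gene = "", chrom = "",
                       pos = NA_integer_, truncated = FALSE) {
  flankRef <- toupper(flankRef)
  offset <- as.integer(offset)
  refBase <- substr(flankRef, offset, offset)
  flankAlt <- flankRef
  substr(flankAlt, offset, offset) <- toupper(altBase)
  new("SnvContext", gene = as.character(gene), chrom = as.character(chrom),
      pos = as.integer(pos), refBase = refBase, altBase = toupper(altBase),
      flankRef = flankRef, flankAlt = flankAlt, offset = offset,
      truncated = isTRUE(truncated))
}

#' @rdname SnvContext-class
#' @param x An \code{SnvContext}.
#' @export
setGeneric("flankRef", function(x) standardGeneric("flankRef"))
#' @rdname SnvContext-class
#' @export
setMethod("flankRef", "SnvContext", function(x) x@flankRef)

#' @rdname SnvContext-class
#' @export
setGeneric("flankAlt", function(x) standardGeneric("flankAlt"))
#' @rdname SnvContext-class
#' @export
setMethod("flankAlt", "SnvContext", function(x) x@flankAlt)

#' @rdname SnvContext-class
#' @export
setGeneric("snvOffset", function(x) standardGeneric("snvOffset"))
#' @rdname SnvContext-class
#' @export
setMethod("snvOffset", "SnvContext", function(x) x@offset)

setMethod("show", "SnvContext", function(object) {
  lab <- if (nzchar(object@gene)) paste0(object@gene, " ") else ""
  loc <- if (nzchar(object@chrom))
    paste0(object@chrom, ":", object@pos, " ") else ""
  cat("SnvContext: ", lab, loc, object@refBase, ">", object@altBase,
      " (window ", nchar(object@flankRef), " nt, variant at ",
      object@offset, ")\n", sep = "")
})

#' EditabilityCall class
#'
#' Per-nuclease verdict on whether an SNV can be targeted
#' allele-specifically, with the candidate guides that support it. A variant
#' is called editable when at least one protospacer on the mutant allele
#' carries it in the seed window or in the PAM itself.
#'
#' @slot snv The [SnvContext-class] that was scanned.
#' @slot nuclease Name of the nuclease.
#' @slot editable Logical verdict.
#' @slot strandCategory One of \code{"S"} (only sense-strand guides qualify),
#'   \code{"AS"}, \code{"S_plus_AS"}, or \code{"none"}.
#' @slot guides data.frame of all candidate guides covering the SNV (see
#'   [enumerateProtospacers()]); the \code{qualifying} column marks those
#'   with the SNV in seed or PAM (after the strict-discrimination filter,
#'   when enabled).
#' @seealso [editability()], [rankGuides()]
#' @export
setClass("EditabilityCall",
  representation(
    snv = "SnvContext",
    nuclease = "character",
    editable = "logical",
    strandCategory = "character",
    guides = "data.frame"
  )
)

setValidity("EditabilityCall", function(object) {
  msg <- character()
  if (!object@strandCategory %in% c("S", "AS", "S_plus_AS", "none"))
    msg <- c(msg, "invalid strandCategory")
  nq <- sum(object@guides$qualifying %||% logical(0))
  if (object@editable != (nq > 0L))
    msg <- c(msg, "editable flag inconsistent with qualifying guides")
  if (!object@editable && object@strandCategory != "none")
    msg <- c(msg, "non-editable call must have strandCategory \"none\"")
  if (length(msg)) msg else TRUE
})

#' @rdname EditabilityCall-class
#' @param x An \code{EditabilityCall}.
#' @export
setGeneric("isEditable", function(x) standardGeneric("isEditable"))
#' @rdname EditabilityCall-class
#' @export
setMethod("isEditable", "EditabilityCall", function(x) x@editable)

#' @rdname EditabilityCall-class
#' @export
setGeneric("strandCategory", function(x) standardGeneric("strandCategory"))
#' @rdname EditabilityCall-class
#' @export
setMethod("strandCategory", "EditabilityCall", function(x) x@strandCategory)

#' @rdname EditabilityCall-class
#' @export
setGeneric("guides", function(x) standardGeneric("guides"))
#' @rdname EditabilityCall-class
#' @export
setMethod("guides", "EditabilityCall", function(x) x@guides)

setMethod("show", "EditabilityCall", function(object) {
  cat("EditabilityCall [", object@nuclease, "]: ",
      if (object@editable) "EDITABLE" else "not editable",
      " (strand category ", object@strandCategory, ", ",
      sum(object@guides$qualifying), " qualifying / ",
      nrow(object@guides), " candidate guides)\n", sep = "")
})

#' AmpliconRef class
#'
#' Reference geometry for an amplicon deep-sequencing experiment: the
#' amplicon sequence, the protospacer and PAM intervals on its forward
#' strand, the (blunt) cut position, and the quantification window within
#' which editing events are counted.
#'
#' @slot sequence Amplicon reference sequence (forward strand; the
#'   protospacer must lie on this strand).
#' @slot protospacer,pam 1-based closed [IRanges::IRanges] intervals.
#' @slot cutAfter 1-based position such that the nuclease cuts between
#'   \code{cutAfter} and \code{cutAfter + 1}.
#' @slot quantWindow 1-based closed interval around the cut inside which
#'   events are quantified.
#' @seealso [ampliconRef()], [profileAmplicon()]
#' @export
setClass("AmpliconRef",
  representation(
    sequence = "character",
    protospacer = "IRanges",
    pam = "IRanges",
    cutAfter = "integer",
    quantWindow = "IRanges"
  )
)

setValidity("AmpliconRef", function(object) {
  msg <- character()
  L <- nchar(object@sequence)
  iv <- function(r) IRanges::start(r) >= 1L && IRanges::end(r) <= L
  if (!iv(object@protospacer)) msg <- c(msg, "protospacer outside sequence")
  if (!iv(object@pam)) msg <- c(msg, "pam outside sequence")
  if (!iv(object@quantWindow)) msg <- c(msg, "quantWindow outside sequence")
  adj <- IRanges::start(object@pam) == IRanges::end(object@protospacer) + 1L ||
         IRanges::end(object@pam) == IRanges::start(object@protospacer) - 1L
  if (!adj) msg <- c(msg, "PAM must be adjacent to the protospacer")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AmpliconRef", function(object) {
  cat("AmpliconRef: ", nchar(object@sequence), " nt; protospacer ",
      IRanges::start(object@protospacer), "-",
      IRanges::end(object@protospacer), ", PAM ",
      IRanges::start(object@pam), "-", IRanges::end(object@pam),
      ", cut after ", object@cutAfter, ", window ",
      IRanges::start(object@quantWindow), "-",
      IRanges::end(object@quantWindow), "\n", sep = "")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
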