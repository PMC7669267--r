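#' TemplateSpec: amplicon layout of a saturation-mutagenesis library
#'
#' Describes the sequenced amplicon well enough to locate and validate the
#' library gene in each read: the wild-type gene sequence, which codons are
#' randomised (NNK), the sample barcode length and map, and the admissible
#' random-spacer lengths between barcode and gene. Reads are laid out as
#' `[barcode][random spacer][gene]`; the gene is located by exact match of
#' an anchor (the first `anchorLength` bases of the gene) tried at each
#' spacer offset in order.
#'
#' @slot geneSeq Wild-type nucleotide sequence of the gene (length divisible
#'   by 3).
#' @slot codonPositions Integer vector of the three randomised codon indices
#'   (1-based into the codon sequence).
#' @slot barcodeLength Length of the sample barcode (default 6).
#' @slot spacerRange Inclusive range of random-spacer lengths, default
#'   `c(4L, 6L)`.
#' @slot barcodeMap Named character vector, barcode -> sample identifier.
#' @slot anchorLength Number of leading gene bases used as the exact-match
#'   anchor (default 12).
#'
#' @export
setClass("TemplateSpec",
  representation(geneSeq = "character",
                 codonPositions = "integer",
                 barcodeLength = "integer",
                 spacerRange = "integer",
                 barcodeMap = "character",
                 anchorLength = "integer"))

setValidity("TemplateSpec", function(object) {
  msg <- character()
  n <- nchar(object@geneSeq)
  if (length(object@geneSeq) != 1L || n %% 3L != 0L || n == 0L)
    msg <- c(msg, "geneSeq must be a single sequence of length divisible by 3")
  if (any(!strsplit(object@geneSeq, "")[[1]] %in% DNA_BASES))
    msg <- c(msg, "geneSeq may only contain A, C, G, T")
  nc <- n %/% 3L
  if (length(object@codonPositions) != 3L ||
      anyDuplicated(object@codonPositions) ||
      any(object@codonPositions < 1L | object@codonPositions > nc))
    msg <- c(msg, "codonPositions must be three distinct in-range codon indices")
  if (length(object@barcodeMap)) {
    if (is.null(names(object@barcodeMap)) ||
        any(nchar(names(object@barcodeMap)) != object@barcodeLength))
      msg <- c(msg, "barcodeMap names must be barcodes of barcodeLength")
    if (anyDuplicated(names(object@barcodeMap)))
      msg <- c(msg, "duplicate barcodes in barcodeMap")
  }
  if (length(object@spacerRange) != 2L ||
      object@spacerRange[1] > object@spacerRange[2] ||
      any(object@spacerRange < 0L))
    msg <- c(msg, "spacerRange must be a non-decreasing pair of non-negative lengths")
  if (object@anchorLength < 1L || object@anchorLength > n)
    msg <- c(msg, "anchorLength out of range")
  if (length(msg)) msg else TRUE
})

#' Construct a TemplateSpec
#'
#' @param geneSeq Wild-type nucleotide sequence (character scalar).
#' @param codonPositions Three distinct 1-based codon indices of the
#'   randomised (NNK) positions.
#' @param barcodeMap Named character vector mapping barcode -> sample id.
#' @param barcodeLength Barcode length; defaults to the barcode widths in
#'   `barcodeMap`, or 6.
#' @param spacerRange Inclusive random-spacer length range, default `c(4, 6)`.
#' @param anchorLength Anchor length for locating the gene, default 12.
#' @return A [TemplateSpec-class] object.
#' @export
#' @examples
#' tpl <- exampleTemplate()
#' wtTriplet(tpl)
TemplateSpec <- function(geneSeq, codonPositions,
                         barcodeMap = character(),
                         barcodeLength = NULL,
                         spacerRange = c(4L, 6L),
                         anchorLength = 12L) {
  if (is.null(barcodeLength))
    barcodeLength <- if (length(barcodeMap)) nchar(names(barcodeMap)[1]) else 6L
  new("TemplateSpec",
      geneSeq = toupper(as.character(geneSeq)),
      codonPositions = as.integer(sort(codonPositions)),
      barcodeLength = as.integer(barcodeLength),
      spacerRange = as.integer(spacerRange),
      barcodeMap = barcodeMap,
      anchorLength = as.integer(anchorLength))
}

#' @describeIn TemplateSpec-class Wild-type gene nucleotide sequence.
#' @param object,x A `TemplateSpec`.
#' @export
geneSeq <- function(x) x@geneSeq

#' @describeIn TemplateSpec-class Indices of the randomised codons.
#' @export
codonPositions <- function(x) x@codonPositions

#' @describeIn TemplateSpec-class Number of codons in the gene.
#' @export
nCodons <- function(x) nchar(x@geneSeq) %/% 3L

#' @describeIn TemplateSpec-class Translated wild-type protein sequence.
#' @export
wtProtein <- function(x) {
  paste(translateCodons(codonMatrix(x@geneSeq, nCodons(x))[1, ]),
        collapse = "")
}

#' @describeIn TemplateSpec-class Wild-type residues at the randomised
#'   positions, as a 3-letter triplet.
#' @export
wtTriplet <- function(x) {
  paste(strsplit(wtProtein(x), "")[[1]][x@codonPositions], collapse = "")
}

#' @describeIn TemplateSpec-class Barcode-to-sample map.
#' @export
barcodeMap <- function(x) x@barcodeMap

setMethod("show", "TemplateSpec", function(object) {
  cat("TemplateSpec:", nCodons(object), "codons,",
      "randomised at", paste(object@codonPositions, collapse = "/"),
      paste0("(wild type ", wtTriplet(object), ")\n"))
  cat("  barcode length", object@barcodeLength,
      "| spacer", paste(object@spacerRange, collapse = "-"), "nt |",
      length(object@barcodeMap), "samples mapped\n")
})

#' A synthetic example template
#'
#' A deterministic, synthetic 94-codon gene (not a natural sequence) whose
#' randomised codons sit at codon positions 61, 64 and 80 with wild-type
#' residues D, K, E — mirroring the geometry of a three-position antitoxin
#' interface library. Useful for examples, tests and simulation.
#'
#' @param barcodeMap Optional barcode map; default none.
#' @return A [TemplateSpec-class] object.
#' @export
exampleTemplate <- function(barcodeMap = character()) {
  aa20 <- setdiff(aaAlphabet(), "*")
  prot <- c("M", rep(aa20, length.out = 93L))
  prot[c(61L, 64L, 80L)] <- c("D", "K", "E")
  # deterministic reverse translation: first NNK codon of each residue
  syn <- nnkSynonyms()
  gene <- paste(vapply(prot, function(a) syn[[a]][1], ""), collapse = "")
  TemplateSpec(gene, c(61L, 64L, 80L), barcodeMap = barcodeMap)
}
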