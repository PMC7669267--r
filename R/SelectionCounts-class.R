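#' SelectionCounts: variant read counts across selection samples
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' `"reads"` assay of non-negative integer counts, rows = library variants
#' (codon- or protein-level), columns = samples. Column data must carry
#' `sample_id`, `toxin`, `replicate` and `timepoint` (`"pre"`/`"post"`);
#' row data carries `aa_triplet` and, at codon level, `codon_triplet`.
#' `metadata()$level` records the counting level.
#'
#' @export
setClass("SelectionCounts", contains = "SummarizedExperiment")

setValidity("SelectionCounts", function(object) {
  msg <- character()
  if (!"reads" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "missing 'reads' assay")
  else {
    m <- SummarizedExperiment::assay(object, "reads")
    if (any(m < 0) || any(m != round(m)))
      msg <- c(msg, "'reads' must be non-negative integers")
  }
  need <- c("sample_id", "toxin", "replicate", "timepoint")
  if (!all(need %in% colnames(SummarizedExperiment::colData(object))))
    msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
  else if (!all(object$timepoint %in% c("pre", "post")))
    msg <- c(msg, "timepoint must be 'pre' or 'post'")
  if (!"aa_triplet" %in% colnames(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData must contain aa_triplet")
  lev <- S4Vectors::metadata(object)$level
  if (is.null(lev) || !lev %in% c("codon", "protein"))
    msg <- c(msg, "metadata()$level must be 'codon' or 'protein'")
  if (length(msg)) msg else TRUE
})

#' Construct a SelectionCounts object
#'
#' @param counts Integer matrix, variants x samples. Rownames are codon
#'   triplets (9-nt strings) at codon level or amino-acid triplets at
#'   protein level.
#' @param sampleInfo `data.frame` with one row per column of `counts` and
#'   columns `sample_id`, `toxin`, `replicate`, `timepoint`.
#' @param level `"codon"` or `"protein"`.
#' @param aaTriplet Amino-acid triplet per row; derived from rownames when
#'   `level = "codon"` if omitted.
#' @param reference Reference (wild-type) triplet stored in metadata,
#'   default `"DKE"`.
#' @return A [SelectionCounts-class] object.
#' @export
#' @examples
#' m <- matrix(c(10L, 5L, 20L, 2L), 2,
#'             dimnames = list(c("DKE", "ILK"), c("s1", "s2")))
#' si <- data.frame(sample_id = c("s1", "s2"), toxin = "E3",
#'                  replicate = 1L, timepoint = c("pre", "post"))
#' sc <- SelectionCounts(m, si, level = "protein")
SelectionCounts <- function(counts, sampleInfo, level = c("protein", "codon"),
                            aaTriplet = NULL, reference = "DKE") {
  level <- match.arg(level)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(aaTriplet)) {
    aaTriplet <- if (level == "codon") {
      vapply(rownames(counts), function(s)
        paste(translateCodons(substring(s, c(1, 4, 7), c(3, 6, 9))),
              collapse = ""), "")
    } else rownames(counts)
  }
  rd <- S4Vectors::DataFrame(aa_triplet = unname(aaTriplet))
  if (level == "codon") rd$codon_triplet <- rownames(counts)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(reads = counts),
    rowData = rd,
    colData = S4Vectors::DataFrame(sampleInfo, row.names = colnames(counts)))
  S4Vectors::metadata(se)$level <- level
  S4Vectors::metadata(se)$reference <- reference
  new("SelectionCounts", se)
}

#' @describeIn SelectionCounts-class Count matrix accessor.
#' @param x,object A `SelectionCounts`.
#' @export
readCountMatrix <- function(x) SummarizedExperiment::assay(x, "reads")

#' @describeIn SelectionCounts-class Counting level (`"codon"` or
#'   `"protein"`).
#' @export
countLevel <- function(x) S4Vectors::metadata(x)$level

#' @describeIn SelectionCounts-class Per-sample total read counts.
#' @export
sampleTotals <- function(x) colSums(readCountMatrix(x))

setMethod("show", "SelectionCounts", function(object) {
  cat("SelectionCounts:", nrow(object), paste0(countLevel(object), "-level"),
      "variants x", ncol(object), "samples\n")
  cat("  toxins:", paste(unique(object$toxin), collapse = ", "),
      "| replicates:", paste(unique(object$replicate), collapse = ", "), "\n")
  cat("  total reads per sample:",
      paste(format(sampleTotals(object), big.mark = ","), collapse = ", "),
      "\n")
})

#' Collapse codon-level counts to protein level
#'
#' Sums counts over the NNK codon spellings of each amino-acid triplet.
#' The grand total per sample is conserved. Protein-level input is returned
#' unchanged.
#'
#' @param x A [SelectionCounts-class] object.
#' @return A protein-level [SelectionCounts-class] object.
#' @export
aggregateToProtein <- function(x) {
  stopifnot(is(x, "SelectionCounts"))
  if (countLevel(x) == "protein") return(x)
  aa <- SummarizedExperiment::rowData(x)$aa_triplet
  m <- rowsum(readCountMatrix(x), group = aa)
  si <- as.data.frame(SummarizedExperiment::colData(x))
  out <- SelectionCounts(m, si, level = "protein",
                         reference = S4Vectors::metadata(x)$reference)
  keep <- setdiff(names(S4Vectors::metadata(x)), c("level", "reference"))
  for (k in keep)
    S4Vectors::metadata(out)[[k]] <- S4Vectors::metadata(x)[[k]]
  out
}
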