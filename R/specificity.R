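# Joint two-toxin analysis: specificity gap, interaction classes,
# neutralizer tallies, position frequency matrices.

#' Specificity gap
#'
#' Fitness against the cognate partner minus fitness against the
#' non-cognate partner; a wider gap means stronger discrimination.
#'
#' @param wCognate,wNonCognate Numeric vectors of scaled fitness values.
#' @return `wCognate - wNonCognate` (`NA` where either is missing).
#' @export
#' @examples
#' specificityGap(1.0, -0.2)  # 1.2
specificityGap <- function(wCognate, wNonCognate) wCognate - wNonCognate

#' Classify the joint interaction phenotype
#'
#' Thresholded quadrants of (W_cognate, W_non-cognate): a variant above
#' threshold for one partner only is specific for it; above for both is
#' promiscuous; below for both is dead. The comparison is strict (`>`) by
#' default.
#'
#' @param wCognate,wNonCognate Numeric vectors.
#' @param threshold Fitness threshold, default 0.5.
#' @param labels Category labels, in the order cognate-specific,
#'   non-cognate-specific, promiscuous, dead.
#' @return Character vector of categories (`NA` where either fitness is
#'   missing).
#' @export
classifyInteraction <- function(wCognate, wNonCognate, threshold = 0.5,
                                labels = c("E3_specific", "E2_specific",
                                           "promiscuous", "dead")) {
  a <- wCognate > threshold
  b <- wNonCognate > threshold
  out <- rep(NA_character_, length(a))
  out[a & !b] <- labels[1]
  out[!a & b] <- labels[2]
  out[a & b] <- labels[3]
  out[!a & !b] <- labels[4]
  out
}

#' Joint specificity table for two selections
#'
#' Merges two [fitnessScores()] tables on variant, computes the specificity
#' gap and interaction category for variants measured in both.
#'
#' @param fitCognate,fitNonCognate Fitness tables for the cognate and
#'   non-cognate selections.
#' @param threshold Classification threshold, default 0.5.
#' @return `data.frame` with `aa_triplet`, `class`, `W_E3` (cognate),
#'   `W_E2` (non-cognate), `gap`, `category`.
#' @export
specificityTable <- function(fitCognate, fitNonCognate, threshold = 0.5) {
  a <- fitCognate[fitCognate$passed_filter, c("aa_triplet", "class",
                                              "W_combined")]
  b <- fitNonCognate[fitNonCognate$passed_filter, c("aa_triplet",
                                                    "W_combined")]
  names(a)[3] <- "W_E3"; names(b)[2] <- "W_E2"
  d <- merge(a, b, by = "aa_triplet")
  d$gap <- specificityGap(d$W_E3, d$W_E2)
  d$category <- classifyInteraction(d$W_E3, d$W_E2, threshold)
  rownames(d) <- d$aa_triplet
  d
}

#' Count neutralizing variants by mutation class
#'
#' Variants with fitness above the threshold, total and split by the
#' number of substitutions (1/2/3) relative to the wild type, with
#' fractions over the measured variants of each class. Stop-class variants
#' are excluded from the class split.
#'
#' @param fitness A [fitnessScores()] table (or any `data.frame` with
#'   `W_combined`, `class`, `passed_filter`).
#' @param threshold Fitness threshold, default 0.5 (strict `>`).
#' @return List with `total`, per-class counts `by_class`, measured-class
#'   sizes `measured`, and `fraction = by_class / measured`.
#' @export
neutralizerSummary <- function(fitness, threshold = 0.5) {
  f <- fitness[fitness$passed_filter & is.finite(fitness$W_combined), ]
  hit <- f$W_combined > threshold
  cls <- factor(f$class, levels = c("0", "1", "2", "3", "stop"))
  byClass <- table(cls[hit])
  measured <- table(cls)
  list(total = sum(hit & f$class != "stop"),
       by_class = as.integer(byClass[c("1", "2", "3")]),
       measured = as.integer(measured[c("1", "2", "3")]),
       fraction = as.numeric(byClass[c("1", "2", "3")]) /
         as.numeric(measured[c("1", "2", "3")]))
}

#' Position frequency matrix of a variant subset
#'
#' Residue frequencies at each randomised position over a set of variants
#' (e.g. all neutralizers of one toxin); each row (position) sums to 1.
#' Optionally weighted by a non-negative weight per variant (e.g. fitness).
#'
#' @param triplets Character vector of amino-acid triplets.
#' @param weights Optional non-negative weights, recycled to `triplets`.
#' @return 3 x 21 matrix, rows `pos1..pos3`, columns the library alphabet.
#' @export
positionFrequencyMatrix <- function(triplets, weights = NULL) {
  if (!length(triplets)) stop("empty variant subset")
  if (is.null(weights)) weights <- rep(1, length(triplets))
  if (any(weights < 0)) stop("weights must be non-negative")
  aa <- aaAlphabet()
  m <- matrix(0, 3L, length(aa), dimnames = list(paste0("pos", 1:3), aa))
  sp <- do.call(rbind, strsplit(triplets, ""))
  for (p in 1:3) {
    t <- tapply(weights, factor(sp[, p], levels = aa), sum, default = 0)
    m[p, ] <- t / sum(t)
  }
  m
}

#' Fraction of variants with a wider specificity gap than a reference
#'
#' Computed over variants with a defined gap, optionally excluding
#' proline-containing variants (prolines break the helices carrying the
#' library positions, so their effects reflect stability rather than
#' recognition). The comparison is strict.
#'
#' @param spec A [specificityTable()] result.
#' @param reference Reference triplet, default `"DKE"`.
#' @param excludeProline Drop variants containing `P`, default `TRUE`.
#' @return Fraction in `[0, 1]`.
#' @export
gapExceedanceFraction <- function(spec, reference = "DKE",
                                  excludeProline = TRUE) {
  refGap <- spec$gap[match(reference, spec$aa_triplet)]
  if (length(refGap) != 1L || is.na(refGap))
    stop("reference variant has no defined specificity gap")
  d <- spec[is.finite(spec$gap), ]
  if (excludeProline) d <- d[!grepl("P", d$aa_triplet, fixed = TRUE), ]
  mean(d$gap > refGap)
}
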