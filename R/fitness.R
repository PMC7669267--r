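# Fitness scoring from pre-/post-selection counts.
#
# Raw fitness is the log-fold expansion of a variant relative to the rest
# of the library; scaled fitness anchors the stop-codon class at W = 0 and
# a reference (wild-type or predicted-best) variant at W = 1.

#' ScalingConfig: anchoring rules for fitness scaling
#'
#' @slot stopStatistic `"median"` (default) or `"mean"`: the statistic of
#'   the stop-class raw fitness values mapped to W = 0.
#' @slot references Named character vector, toxin -> reference triplet
#'   mapped to W = 1 (default `c(E3 = "DKE", E2 = "ILK")`).
#' @slot logBase Base of the enrichment logarithm (default natural). Scaled
#'   fitness is invariant to this choice.
#' @slot minPre,minPost Strict lower bounds of the measurement filter
#'   (defaults 25 and 0: pass iff pre > 25 and post > 0, in every replicate).
#' @export
setClass("ScalingConfig",
  representation(stopStatistic = "character", references = "character",
                 logBase = "numeric", minPre = "numeric", minPost = "numeric"))

setValidity("ScalingConfig", function(object) {
  if (!object@stopStatistic %in% c("median", "mean"))
    return("stopStatistic must be 'median' or 'mean'")
  if (object@logBase <= 0 || object@logBase == 1)
    return("logBase must be positive and != 1")
  TRUE
})

#' @rdname ScalingConfig-class
#' @param stopStatistic,references,logBase,minPre,minPost See slots.
#' @return `scalingConfig()` returns a `ScalingConfig`.
#' @export
scalingConfig <- function(stopStatistic = "median",
                          references = c(E3 = "DKE", E2 = "ILK"),
                          logBase = exp(1), minPre = 25, minPost = 0) {
  new("ScalingConfig", stopStatistic = stopStatistic, references = references,
      logBase = logBase, minPre = minPre, minPost = minPost)
}

#' Measurement filter on pre/post read counts
#'
#' A variant is reliably measured when its pre-selection count exceeds
#' `minPre` and its post-selection count exceeds `minPost` (strict
#' inequalities; defaults 25 and 0).
#'
#' @param pre,post Integer count vectors.
#' @param minPre,minPost Strict lower bounds.
#' @return Logical vector.
#' @export
#' @examples
#' applyMeasurementFilter(c(25, 26, 1000), c(10, 1, 0))  # F T F
applyMeasurementFilter <- function(pre, post, minPre = 25, minPost = 0) {
  pre > minPre & post > minPost
}

#' Per-sample variant frequencies
#'
#' Counts normalised by the sample total; frequencies sum to 1 per sample.
#'
#' @param counts Numeric vector or matrix (variants x samples) of counts.
#' @return Object of the same shape holding frequencies.
#' @export
variantFrequencies <- function(counts) {
  if (is.matrix(counts)) {
    tot <- colSums(counts)
    if (any(tot == 0)) stop("sample with zero total reads")
    sweep(counts, 2L, tot, "/")
  } else {
    tot <- sum(counts)
    if (tot == 0) stop("sample with zero total reads")
    counts / tot
  }
}

#' Raw fitness: rest-of-library-normalised log enrichment
#'
#' `W_raw(i) = log[(f_post(i)/f_pre(i)) / (F_post(-i)/F_pre(-i))]`, where
#' `F(-i) = 1 - f(i)` is the summed frequency of all other variants. This
#' is the log-fold expansion of variant i relative to the remaining
#' library.
#'
#' @param preFreq,postFreq Frequency vectors over the same variants
#'   (each summing to 1 across the full sample).
#' @param logBase Log base (default natural).
#' @return Numeric vector of raw fitness values; `NA` where undefined
#'   (zero focal or rest-of-library frequency).
#' @export
#' @examples
#' # 3-variant toy: pre (100,100,100), post (400,100,100)
#' rawFitness(c(1, 1, 1)/3, c(4, 1, 1)/6)[1]  # log 4
rawFitness <- function(preFreq, postFreq, logBase = exp(1)) {
  ok <- preFreq > 0 & postFreq > 0 & preFreq < 1 & postFreq < 1
  w <- rep(NA_real_, length(preFreq))
  w[ok] <- (log(postFreq[ok] / preFreq[ok]) -
              log((1 - postFreq[ok]) / (1 - preFreq[ok]))) / log(logBase)
  w
}

#' Scale raw fitness to the stop/reference anchors
#'
#' Affine map `W = (W_raw - s0) / (s_ref - s0)` with `s0` the configured
#' statistic (median by default) of stop-class raw values and `s_ref` the
#' reference variant's raw value, so the stop class maps to 0 and the
#' reference to 1.
#'
#' @param wRaw Named or unnamed numeric vector of raw fitness values (`NA`
#'   for unmeasured variants).
#' @param stopClass Logical vector marking stop-containing variants.
#' @param referenceIdx Index (or name) of the reference variant in `wRaw`.
#' @param stopStatistic `"median"` or `"mean"`.
#' @return Numeric vector of scaled fitness values.
#' @export
scaleFitness <- function(wRaw, stopClass, referenceIdx,
                         stopStatistic = c("median", "mean")) {
  stopStatistic <- match.arg(stopStatistic)
  sRef <- unname(wRaw[referenceIdx])
  if (length(sRef) != 1L || is.na(sRef))
    stop("reference variant has no defined raw fitness")
  stops <- wRaw[stopClass & !is.na(wRaw)]
  if (length(stops) < 3L)
    stop("need at least 3 measured stop-class variants to anchor W = 0")
  s0 <- if (stopStatistic == "median") median(stops) else mean(stops)
  if (isTRUE(all.equal(sRef, s0)))
    stop("degenerate selection: reference and stop baseline coincide")
  (wRaw - s0) / (sRef - s0)
}

#' Combine replicate fitness values
#'
#' Combined fitness is the mean of per-replicate scaled values over
#' replicates in which the variant passes the measurement filter; the
#' cross-replicate R-squared (squared Pearson correlation) and regression
#' slope are computed over variants passing in both replicates.
#'
#' @param wMat Numeric matrix, variants x replicates, `NA` where a variant
#'   fails the filter in that replicate.
#' @param requireAll If `TRUE` (default) the combined value is reported
#'   only for variants passing in every replicate.
#' @return List with `combined` (numeric vector), `r_squared`, `slope`,
#'   `n_shared` (all between the first two replicates; `NA` when fewer
#'   than 2 shared variants).
#' @export
combineReplicates <- function(wMat, requireAll = TRUE) {
  wMat <- as.matrix(wMat)
  comb <- rowMeans(wMat, na.rm = !requireAll)
  if (!requireAll) comb[rowSums(is.finite(wMat)) == 0L] <- NA_real_
  r2 <- slope <- NA_real_
  nShared <- 0L
  if (ncol(wMat) >= 2L) {
    both <- is.finite(wMat[, 1L]) & is.finite(wMat[, 2L])
    nShared <- sum(both)
    if (nShared >= 2L && sd(wMat[both, 1L]) > 0 && sd(wMat[both, 2L]) > 0) {
      r <- cor(wMat[both, 1L], wMat[both, 2L])
      r2 <- r^2
      slope <- r * sd(wMat[both, 2L]) / sd(wMat[both, 1L])
    }
  }
  list(combined = comb, r_squared = r2, slope = slope, n_shared = nShared)
}

#' Fitness table for one toxin selection
#'
#' Runs the full scoring path for one toxin: per replicate, apply the
#' measurement filter, compute raw fitness from pre/post frequencies, scale
#' to the stop/reference anchors, then combine replicates. Replicates are
#' scaled independently (stops and the reference act as per-replicate
#' internal controls) and averaged.
#'
#' @param counts A protein-level [SelectionCounts-class] containing `pre`
#'   and `post` samples for the requested toxin (one pair per replicate).
#' @param toxin Toxin label to score (must appear in `counts$toxin`).
#' @param config A [ScalingConfig-class]; its `references` entry for
#'   `toxin` names the W = 1 anchor variant.
#' @return `data.frame` with one row per variant: `toxin`, `aa_triplet`,
#'   `class`, per-replicate `pre_reads_*`, `post_reads_*`, `W_raw_*`,
#'   `W_*`, plus `W_combined` and `passed_filter`. Replicate agreement
#'   statistics are attached as `attr(, "replicate_stats")`.
#' @export
fitnessScores <- function(counts, toxin, config = scalingConfig()) {
  stopifnot(is(counts, "SelectionCounts"))
  if (countLevel(counts) != "protein") counts <- aggregateToProtein(counts)
  cd <- as.data.frame(SummarizedExperiment::colData(counts))
  sel <- cd$toxin == toxin
  if (!any(sel)) stop("no samples for toxin ", toxin)
  reps <- sort(unique(cd$replicate[sel]))
  m <- readCountMatrix(counts)
  trip <- SummarizedExperiment::rowData(counts)$aa_triplet
  ref <- S4Vectors::metadata(counts)$reference
  refVariant <- if (toxin %in% names(config@references))
    config@references[[toxin]] else ref
  cls <- classifyVariant(trip, ref)
  isStop <- cls == "stop"
  refIdx <- match(refVariant, trip)
  if (is.na(refIdx)) stop("reference variant ", refVariant, " not in counts")

  out <- data.frame(toxin = toxin, aa_triplet = trip, class = cls,
                    stringsAsFactors = FALSE)
  wScaled <- matrix(NA_real_, nrow(out), length(reps))
  for (j in seq_along(reps)) {
    preCol <- which(sel & cd$replicate == reps[j] & cd$timepoint == "pre")
    postCol <- which(sel & cd$replicate == reps[j] & cd$timepoint == "post")
    if (length(preCol) != 1L || length(postCol) != 1L)
      stop("expected exactly one pre and one post sample for toxin ", toxin,
           " replicate ", reps[j])
    pre <- m[, preCol]; post <- m[, postCol]
    pass <- applyMeasurementFilter(pre, post, config@minPre, config@minPost)
    wRaw <- rep(NA_real_, length(pre))
    f <- variantFrequencies(cbind(pre, post))
    wRaw[pass] <- rawFitness(f[, 1L], f[, 2L], config@logBase)[pass]
    w <- scaleFitness(wRaw, isStop, refIdx, config@stopStatistic)
    wScaled[, j] <- w
    out[[paste0("pre_reads_", reps[j])]] <- pre
    out[[paste0("post_reads_", reps[j])]] <- post
    out[[paste0("W_raw_", reps[j])]] <- wRaw
    out[[paste0("W_", reps[j])]] <- w
  }
  comb <- combineReplicates(wScaled, requireAll = TRUE)
  out$passed_filter <- rowSums(is.na(wScaled)) == 0L
  out$W_combined <- ifelse(out$passed_filter, comb$combined, NA_real_)
  rownames(out) <- out$aa_triplet
  attr(out, "replicate_stats") <- comb[c("r_squared", "slope", "n_shared")]
  out
}

#' Named combined-fitness vector from a fitness table
#'
#' @param fitness A [fitnessScores()] table.
#' @return Named numeric vector of `W_combined` over variants passing the
#'   filter.
#' @export
fitnessVector <- function(fitness) {
  keep <- fitness$passed_filter & is.finite(fitness$W_combined)
  setNames(fitness$W_combined[keep], fitness$aa_triplet[keep])
}
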