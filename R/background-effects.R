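# Background-resolved substitution effects: for a substitution X -> Y at a
# library position, the distribution of fitness changes dW = W(Y, bg) -
# W(X, bg) over all genetic backgrounds bg at the other positions,
# summarised by the mode of a maximum-likelihood skew-normal fit, with
# significance calibrated against a label-shuffling permutation null.

backgroundAlphabet <- function(excludedAas = "P") {
  setdiff(setdiff(aaAlphabet(), "*"), excludedAas)
}

# Variant names for focal residue 'aa' at 'position' across a background
# grid; bg is a 2-column matrix of residues at the other two positions in
# ascending position order.
.variantNames <- function(position, aa, bg) {
  v <- matrix("", nrow(bg), 3L)
  v[, position] <- aa
  v[, setdiff(1:3, position)] <- bg
  paste0(v[, 1], v[, 2], v[, 3])
}

# Integer-indexed lookup engine: for one position, a (focal aa) x
# (background) matrix of match indices into names(W).
.positionIndex <- function(position, wNames, excludedAas = "P") {
  aa <- backgroundAlphabet(excludedAas)
  bgGrid <- as.matrix(expand.grid(a = aa, b = aa, stringsAsFactors = FALSE,
                                  KEEP.OUT.ATTRS = FALSE))
  idx <- vapply(aa, function(f)
    match(.variantNames(position, f, bgGrid), wNames),
    integer(nrow(bgGrid)))
  t(idx)  # rows = focal residues, cols = backgrounds
}

#' Per-background fitness changes for one substitution
#'
#' For substitution `fromAa -> toAa` at `position`, computes
#' `dW(bg) = W(toAa, bg) - W(fromAa, bg)` over every background `bg` of
#' residues at the other two positions, keeping backgrounds where both
#' flanking variants are measured. With one excluded residue (proline by
#' default) a complete fitness table yields 19 x 19 = 361 backgrounds; with
#' none, 400.
#'
#' @param position Library position, 1-3.
#' @param fromAa,toAa Original and substituted residue (distinct, neither
#'   excluded).
#' @param fitness Named numeric vector of combined fitness values (names
#'   are amino-acid triplets), e.g. from [fitnessVector()].
#' @param excludedAas Residues excluded both as focal residues and in
#'   backgrounds; default `"P"`.
#' @param flipSign If `TRUE`, report original-minus-mutant instead.
#' @return List with `position`, `from_aa`, `to_aa`, `delta_w` (named by
#'   background), `n_backgrounds`.
#' @export
deltaWProfile <- function(position, fromAa, toAa, fitness,
                          excludedAas = "P", flipSign = FALSE) {
  if (fromAa == toAa) stop("fromAa and toAa must differ")
  if (any(c(fromAa, toAa) %in% excludedAas))
    stop("focal residues must not be excluded residues")
  aa <- backgroundAlphabet(excludedAas)
  bgGrid <- as.matrix(expand.grid(a = aa, b = aa, stringsAsFactors = FALSE,
                                  KEEP.OUT.ATTRS = FALSE))
  wFrom <- fitness[.variantNames(position, fromAa, bgGrid)]
  wTo <- fitness[.variantNames(position, toAa, bgGrid)]
  d <- unname(wTo) - unname(wFrom)
  if (flipSign) d <- -d
  names(d) <- paste0(bgGrid[, 1], bgGrid[, 2])
  d <- d[is.finite(d)]
  if (!length(d)) warning("no measured backgrounds for ", fromAa, position,
                          toAa)
  list(position = position, from_aa = fromAa, to_aa = toAa,
       delta_w = d, n_backgrounds = length(d))
}

#' Summarise a substitution-effect profile
#'
#' The mode comes from the maximum-likelihood skew-normal fit; mean,
#' median and interquartile range are empirical. If the fit fails the mode
#' is `NA` and empirical summaries are still returned.
#'
#' @param deltaW Numeric vector of per-background fitness changes (or a
#'   [deltaWProfile()] result).
#' @param minN Minimum profile size for fitting, default 20.
#' @return List with `mode`, `xi`, `omega`, `alpha`, `mean`, `median`,
#'   `iqr`, `n`, `converged`.
#' @export
summarizeEffect <- function(deltaW, minN = 20L) {
  if (is.list(deltaW)) deltaW <- deltaW$delta_w
  x <- deltaW[is.finite(deltaW)]
  if (!length(x)) stop("empty profile")
  fit <- fitSkewNormal(x, minN = minN)
  list(mode = fit$mode, xi = fit$xi, omega = fit$omega, alpha = fit$alpha,
       mean = mean(x), median = median(x),
       iqr = unname(diff(quantile(x, c(0.25, 0.75)))),
       n = length(x), converged = fit$converged)
}

# Core engine: skew-normal summaries for a set of substitutions, computed
# once per unordered pair and mirrored (the ML fit of a reflected sample is
# the reflected fit, so modes negate exactly, means/medians negate, IQR is
# unchanged).
.effectsEngine <- function(w, substitutions, excludedAas = "P", minN = 20L,
                           idxCache = NULL) {
  wNames <- names(w)
  vals <- unname(w)
  positions <- sort(unique(substitutions$position))
  if (is.null(idxCache))
    idxCache <- lapply(setNames(positions, positions), .positionIndex,
                       wNames = wNames, excludedAas = excludedAas)
  key <- with(substitutions,
              paste(position, pmin(from_aa, to_aa), pmax(from_aa, to_aa)))
  out <- substitutions
  cols <- c("n_backgrounds", "xi", "omega", "alpha", "mode", "mean",
            "median", "iqr")
  for (cc in cols) out[[cc]] <- NA_real_
  out$converged <- FALSE
  done <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(out))) {
    p <- out$position[i]; f <- out$from_aa[i]; t <- out$to_aa[i]
    cached <- get0(key[i], envir = done)
    if (is.null(cached)) {
      idx <- idxCache[[as.character(p)]]
      lo <- min(f, t); hi <- max(f, t)
      d <- vals[idx[hi, ]] - vals[idx[lo, ]]
      d <- d[is.finite(d)]
      s <- if (length(d)) summarizeEffect(d, minN = minN) else
        list(mode = NA_real_, xi = NA_real_, omega = NA_real_,
             alpha = NA_real_, mean = NA_real_, median = NA_real_,
             iqr = NA_real_, n = 0L, converged = FALSE)
      cached <- s
      assign(key[i], s, envir = done)
    }
    s <- cached
    sgn <- if (out$from_aa[i] <= out$to_aa[i]) 1 else -1
    out$n_backgrounds[i] <- s$n
    out$xi[i] <- sgn * s$xi
    out$omega[i] <- s$omega
    out$alpha[i] <- sgn * s$alpha
    out$mode[i] <- sgn * s$mode
    out$mean[i] <- sgn * s$mean
    out$median[i] <- sgn * s$median
    out$iqr[i] <- s$iqr
    out$converged[i] <- s$converged
  }
  out
}

#' Substitutions from the wild-type residue at each position
#'
#' @param reference Reference triplet, default `"DKE"`.
#' @param excludedAas Excluded residues, default `"P"`.
#' @return `data.frame` with columns `position`, `from_aa`, `to_aa`.
#' @export
wtSubstitutions <- function(reference = "DKE", excludedAas = "P") {
  ref <- strsplit(reference, "")[[1]]
  do.call(rbind, lapply(1:3, function(p) {
    to <- setdiff(backgroundAlphabet(excludedAas), ref[p])
    data.frame(position = p, from_aa = ref[p], to_aa = to,
               stringsAsFactors = FALSE)
  }))
}

#' All ordered substitution pairs at each position
#'
#' @inheritParams wtSubstitutions
#' @param positions Positions to enumerate, default 1:3.
#' @return `data.frame` with columns `position`, `from_aa`, `to_aa`.
#' @export
allSubstitutions <- function(positions = 1:3, excludedAas = "P") {
  aa <- backgroundAlphabet(excludedAas)
  do.call(rbind, lapply(positions, function(p) {
    g <- expand.grid(to_aa = aa, from_aa = aa, stringsAsFactors = FALSE)
    g <- g[g$from_aa != g$to_aa, c("from_aa", "to_aa")]
    data.frame(position = p, g, stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Background-resolved effects for a set of substitutions
#'
#' Computes the dW profile and its skew-normal summary for every requested
#' substitution. Antisymmetric pairs are fitted once and mirrored, since
#' the ML fit of a negated sample is exactly the negated fit.
#'
#' @param fitness Named combined-fitness vector (see [fitnessVector()]).
#' @param substitutions `data.frame` with `position`, `from_aa`, `to_aa`;
#'   default [wtSubstitutions()].
#' @param excludedAas Excluded residues, default `"P"`.
#' @param minN Minimum profile size for fitting, default 20.
#' @return `data.frame` with one row per substitution and columns
#'   `position`, `from_aa`, `to_aa`, `n_backgrounds`, `xi`, `omega`,
#'   `alpha`, `mode`, `mean`, `median`, `iqr`, `converged`.
#' @export
substitutionEffects <- function(fitness, substitutions = wtSubstitutions(),
                                excludedAas = "P", minN = 20L) {
  .effectsEngine(fitness, substitutions, excludedAas, minN)
}

#' Permutation null for substitution-effect modes
#'
#' Generates the null distribution of modes by shuffling fitness values
#' across variant labels and recomputing the mode of every requested
#' substitution cell; all null modes are pooled and the 5th/95th
#' percentiles serve as two-sided significance cutoffs.
#'
#' @inheritParams substitutionEffects
#' @param n Number of permutations, default 1000.
#' @param seed Random seed for the shuffles.
#' @return List with `null_modes` (numeric vector, pooled), `lower`,
#'   `upper` (5%/95% cutoffs), `n`, `seed`.
#' @export
permutationNull <- function(fitness, substitutions = wtSubstitutions(),
                            n = 1000L, seed = 1L, excludedAas = "P",
                            minN = 20L) {
  set.seed(seed)
  wNames <- names(fitness)
  positions <- sort(unique(substitutions$position))
  idxCache <- lapply(setNames(positions, positions), .positionIndex,
                     wNames = wNames, excludedAas = excludedAas)
  pool <- vector("list", n)
  for (b in seq_len(n)) {
    wp <- setNames(sample(unname(fitness)), wNames)
    eff <- .effectsEngine(wp, substitutions, excludedAas, minN,
                          idxCache = idxCache)
    pool[[b]] <- eff$mode
  }
  nullModes <- unlist(pool)
  nullModes <- nullModes[is.finite(nullModes)]
  qs <- quantile(nullModes, c(0.05, 0.95), names = FALSE)
  list(null_modes = nullModes, lower = qs[1], upper = qs[2],
       n = n, seed = seed)
}

#' Label substitution modes against a permutation null
#'
#' @param effects A [substitutionEffects()] table.
#' @param null A [permutationNull()] result.
#' @return `effects` with a `significance` column in
#'   `{"negative", "none", "positive"}` (`NA` when the mode is missing).
#' @export
significanceCalls <- function(effects, null) {
  sig <- rep(NA_character_, nrow(effects))
  m <- effects$mode
  sig[is.finite(m)] <- "none"
  sig[is.finite(m) & m < null$lower] <- "negative"
  sig[is.finite(m) & m > null$upper] <- "positive"
  effects$significance <- sig
  effects
}

#' Joint mode-shift coordinates for cognate and non-cognate selections
#'
#' Places each substitution on a (cognate, non-cognate) fitness diagram
#' with the wild type at (1, -1): coordinates are
#' `(1 + mode_cognate, -1 + mode_noncognate)`.
#'
#' @param effectsCognate,effectsNonCognate [substitutionEffects()] tables
#'   for the two selections (matched on position/from/to).
#' @return `data.frame` with `position`, `from_aa`, `to_aa`, `w_cognate`,
#'   `w_noncognate`; substitutions missing a mode on either side are
#'   omitted.
#' @export
modeShiftSummary <- function(effectsCognate, effectsNonCognate) {
  keyA <- with(effectsCognate, paste(position, from_aa, to_aa))
  keyB <- with(effectsNonCognate, paste(position, from_aa, to_aa))
  common <- intersect(keyA, keyB)
  a <- effectsCognate[match(common, keyA), ]
  b <- effectsNonCognate[match(common, keyB), ]
  out <- data.frame(position = a$position, from_aa = a$from_aa,
                    to_aa = a$to_aa,
                    w_cognate = 1 + a$mode,
                    w_noncognate = -1 + b$mode,
                    stringsAsFactors = FALSE)
  out[is.finite(out$w_cognate) & is.finite(out$w_noncognate), ]
}

#' Position-wise comparison against the wild-type residue's distribution
#'
#' An alternative to paired dW profiles: the fitness distribution of all
#' variants carrying `aa` at `position` is compared (unpaired) to the
#' distribution of variants carrying the wild-type residue there, as the
#' difference of skew-normal modes.
#'
#' @inheritParams deltaWProfile
#' @param aa Focal residue.
#' @param reference Reference triplet supplying the wild-type residue.
#' @param minN Minimum sample size per fit.
#' @return List with `shift` (mode difference), `mode_aa`, `mode_wt`,
#'   `n_aa`, `n_wt`.
#' @export
positionwiseWtComparison <- function(position, aa, fitness,
                                     reference = "DKE", excludedAas = "P",
                                     minN = 20L) {
  if (aa %in% excludedAas) stop("focal residue is excluded")
  wtAa <- strsplit(reference, "")[[1]][position]
  bgAa <- backgroundAlphabet(excludedAas)
  bgGrid <- as.matrix(expand.grid(a = bgAa, b = bgAa,
                                  stringsAsFactors = FALSE,
                                  KEEP.OUT.ATTRS = FALSE))
  wAa <- fitness[.variantNames(position, aa, bgGrid)]
  wWt <- fitness[.variantNames(position, wtAa, bgGrid)]
  wAa <- wAa[is.finite(wAa)]; wWt <- wWt[is.finite(wWt)]
  fa <- fitSkewNormal(wAa, minN = minN)
  fw <- fitSkewNormal(wWt, minN = minN)
  list(shift = fa$mode - fw$mode, mode_aa = fa$mode, mode_wt = fw$mode,
       n_aa = length(wAa), n_wt = length(wWt))
}
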