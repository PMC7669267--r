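# Additive (independent-residue) fitness model with k-fold cross-validation,
# and epistasis as observed-minus-additive residuals.

#' Indicator design matrix for the additive model
#'
#' One indicator column per (position, residue), excluding the per-position
#' reference residue (reference-cell encoding), plus an intercept. The
#' reference triplet's row is all zeros apart from the intercept.
#'
#' @param triplets Stop-free amino-acid triplets.
#' @param reference Reference triplet whose residues are absorbed into the
#'   intercept, default `"DKE"`.
#' @return Numeric matrix with `3 * 19 + 1` columns (intercept first) for
#'   the 20-residue alphabet.
#' @export
buildDesignMatrix <- function(triplets, reference = "DKE") {
  sp <- do.call(rbind, strsplit(triplets, ""))
  if (any(sp == "*")) stop("stop-containing variants are not modelled")
  aa20 <- setdiff(aaAlphabet(), "*")
  if (any(!sp %in% aa20)) stop("unknown residue symbol in triplets")
  ref <- strsplit(reference, "")[[1]]
  blocks <- lapply(1:3, function(p) {
    lev <- c(ref[p], setdiff(aa20, ref[p]))
    m <- 0 + outer(sp[, p], lev[-1], "==")
    colnames(m) <- paste0("pos", p, ".", lev[-1])
    m
  })
  X <- cbind(`(Intercept)` = 1, do.call(cbind, blocks))
  rownames(X) <- triplets
  X
}

#' Fit the additive model with k-fold cross-validation
#'
#' Ordinary least squares of combined fitness on per-position residue
#' indicators. Variants are assigned to `k` folds by a seeded random
#' permutation (fold sizes differ by at most one); each fold is held out
#' once and R-squared is computed on the held-out variants
#' (`1 - SSE/SST`, SST about the held-out mean). Final coefficients and
#' their standard errors come from a fit on all data.
#'
#' @param fitness Named combined-fitness vector ([fitnessVector()]) or a
#'   [fitnessScores()] table; stop-containing variants are dropped.
#' @param k Number of folds, default 5.
#' @param seed Seed for fold assignment.
#' @param reference Reference triplet for the encoding, default `"DKE"`.
#' @return List of class `"additiveFit"`: `coefficients`, `se`,
#'   `fold_r_squared` (length `k`), `mean_r_squared`, `sd_r_squared`,
#'   `k`, `seed`, `n`, `reference`.
#' @export
fitAdditiveCV <- function(fitness, k = 5L, seed = 1L, reference = "DKE") {
  if (is.data.frame(fitness)) fitness <- fitnessVector(fitness)
  fitness <- fitness[!grepl("*", names(fitness), fixed = TRUE)]
  fitness <- fitness[is.finite(fitness)]
  X <- buildDesignMatrix(names(fitness), reference)
  y <- unname(fitness)
  n <- length(y)
  if (n < 10 * ncol(X))
    warning("fewer than 10 variants per coefficient; estimates may be unstable")
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  r2 <- numeric(k)
  for (j in seq_len(k)) {
    tr <- fold != j
    fit <- lm.fit(X[tr, , drop = FALSE], y[tr])
    if (any(is.na(fit$coefficients)))
      stop("rank-deficient design; unidentifiable coefficients: ",
           paste(names(fit$coefficients)[is.na(fit$coefficients)],
                 collapse = ", "))
    pred <- X[!tr, , drop = FALSE] %*% fit$coefficients
    sse <- sum((y[!tr] - pred)^2)
    sst <- sum((y[!tr] - mean(y[!tr]))^2)
    r2[j] <- 1 - sse / sst
  }
  full <- lm.fit(X, y)
  resid <- y - X %*% full$coefficients
  dfres <- n - ncol(X)
  sigma2 <- sum(resid^2) / dfres
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * diag(XtXinv))
  names(se) <- colnames(X)
  structure(list(coefficients = setNames(full$coefficients, colnames(X)),
                 se = se, fold_r_squared = r2,
                 mean_r_squared = mean(r2), sd_r_squared = sd(r2),
                 k = k, seed = seed, n = n, reference = reference),
            class = "additiveFit")
}

#' @export
print.additiveFit <- function(x, ...) {
  cat("Additive fitness model:", x$n, "variants,",
      length(x$coefficients), "coefficients\n")
  cat(sprintf("  held-out R^2 (k = %d folds): %.4f (SD %.4f)\n",
              x$k, x$mean_r_squared, x$sd_r_squared))
  invisible(x)
}

#' Epistasis residuals relative to an additive single-mutant prediction
#'
#' For every double and triple mutant relative to the reference, the
#' additive prediction is `W_ref + sum_p [W(single mutant at p) - W_ref]`
#' over its mutated positions; the residual is observed minus predicted.
#' Variants whose constituent single mutants are unmeasured are skipped
#' and counted.
#'
#' @inheritParams fitAdditiveCV
#' @param reference Reference triplet, default `"DKE"`.
#' @return List with `residuals` (`data.frame`: `aa_triplet`, `n_mutations`,
#'   `observed`, `predicted`, `residual`) and `n_skipped`.
#' @export
epistasisResiduals <- function(fitness, reference = "DKE") {
  if (is.data.frame(fitness)) fitness <- fitnessVector(fitness)
  fitness <- fitness[!grepl("*", names(fitness), fixed = TRUE) &
                       is.finite(fitness)]
  ref <- strsplit(reference, "")[[1]]
  wRef <- unname(fitness[reference])
  if (!is.finite(wRef)) stop("reference variant has no measured fitness")
  sp <- do.call(rbind, strsplit(names(fitness), ""))
  mut <- sp != matrix(ref, nrow(sp), 3L, byrow = TRUE)
  nm <- rowSums(mut)
  multi <- which(nm >= 2L)
  # single-mutant fitness lookup, positions x residues, wild-type background
  aa20 <- setdiff(aaAlphabet(), "*")
  singles <- vapply(aa20, function(aa) vapply(1:3, function(p) {
    v <- ref; v[p] <- aa
    w <- fitness[paste(v, collapse = "")]
    if (length(w)) unname(w) else NA_real_
  }, 0), numeric(3L))
  contrib <- vapply(1:3, function(p)
    ifelse(mut[multi, p], singles[p, sp[multi, p]] - wRef, 0),
    numeric(length(multi)))
  pred <- wRef + rowSums(contrib)
  ok <- is.finite(pred)
  res <- data.frame(aa_triplet = names(fitness)[multi][ok],
                    n_mutations = nm[multi][ok],
                    observed = unname(fitness[multi])[ok],
                    predicted = pred[ok],
                    stringsAsFactors = FALSE)
  res$residual <- res$observed - res$predicted
  list(residuals = res, n_skipped = sum(!ok))
}
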