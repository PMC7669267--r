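# Additive model, cross-validation, epistasis residuals.

test_that("design matrix uses reference-cell encoding", {
  X <- buildDesignMatrix(c("DKE", "ILK", "AKE"), reference = "DKE")
  expect_equal(ncol(X), 3 * 19 + 1)
  expect_equal(unname(X["DKE", ]), c(1, rep(0, 57)))  # reference row
  expect_equal(sum(X["ILK", -1]), 3)  # triple mutant: 3 indicators
  expect_equal(sum(X["AKE", -1]), 1)
  expect_equal(unname(X["AKE", "pos1.A"]), 1)
  expect_error(buildDesignMatrix("DK*"), "stop")
  expect_error(buildDesignMatrix("DKB"), "unknown residue")
})

test_that("noise-free additive landscapes give held-out R^2 of 1", {
  set.seed(21)
  ls <- generateTrueLandscape(simConfig(noiseSD = 0, fitnessFloor = -Inf),
                              "DKE")
  w <- ls$trueW[classifyVariant(names(ls$trueW), "DKE") != "stop"]
  fit <- fitAdditiveCV(w, k = 5, seed = 3)
  expect_true(all(fit$fold_r_squared > 1 - 1e-9))
  # recovered coefficients equal the generating ones
  for (p in 1:3) {
    aa <- setdiff(colnames(ls$coefficients), strsplit("DKE", "")[[1]][p])
    est <- fit$coefficients[paste0("pos", p, ".", aa)]
    expect_equal(unname(est), unname(ls$coefficients[p, aa]),
                 tolerance = 1e-8)
  }
})

test_that("folds partition the variants with near-equal sizes", {
  set.seed(22)
  w <- generateTrueLandscape(simConfig(noiseSD = 0.1, fitnessFloor = -Inf),
                             "DKE")$trueW
  w <- w[classifyVariant(names(w), "DKE") != "stop"]
  # reproduce the internal fold assignment contract
  n <- length(w)
  set.seed(17)
  fold <- sample(rep(seq_len(5), length.out = n))
  expect_equal(sum(table(fold)), n)
  expect_lte(diff(range(table(fold))), 1)
  # same seed, same folds, same result
  f1 <- fitAdditiveCV(w, seed = 17)
  f2 <- fitAdditiveCV(w, seed = 17)
  expect_equal(f1$fold_r_squared, f2$fold_r_squared)
})

test_that("coefficients are recovered within standard error under noise", {
  set.seed(23)
  ls <- generateTrueLandscape(simConfig(noiseSD = 0.1, fitnessFloor = -Inf),
                              "DKE")
  w <- ls$trueW[classifyVariant(names(ls$trueW), "DKE") != "stop"]
  fit <- fitAdditiveCV(w, seed = 5)
  z <- c()
  for (p in 1:3) {
    aa <- setdiff(colnames(ls$coefficients), strsplit("DKE", "")[[1]][p])
    nm <- paste0("pos", p, ".", aa)
    z <- c(z, (fit$coefficients[nm] - ls$coefficients[p, aa]) / fit$se[nm])
  }
  expect_lt(max(abs(z)), 4)          # each within 4 SE
  expect_gt(mean(abs(z) <= 3), 0.98) # and nearly all within 3 SE
})

test_that("epistasis residuals vanish on additive data and expose
          an injected pairwise term", {
  set.seed(24)
  ls <- generateTrueLandscape(simConfig(noiseSD = 0, fitnessFloor = -Inf),
                              "DKE")
  w <- ls$trueW[classifyVariant(names(ls$trueW), "DKE") != "stop"]
  er <- epistasisResiduals(w, "DKE")
  expect_lt(max(abs(er$residuals$residual)), 1e-9)
  expect_setequal(unique(er$residuals$n_mutations), c(2L, 3L))
  # inject a single pairwise term on (pos1 = A, pos2 = C)
  eps <- 0.4
  w2 <- w
  hit <- substr(names(w2), 1, 1) == "A" & substr(names(w2), 2, 2) == "C"
  w2[hit] <- w2[hit] + eps
  er2 <- epistasisResiduals(w2, "DKE")
  r <- er2$residuals
  affected <- substr(r$aa_triplet, 1, 1) == "A" &
    substr(r$aa_triplet, 2, 2) == "C"
  expect_equal(unique(round(r$residual[affected], 9)), eps)
  expect_lt(max(abs(r$residual[!affected])), 1e-9)
  # missing constituent single mutants are skipped and counted
  er3 <- epistasisResiduals(w[names(w) != "AKE"], "DKE")
  expect_gt(er3$n_skipped, 0)
})

test_that("the generator's epistasis terms are recovered end to end", {
  set.seed(25)
  cfg <- simConfig(noiseSD = 0, fitnessFloor = -Inf,
                   epistasisFraction = 0.02, epistasisSD = 0.3)
  ls <- generateTrueLandscape(cfg, "DKE")
  w <- ls$trueW[classifyVariant(names(ls$trueW), "DKE") != "stop"]
  er <- epistasisResiduals(w, "DKE")
  epi <- ls$epistasis
  expect_gt(nrow(epi), 0)
  # independent oracle: residual(v) = T(v) - sum_singles T(s) +
  # (mutations - 1) * T(ref), with T(x) the summed injected terms active
  # in x (noise-free, so everything else cancels)
  termSum <- function(trip) {
    v <- strsplit(trip, "")[[1]]
    active <- v[epi$pos_a] == epi$aa_a & v[epi$pos_b] == epi$aa_b
    sum(epi$term[active])
  }
  ref <- strsplit("DKE", "")[[1]]
  set.seed(26)
  pick <- sample(nrow(er$residuals), 25)
  for (i in pick) {
    trip <- er$residuals$aa_triplet[i]
    v <- strsplit(trip, "")[[1]]
    mut <- which(v != ref)
    singles <- vapply(mut, function(p) {
      s <- ref; s[p] <- v[p]; paste(s, collapse = "")
    }, "")
    expected <- termSum(trip) - sum(vapply(singles, termSum, 0)) +
      (length(mut) - 1) * termSum("DKE")
    expect_equal(er$residuals$residual[i], expected, tolerance = 1e-9)
  }
})
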