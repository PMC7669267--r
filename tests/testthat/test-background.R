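# Background-resolved substitution effects and the permutation null.

# a complete noise-free additive fitness landscape as a named vector
additiveW <- function(coef = NULL, seed = 1) {
  set.seed(seed)
  cfg <- simConfig(noiseSD = 0, fitnessFloor = -Inf)
  generateTrueLandscape(cfg, "DKE", coefficients = coef)
}

test_that("profiles have the expected background cardinality", {
  ls <- additiveW()
  p <- deltaWProfile(1, "D", "I", ls$trueW)
  expect_equal(p$n_backgrounds, 19^2)  # 361 with proline excluded
  p2 <- deltaWProfile(1, "D", "I", ls$trueW, excludedAas = character())
  expect_equal(p2$n_backgrounds, 20^2)  # 400 with no exclusion
  # two excluded residues: (20 - 2)^2
  p3 <- deltaWProfile(1, "D", "I", ls$trueW, excludedAas = c("P", "G"))
  expect_equal(p3$n_backgrounds, 18^2)
  expect_error(deltaWProfile(1, "D", "D", ls$trueW), "must differ")
  expect_error(deltaWProfile(1, "P", "I", ls$trueW), "excluded")
})

test_that("delta-W profiles are antisymmetric and additive effects exact", {
  ls <- additiveW()
  w <- ls$trueW
  fwd <- deltaWProfile(2, "K", "L", w)
  rev <- deltaWProfile(2, "L", "K", w)
  expect_equal(fwd$delta_w, -rev$delta_w)
  # under pure additivity every background gives c(p, to) - c(p, from)
  expect_equal(unname(fwd$delta_w),
               rep(ls$coefficients[2, "L"] - ls$coefficients[2, "K"], 361),
               tolerance = 1e-12)
})

test_that("profiles only use backgrounds measured on both sides", {
  ls <- additiveW()
  w <- ls$trueW
  w <- w[setdiff(names(w), c("IAA", "DCC"))]  # knock out two variants
  p <- deltaWProfile(1, "D", "I", w)
  expect_equal(p$n_backgrounds, 361 - 2)
  expect_false(any(c("AA", "CC") %in% names(p$delta_w)))
})

test_that("effect summaries mirror exactly across substitution direction", {
  set.seed(4)
  cfg <- simConfig(noiseSD = 0.3, fitnessFloor = -Inf)
  w <- generateTrueLandscape(cfg, "DKE")$trueW
  subs <- data.frame(position = c(2, 2), from_aa = c("K", "L"),
                     to_aa = c("L", "K"))
  eff <- substitutionEffects(w, subs)
  expect_equal(eff$mode[1], -eff$mode[2])
  expect_equal(eff$median[1], -eff$median[2])
  expect_equal(eff$iqr[1], eff$iqr[2])
  expect_equal(eff$alpha[1], -eff$alpha[2])
  # and the mirrored summary matches an independent direct fit
  direct <- summarizeEffect(deltaWProfile(2, "L", "K", w))
  expect_equal(eff$mode[2], direct$mode, tolerance = 1e-6)
})

test_that("modes recover additive coefficient differences under noise", {
  set.seed(8)
  cfg <- simConfig(noiseSD = 0.05, fitnessFloor = -Inf)
  ls <- generateTrueLandscape(cfg, "DKE")
  eff <- substitutionEffects(ls$trueW, wtSubstitutions())
  expected <- mapply(function(p, f, t)
    ls$coefficients[p, t] - ls$coefficients[p, f],
    eff$position, eff$from_aa, eff$to_aa)
  # noise sd 0.05 on each variant -> dW sd ~0.07; the mode of 361 values
  # tracks the coefficient difference well inside that
  expect_gt(cor(eff$mode, expected), 0.999)
  expect_lt(max(abs(eff$mode - expected)), 0.05)
})

test_that("summarizeEffect returns empirical summaries when the fit fails", {
  x <- rep(c(-1, 0, 1), 30)
  s <- summarizeEffect(c(0.5, -0.5))  # below minN: no fit
  expect_true(is.na(s$mode))
  expect_equal(s$mean, 0)
  s2 <- summarizeEffect(x)
  expect_equal(s2$mean, 0)
  expect_equal(s2$median, 0)
  expect_equal(s2$iqr, 2)
})

test_that("constant fitness gives all-zero profiles and no significance", {
  w <- setNames(rep(0.7, 9261), enumerateLibrary()$aa_triplet)
  p <- deltaWProfile(1, "D", "I", w)
  expect_true(all(p$delta_w == 0))
  subs <- data.frame(position = 1, from_aa = "D", to_aa = c("I", "L"))
  nul <- permutationNull(w, subs, n = 5, seed = 1)
  expect_true(all(nul$null_modes == 0 | is.na(nul$null_modes)))
  eff <- significanceCalls(substitutionEffects(w, subs), nul)
  expect_false(any(eff$significance %in% c("negative", "positive")))
})

test_that("mode-shift summary places the wild type at (1, -1)", {
  e3 <- data.frame(position = c(1, 1), from_aa = "D", to_aa = c("I", "A"),
                   mode = c(-0.63, 0))
  e2 <- data.frame(position = c(1, 1), from_aa = "D", to_aa = c("I", "A"),
                   mode = c(-0.01, NA))
  ms <- modeShiftSummary(e3, e2)
  expect_equal(nrow(ms), 1L)  # the NA-mode substitution is omitted
  expect_equal(ms$w_cognate, 1 - 0.63)
  expect_equal(ms$w_noncognate, -1 - 0.01)
  # zero modes map to the wild-type anchor point
  e0 <- data.frame(position = 1, from_aa = "D", to_aa = "A", mode = 0)
  ms0 <- modeShiftSummary(e0, e0)
  expect_equal(c(ms0$w_cognate, ms0$w_noncognate), c(1, -1))
})

test_that("position-wise comparison matches additive coefficients", {
  ls <- additiveW(seed = 13)
  # noise-free additivity: mode shift of {aa at pos} vs {wt at pos}
  # equals the coefficient difference; distributions are translates
  cmp <- positionwiseWtComparison(2, "L", ls$trueW)
  expect_equal(cmp$shift, ls$coefficients[2, "L"], tolerance = 1e-6)
  expect_equal(cmp$n_aa, 361)
  cmpSelf <- positionwiseWtComparison(2, "K", ls$trueW)
  expect_equal(cmpSelf$shift, 0)
  # sign agreement with the paired delta-W mode under noise
  set.seed(14)
  cfg <- simConfig(noiseSD = 0.1, fitnessFloor = -Inf)
  ls2 <- generateTrueLandscape(cfg, "DKE")
  eff <- substitutionEffects(ls2$trueW,
                             data.frame(position = 2, from_aa = "K",
                                        to_aa = c("L", "G", "W")))
  shifts <- vapply(c("L", "G", "W"), function(a)
    positionwiseWtComparison(2, a, ls2$trueW)$shift, 0)
  expect_equal(sign(unname(shifts)), sign(eff$mode))
})
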