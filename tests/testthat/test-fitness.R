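# Raw fitness, anchored scaling, and replicate combination.

test_that("measurement filter uses strict pre > 25 and post > 0", {
  expect_equal(applyMeasurementFilter(c(25, 26, 1000), c(10, 1, 0)),
               c(FALSE, TRUE, FALSE))
})

test_that("frequencies normalise per sample and reject empty samples", {
  expect_equal(variantFrequencies(c(100, 100, 100)), rep(1/3, 3))
  expect_equal(variantFrequencies(c(400, 100, 100)), c(2/3, 1/6, 1/6))
  expect_equal(variantFrequencies(5), 1)
  expect_error(variantFrequencies(c(0, 0)), "zero total")
  m <- variantFrequencies(matrix(c(1, 3, 2, 2), 2))
  expect_equal(colSums(m), c(1, 1))
})

test_that("raw fitness matches the hand-computed 3-variant toy", {
  # pre (100,100,100), post (400,100,100): variant 1 expands 2x while the
  # rest-of-library halves its share -> W_raw = ln 4
  w <- rawFitness(c(1, 1, 1) / 3, c(4, 1, 1) / 6)
  expect_equal(w[1], log(4))
  # neutral variant: focal ratio equals rest-of-library ratio
  expect_equal(rawFitness(c(0.5, 0.5), c(0.5, 0.5)), c(0, 0))
  # 2-variant symmetry: swapping the focal variant flips the sign
  w2 <- rawFitness(c(0.3, 0.7), c(0.6, 0.4))
  expect_equal(w2[1], -w2[2])
  # adding an unrelated variant changes others only via the rest term
  w3 <- rawFitness(c(1, 1, 2) / 4, c(4, 1, 1) / 6)
  expect_false(isTRUE(all.equal(w3[1], log(4))))
})

test_that("scaling maps the stop statistic to 0 and the reference to 1", {
  wRaw <- c(ref = 2, a = -0.5, s1 = -3.5, s2 = -3, s3 = -2.5)
  stopClass <- c(FALSE, FALSE, TRUE, TRUE, TRUE)
  w <- scaleFitness(wRaw, stopClass, "ref")
  expect_equal(unname(w["ref"]), 1)
  expect_equal(median(w[stopClass]), 0)
  expect_equal(unname(w["a"]), 0.5)
  # mean anchoring as the configurable alternative
  wm <- scaleFitness(wRaw, stopClass, "ref", stopStatistic = "mean")
  expect_equal(mean(wm[stopClass]), 0)
  # degenerate selection errors
  expect_error(scaleFitness(c(ref = -3, s = -3, s2 = -3, s3 = -3),
                            c(FALSE, TRUE, TRUE, TRUE), "ref"),
               "degenerate")
})

test_that("scaled fitness is invariant to the log base", {
  sim <- smallSim()
  fe <- fitnessScores(sim$counts, "E3", scalingConfig(logBase = exp(1)))
  f2 <- fitnessScores(sim$counts, "E3", scalingConfig(logBase = 2))
  expect_equal(fe$W_combined, f2$W_combined, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(fe$W_raw_1, f2$W_raw_1)))
})

test_that("scaling fixed points hold on simulated selections", {
  sim <- smallSim()
  fit <- fitnessScores(sim$counts, "E3")
  for (r in 1:2) {
    w <- fit[[paste0("W_", r)]]
    expect_equal(median(w[fit$class == "stop"], na.rm = TRUE), 0)
    expect_equal(fit["DKE", paste0("W_", r)], 1)
  }
  # the E2 selection anchors its own reference, ILK
  fit2 <- fitnessScores(sim$counts, "E2")
  expect_equal(fit2["ILK", "W_combined"], 1)
})

test_that("replicate combination reports R^2 and slope", {
  w1 <- c(0.1, 0.5, 0.9, 0.2, 0.7)
  # identical replicates
  c1 <- combineReplicates(cbind(w1, w1))
  expect_equal(c1$r_squared, 1)
  expect_equal(c1$combined, w1)
  # constant offset: correlation is shift-invariant
  c2 <- combineReplicates(cbind(w1, w1 + 0.1))
  expect_equal(c2$r_squared, 1)
  expect_equal(c2$slope, 1)
  # anti-correlated replicates: R^2 = 1 but the slope exposes the flip
  set.seed(1)
  a <- rnorm(10)
  c3 <- combineReplicates(cbind(a, -a))
  expect_equal(c3$r_squared, 1)
  expect_equal(c3$slope, -1)
  # combined requires all replicates to pass
  c4 <- combineReplicates(cbind(c(1, NA), c(1, 2)))
  expect_equal(is.na(c4$combined), c(FALSE, TRUE))
})

test_that("estimated fitness tracks truth on deep selections", {
  sim <- smallSim()
  fit <- fitnessScores(sim$counts, "E3")
  w <- fitnessVector(fit)
  tw <- trueFitness(sim$truth, "E3")[names(w)]
  expect_gt(cor(w, tw), 0.95)
  # away from the floor the relationship is monotone in rank too
  live <- tw > 0.2
  expect_gt(cor(w[live], tw[live], method = "spearman"), 0.9)
})
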