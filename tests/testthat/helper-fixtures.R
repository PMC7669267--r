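# Shared fixtures, built in code.

demoTemplate <- function() {
  exampleTemplate(barcodeMap = c(ACGTAC = "s1", GGTTCC = "s2"))
}

# one NNK codon spelling of an amino-acid triplet, deterministic
firstSpelling <- function(aaTriplet) {
  syn <- specscan:::nnkSynonyms()
  paste(vapply(strsplit(aaTriplet, "")[[1]], function(a) syn[[a]][1], ""),
        collapse = "")
}

# minimal pre/post sample sheet for one toxin and one replicate
prePostInfo <- function(toxin = "E3", replicate = 1L,
                        ids = c("s1", "s2")) {
  data.frame(sample_id = ids, toxin = toxin, replicate = replicate,
             timepoint = c("pre", "post"), stringsAsFactors = FALSE)
}

# a small but selection-realistic simulated experiment, cached per session
smallSim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulateExperiment(simConfig(readDepth = 1e6), seed = 101L)
    cache
  }
})

# draw n values from a skew-normal(xi, omega, alpha) by the delta
# representation (independent of the package's density code)
rSkewNormal <- function(n, xi = 0, omega = 1, alpha = 0) {
  delta <- alpha / sqrt(1 + alpha^2)
  z <- delta * abs(rnorm(n)) + sqrt(1 - delta^2) * rnorm(n)
  xi + omega * z
}
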