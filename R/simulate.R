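# Synthetic bulk-competition generator: additive-plus-noise landscapes over
# the complete NNK library, growth selection, multinomial read sampling,
# and optional FASTQ emission with NNK codon redundancy.

#' Simulation configuration
#'
#' Defaults describe a two-replicate bulk competition over the complete
#' three-position library (9261 protein variants including stops):
#' additive landscape with per-substitution coefficients drawn from
#' `N(coefMean, coefSD)`, biological noise `N(0, noiseSD)`, log-normal
#' pre-selection abundances, an `expansionFactor`-fold expansion of a fully
#' rescuing variant over the selection window, and multinomial read
#' sampling at `readDepth` per sample.
#'
#' @param coefMean,coefSD Mean and SD of the additive coefficients for
#'   non-reference residues (defaults -0.3 and 0.35, giving a landscape in
#'   which roughly a quarter of variants retain above-half-maximal
#'   fitness).
#' @param coefficients Optional list, per toxin, of a 3 x 20 coefficient
#'   matrix (rows positions, columns residues) overriding the random draw.
#' @param epistasisFraction Fraction of position-pair residue combinations
#'   receiving a pairwise epistatic term (default 0: purely additive).
#' @param epistasisSD SD of injected pairwise terms.
#' @param noiseSD SD of biological noise on true fitness (default 0.05).
#' @param stopFitness True fitness of stop-containing variants (0).
#' @param refFitness True fitness of the reference variant (1).
#' @param preLogSD Log-normal sigma of pre-selection variant abundances
#'   (default 0.5).
#' @param expansionFactor Fold-expansion A of a W = 1 variant relative to a
#'   W = 0 variant over the selection (default 50).
#' @param readDepth Reads per sample (default 5e6).
#' @param nReplicates Biological replicates per selection (default 2).
#' @param fitnessFloor Lower bound applied to true fitness (default 0:
#'   toxin-arrested cells do not shrink, so the assay cannot resolve
#'   fitness below the stop baseline; set `-Inf` to disable, e.g. for
#'   exactly-additive landscapes).
#' @param references Named character vector of reference triplets per toxin
#'   (default `c(E3 = "DKE", E2 = "ILK")`).
#' @param errorRate Per-base substitution rate for read emission
#'   (default 0, error-free).
#' @return A list of class `"simConfig"`.
#' @export
simConfig <- function(coefMean = -0.3, coefSD = 0.35, coefficients = NULL,
                      epistasisFraction = 0, epistasisSD = 0.2,
                      noiseSD = 0.05, stopFitness = 0, refFitness = 1,
                      preLogSD = 0.5, expansionFactor = 50,
                      readDepth = 5e6, nReplicates = 2L,
                      fitnessFloor = 0,
                      references = c(E3 = "DKE", E2 = "ILK"),
                      errorRate = 0) {
  stopifnot(expansionFactor > 1, readDepth > 0, nReplicates >= 1)
  structure(list(coefMean = coefMean, coefSD = coefSD,
                 coefficients = coefficients,
                 epistasisFraction = epistasisFraction,
                 epistasisSD = epistasisSD, noiseSD = noiseSD,
                 stopFitness = stopFitness, refFitness = refFitness,
                 preLogSD = preLogSD, expansionFactor = expansionFactor,
                 readDepth = readDepth, nReplicates = as.integer(nReplicates),
                 fitnessFloor = fitnessFloor, references = references,
                 errorRate = errorRate),
            class = "simConfig")
}

#' SimTruth: ground truth of a simulated experiment
#'
#' @slot trueW Matrix of true fitness, variants x toxins (rownames are
#'   amino-acid triplets).
#' @slot coefficients List per toxin of the generating 3 x 20 additive
#'   coefficient matrices.
#' @slot epistasis List per toxin of injected pairwise terms.
#' @slot preFreq Pre-selection frequency per variant.
#' @slot config The `simConfig` used.
#' @slot seed Integer seed.
#' @export
setClass("SimTruth",
  representation(trueW = "matrix", coefficients = "list",
                 epistasis = "list", preFreq = "numeric", config = "list",
                 seed = "integer"))

setValidity("SimTruth", function(object) {
  if (is.null(rownames(object@trueW)))
    return("trueW must have variant rownames")
  TRUE
})

#' @describeIn SimTruth-class True fitness vector for one toxin.
#' @param x A `SimTruth`.
#' @param toxin Toxin label (column of `trueW`).
#' @export
trueFitness <- function(x, toxin) {
  setNames(x@trueW[, toxin], rownames(x@trueW))
}

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", nrow(object@trueW), "variants x",
      ncol(object@trueW), "toxins; seed", object@seed, "\n")
})

# Draw a 3 x 20 additive coefficient matrix with zero at the reference
# residue of each position.
.drawCoefficients <- function(config, reference) {
  aa20 <- setdiff(aaAlphabet(), "*")
  ref <- strsplit(reference, "")[[1]]
  m <- matrix(rnorm(60L, config$coefMean, config$coefSD), 3L, 20L,
              dimnames = list(paste0("pos", 1:3), aa20))
  for (p in 1:3) m[p, ref[p]] <- 0
  m
}

# Draw pairwise epistatic terms: data.frame(pos_a, pos_b, aa_a, aa_b, term).
.drawEpistasis <- function(config) {
  if (config$epistasisFraction <= 0)
    return(data.frame(pos_a = integer(), pos_b = integer(),
                      aa_a = character(), aa_b = character(),
                      term = numeric(), stringsAsFactors = FALSE))
  aa20 <- setdiff(aaAlphabet(), "*")
  pairs <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    g <- expand.grid(aa_a = aa20, aa_b = aa20, stringsAsFactors = FALSE)
    keep <- runif(nrow(g)) < config$epistasisFraction
    if (!any(keep)) return(NULL)
    data.frame(pos_a = pairs[i, 1], pos_b = pairs[i, 2],
               g[keep, , drop = FALSE],
               term = rnorm(sum(keep), 0, config$epistasisSD),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  if (is.null(out))
    out <- data.frame(pos_a = integer(), pos_b = integer(),
                      aa_a = character(), aa_b = character(),
                      term = numeric(), stringsAsFactors = FALSE)
  out
}

#' Generate a true fitness landscape for one selection
#'
#' True fitness is `refFitness + sum_p c(p, v_p)` plus any injected
#' pairwise terms and `N(0, noiseSD)` noise, rectified at `fitnessFloor`
#' (default 0, the stop baseline). Stop-containing variants are forced to
#' `stopFitness` and the reference variant to `refFitness` exactly.
#'
#' @param config A [simConfig()].
#' @param reference Reference triplet for this selection (its residues
#'   carry coefficient 0).
#' @param coefficients Optional 3 x 20 coefficient matrix; drawn randomly
#'   when `NULL`.
#' @return List with `trueW` (named vector over all 9261 variants),
#'   `coefficients`, `epistasis`.
#' @export
generateTrueLandscape <- function(config, reference = "DKE",
                                  coefficients = NULL) {
  lib <- enumerateLibrary(reference)
  if (is.null(coefficients)) coefficients <- .drawCoefficients(config,
                                                               reference)
  epi <- .drawEpistasis(config)
  isStop <- lib$class == "stop"
  g <- rep(config$refFitness, nrow(lib))
  for (p in 1:3)
    g[!isStop] <- g[!isStop] +
      coefficients[p, lib[[paste0("aa", p)]][!isStop]]
  if (nrow(epi)) {
    for (i in seq_len(nrow(epi))) {
      hit <- !isStop &
        lib[[paste0("aa", epi$pos_a[i])]] == epi$aa_a[i] &
        lib[[paste0("aa", epi$pos_b[i])]] == epi$aa_b[i]
      g[hit] <- g[hit] + epi$term[i]
    }
  }
  w <- g + rnorm(nrow(lib), 0, config$noiseSD)
  w <- pmax(w, config$fitnessFloor)
  w[isStop] <- config$stopFitness
  w[lib$aa_triplet == reference] <- config$refFitness
  list(trueW = setNames(w, lib$aa_triplet), coefficients = coefficients,
       epistasis = epi)
}

#' Deterministic growth selection on frequencies
#'
#' Post-selection frequencies are proportional to
#' `f_pre * A^max(W, 0)`: a fully rescuing variant (W = 1) expands A-fold
#' relative to a dead one (W = 0), and variants at or below the floor do
#' not expand relative to each other.
#'
#' @param trueW Named true-fitness vector.
#' @param preFreq Named pre-selection frequencies (same variants).
#' @param expansionFactor Fold-expansion A (> 1).
#' @return Named post-selection frequencies summing to 1.
#' @export
simulateSelection <- function(trueW, preFreq, expansionFactor = 50) {
  stopifnot(expansionFactor > 1)
  post <- preFreq * expansionFactor^pmax(trueW[names(preFreq)], 0)
  post / sum(post)
}

#' Multinomial read sampling
#'
#' @param frequencies Named frequency vector (sums to 1).
#' @param depth Total reads to draw.
#' @param seed Optional seed; when `NULL` the current RNG state is used.
#' @return Named integer count vector.
#' @export
sampleReads <- function(frequencies, depth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- rmultinom(1L, size = depth, prob = frequencies)[, 1L]
  setNames(as.integer(counts), names(frequencies))
}

#' Simulate a complete two-toxin bulk-competition experiment
#'
#' Draws one landscape per toxin, one shared log-normal pre-selection
#' library, and per replicate an independent multinomial pre and post
#' sample at the configured depth. All randomness flows from `seed`.
#'
#' @param config A [simConfig()].
#' @param seed Integer seed.
#' @return List with `counts` (protein-level [SelectionCounts-class] over
#'   all toxin x replicate x timepoint samples) and `truth`
#'   ([SimTruth-class]).
#' @export
simulateExperiment <- function(config = simConfig(), seed = 1L) {
  set.seed(seed)
  toxins <- names(config$references)
  landscapes <- lapply(toxins, function(tox)
    generateTrueLandscape(config, config$references[[tox]],
                          config$coefficients[[tox]]))
  names(landscapes) <- toxins
  variants <- names(landscapes[[1]]$trueW)
  preFreq <- rlnorm(length(variants), 0, config$preLogSD)
  preFreq <- setNames(preFreq / sum(preFreq), variants)

  cols <- list(); info <- list()
  for (tox in toxins) {
    postFreq <- simulateSelection(landscapes[[tox]]$trueW, preFreq,
                                  config$expansionFactor)
    for (r in seq_len(config$nReplicates)) {
      for (tp in c("pre", "post")) {
        f <- if (tp == "pre") preFreq else postFreq
        sid <- paste(tox, paste0("rep", r), tp, sep = "_")
        cols[[sid]] <- sampleReads(f, config$readDepth)
        info[[sid]] <- data.frame(sample_id = sid, toxin = tox,
                                  replicate = r, timepoint = tp,
                                  stringsAsFactors = FALSE)
      }
    }
  }
  m <- do.call(cbind, cols)
  counts <- SelectionCounts(m, do.call(rbind, info), level = "protein",
                            reference = config$references[[1]])
  truth <- new("SimTruth",
               trueW = vapply(landscapes, `[[`, numeric(length(variants)),
                              "trueW"),
               coefficients = lapply(landscapes, `[[`, "coefficients"),
               epistasis = lapply(landscapes, `[[`, "epistasis"),
               preFreq = preFreq, config = unclass(config),
               seed = as.integer(seed))
  list(counts = counts, truth = truth)
}

#' Emit reads for a variant count table
#'
#' Synthesises amplicon reads for one sample: each read is
#' `[barcode][random 4-6 nt spacer][gene]`, the gene being the template
#' wild type with the randomised codons replaced. Protein-level counts use
#' a uniformly random NNK synonym per read; codon-level counts use their
#' exact codons. With `errorRate = 0` the reads round-trip through
#' [extractVariants()] to exactly the input counts.
#'
#' @param counts Named integer vector: names are amino-acid triplets
#'   (protein level) or 9-nt codon triplets (codon level).
#' @param template A [TemplateSpec-class].
#' @param barcode Sample barcode prepended to every read.
#' @param seed Optional seed.
#' @param errorRate Per-base uniform substitution rate (default 0).
#' @return Character vector of reads (shuffled).
#' @export
synthesizeReads <- function(counts, template, barcode, seed = NULL,
                            errorRate = 0) {
  if (!is.null(seed)) set.seed(seed)
  counts <- counts[counts > 0]
  keys <- rep(names(counts), counts)
  n <- length(keys)
  codonLevel <- all(nchar(names(counts)) == 9L)
  syn <- nnkSynonyms()
  codons <- if (codonLevel) {
    cbind(substr(keys, 1, 3), substr(keys, 4, 6), substr(keys, 7, 9))
  } else {
    vapply(1:3, function(p) {
      aa <- substr(keys, p, p)
      vapply(aa, function(a) {
        s <- syn[[a]]
        s[sample.int(length(s), 1L)]
      }, "")
    }, character(n))
  }
  if (n == 1L) codons <- matrix(codons, nrow = 1L)
  gene <- geneSeq(template)
  rp <- codonPositions(template)
  pre <- substr(gene, 1L, (rp[1] - 1L) * 3L)
  mid1 <- substr(gene, rp[1] * 3L + 1L, (rp[2] - 1L) * 3L)
  mid2 <- substr(gene, rp[2] * 3L + 1L, (rp[3] - 1L) * 3L)
  post <- substr(gene, rp[3] * 3L + 1L, nchar(gene))
  sp <- template@spacerRange
  spLen <- sample(seq(sp[1], sp[2]), n, replace = TRUE)
  spacer <- vapply(spLen, function(k)
    paste(sample(DNA_BASES, k, replace = TRUE), collapse = ""), "")
  reads <- paste0(barcode, spacer, pre, codons[, 1], mid1, codons[, 2],
                  mid2, codons[, 3], post)
  if (errorRate > 0) {
    reads <- vapply(reads, function(r) {
      b <- strsplit(r, "")[[1]]
      hit <- runif(length(b)) < errorRate
      b[hit] <- sample(DNA_BASES, sum(hit), replace = TRUE)
      paste(b, collapse = "")
    }, "", USE.NAMES = FALSE)
  }
  sample(reads)
}

#' Write reads to FASTQ
#'
#' @param reads Character vector of reads.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
writeFastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- paste0("read", seq_along(x))
  Biostrings::writeXStringSet(x, path, format = "fastq")
  invisible(path)
}
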