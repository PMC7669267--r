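# End-to-end orchestration: counts (simulated or loaded) -> fitness ->
# specificity -> background effects -> additive model, with a manifest of
# produced artifacts.

#' Run the full analysis pipeline
#'
#' Stages run in dependency order; every output file is recorded in a
#' manifest with its MD5 hash and the seeds used, so an identical
#' configuration reproduces identical outputs. Input is either a
#' simulated experiment (`counts = NULL`) or an existing count table.
#'
#' @param outDir Output directory (created if needed).
#' @param counts A [SelectionCounts-class], path to a counts TSV
#'   ([readCountsTsv()]), or `NULL` to simulate with `sim`.
#' @param sim A [simConfig()] used when `counts` is `NULL`.
#' @param seed Global seed; stage seeds are derived from it.
#' @param scaling A [ScalingConfig-class].
#' @param threshold Specificity threshold, default 0.5.
#' @param permutations Number of permutations for mode significance
#'   (0 disables the permutation stage).
#' @param folds Cross-validation folds for the additive model.
#' @param excludedAas Residues excluded from background analyses,
#'   default `"P"`.
#' @return The manifest (list), invisibly; written to
#'   `file.path(outDir, "manifest.json")`.
#' @export
runPipeline <- function(outDir, counts = NULL, sim = simConfig(),
                        seed = 1L, scaling = scalingConfig(),
                        threshold = 0.5, permutations = 0L, folds = 5L,
                        excludedAas = "P") {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(simulate = seed, permutation = seed + 1L, folds = seed + 2L)
  files <- character()
  addFile <- function(path) files <<- c(files, path)

  truth <- NULL
  if (is.null(counts)) {
    simOut <- simulateExperiment(sim, seed = seeds$simulate)
    counts <- simOut$counts
    truth <- simOut$truth
    truthTsv <- file.path(outDir, "truth.tsv")
    write.table(data.frame(aa_triplet = rownames(truth@trueW),
                           truth@trueW, check.names = FALSE),
                truthTsv, sep = "\t", quote = FALSE, row.names = FALSE)
    addFile(truthTsv)
  } else if (is.character(counts)) {
    if (!file.exists(counts)) stop("counts file not found: ", counts)
    counts <- readCountsTsv(counts)
  }
  countsTsv <- file.path(outDir, "counts.tsv")
  writeCountsTsv(counts, countsTsv); addFile(countsTsv)

  toxins <- unique(counts$toxin)
  fits <- list()
  for (tox in toxins) {
    fits[[tox]] <- fitnessScores(counts, tox, scaling)
    f <- file.path(outDir, paste0("fitness_", tox, ".tsv"))
    write.table(fits[[tox]], f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    addFile(f)
  }

  spec <- effects <- NULL
  if (length(toxins) >= 2L) {
    spec <- specificityTable(fits[[1]], fits[[2]], threshold)
    f <- file.path(outDir, "specificity.tsv")
    write.table(spec, f, sep = "\t", quote = FALSE, row.names = FALSE)
    addFile(f)
    summ <- list(
      threshold = threshold,
      category_counts = as.list(table(spec$category)),
      neutralizers = lapply(fits, neutralizerSummary, threshold = threshold),
      gap_exceedance = gapExceedanceFraction(
        spec, S4Vectors::metadata(counts)$reference))
    f <- file.path(outDir, "specificity_summary.json")
    jsonlite::write_json(summ, f, auto_unbox = TRUE, digits = NA)
    addFile(f)
  }

  effectsList <- list()
  for (tox in toxins) {
    w <- fitnessVector(fits[[tox]])
    eff <- substitutionEffects(w, excludedAas = excludedAas)
    if (permutations > 0L) {
      null <- permutationNull(w, n = permutations,
                              seed = seeds$permutation,
                              excludedAas = excludedAas)
      eff <- significanceCalls(eff, null)
      f <- file.path(outDir, paste0("null_modes_", tox, ".tsv"))
      write.table(data.frame(mode = null$null_modes), f, sep = "\t",
                  quote = FALSE, row.names = FALSE)
      addFile(f)
    }
    eff$toxin <- tox
    effectsList[[tox]] <- eff
    f <- file.path(outDir, paste0("effects_", tox, ".tsv"))
    write.table(eff, f, sep = "\t", quote = FALSE, row.names = FALSE)
    addFile(f)
  }
  if (length(toxins) >= 2L) {
    shift <- modeShiftSummary(effectsList[[1]], effectsList[[2]])
    f <- file.path(outDir, "mode_shift.tsv")
    write.table(shift, f, sep = "\t", quote = FALSE, row.names = FALSE)
    addFile(f)
  }

  models <- list()
  for (tox in toxins) {
    fitTox <- fits[[tox]]
    ref <- if (tox %in% names(scaling@references))
      scaling@references[[tox]] else S4Vectors::metadata(counts)$reference
    mod <- fitAdditiveCV(fitTox, k = folds, seed = seeds$folds,
                         reference = ref)
    models[[tox]] <- mod
    f <- file.path(outDir, paste0("coefficients_", tox, ".tsv"))
    write.table(data.frame(coefficient = names(mod$coefficients),
                           estimate = unname(mod$coefficients),
                           se = unname(mod$se)),
                f, sep = "\t", quote = FALSE, row.names = FALSE)
    addFile(f)
    res <- epistasisResiduals(fitTox, ref)
    f <- file.path(outDir, paste0("epistasis_", tox, ".tsv"))
    write.table(res$residuals, f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    addFile(f)
  }
  cvJson <- file.path(outDir, "cv_summary.json")
  jsonlite::write_json(
    lapply(models, function(m)
      list(mean_r_squared = m$mean_r_squared, sd_r_squared = m$sd_r_squared,
           fold_r_squared = m$fold_r_squared, k = m$k)),
    cvJson, auto_unbox = TRUE, digits = NA)
  addFile(cvJson)

  manifest <- list(seed = seed, stage_seeds = seeds,
                   files = lapply(setNames(files, basename(files)),
                                  function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
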