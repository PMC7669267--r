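Package: specscan
Title: Combinatorially Complete Deep Mutational Scanning of Interaction Specificity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of combinatorially complete saturation-mutagenesis
    libraries screened by bulk competition against cognate and non-cognate
    binding partners, modelled on toxin-antitoxin (ParD-ParE) selections.
    Provides amplicon read demultiplexing and NNK variant counting, raw and
    anchored fitness scoring from pre-/post-selection counts, specificity-gap
    and interaction-class summaries, per-substitution distributions of fitness
    effects across all genetic backgrounds summarised by the mode of a
    maximum-likelihood skew-normal fit with permutation-based significance,
    additive (independent-residue) fitness models with k-fold cross-validation
    and epistasis residuals, and a synthetic bulk-competition generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
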