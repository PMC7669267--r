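---
title: "Methods: fitness, specificity and background-resolved substitution effects in combinatorially complete libraries"
author: "specscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combinatorially complete DMS of interaction specificity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specscan)
```

# The experimental design the package models

`specscan` analyses saturation-mutagenesis libraries in which a small number
of interface positions of a protein — the motivating system is a bacterial
ParD antitoxin binding its ParE toxin — are fully randomised with NNK codons
and the pooled library is competed in bulk against a cognate and a
non-cognate partner. Because toxin activity arrests growth, a variant's
enrichment between the pre-selection and post-selection sequencing samples
reports how well it neutralises the partner it was screened against.

With three NNK positions the library is *combinatorially complete*: all
`20^3 = 8000` stop-free residue combinations exist (plus `21^3 - 20^3 =
1261` stop-containing triplets from the TAG codon of NNK), so every
substitution at one position can be observed in every genetic background
formed by the other two. That completeness is what the package's core
statistic exploits.

# Read processing

Reads follow the layout `[6-nt barcode][4-6-nt random spacer][gene]`.
Demultiplexing is by exact barcode match; the gene is located by exact
match of an anchor (the first 12 gene bases by default) tried at each
admissible spacer offset in ascending order, first hit wins. Two filters
then apply, in order:

* **(a)** every randomised codon must fit the NNK pattern (third base G or
  T); ambiguity characters also fail;
* **(b)** every other codon must encode the wild-type residue — synonymous
  nucleotide changes pass, non-synonymous ones reject the read.

Each rejected read carries exactly one reason, the first failing check in
the order barcode, length, anchor, (a), (b). Counts are tabulated at codon
level and aggregated to protein level before fitness scoring (a
diagnostics flag keeps codon level); the aggregation conserves sample
totals. Quality-based trimming, paired-end merging and alignment are out
of scope: inputs are assumed to be pre-merged reads covering the full
gene.

# Fitness scores

For each variant $i$ with pre- and post-selection frequencies $f_{pre}(i)$
and $f_{post}(i)$, the raw fitness is the rest-of-library-normalised log
enrichment

$$W_{raw}(i) \;=\; \log\!\left[\frac{f_{post}(i)/f_{pre}(i)}
{F_{post}(\neg i)/F_{pre}(\neg i)}\right],
\qquad F(\neg i) = 1 - f(i),$$

i.e. the log-fold expansion of the variant relative to the remaining
library. Raw values are computed only for variants passing the measurement
filter (pre-selection reads > 25 and post-selection reads > 0, strict).
No pseudocounts are used: variants failing the filter get no fitness
rather than an imputed one.

Raw values are then mapped affinely so that the *median* $W_{raw}$ of
stop-codon variants equals 0 and the reference variant equals 1 — the wild
type for the cognate selection, the predicted-best (ParD2-like) triplet
for the non-cognate one. The median was chosen over the mean as the stop
anchor because it is robust to the occasional stop variant rescued by
read-through noise; the mean is available via `scalingConfig()`. Because
the anchoring is affine, scaled fitness is invariant to the logarithm's
base. Replicates are scaled independently — the stops and the reference
act as per-replicate internal controls — and averaged; the combined value
is reported only for variants passing the filter in every replicate, and
the squared Pearson correlation plus regression slope between replicates
are attached (the slope catches pathological anti-correlated agreement
that $R^2$ alone would hide). An intermediate culture dilution during
selection needs no correction because frequencies are invariant to
unbiased dilution.

# Specificity

The specificity gap is $W_{cognate} - W_{noncognate}$; classification at a
threshold $t$ (default 0.5, strict `>`; ties have measure zero on
continuous scores) yields cognate-specific, non-cognate-specific,
promiscuous (above for both) and dead (below for both) categories.
Proline-containing variants are excluded from gap-distribution and all
background-effect analyses — the library positions sit in α-helices, so
proline effects confound stability with recognition — but not from raw
neutralizer counts.

# Background-resolved substitution effects

For a substitution $X \to Y$ at one position, the package computes
$\Delta W(b) = W(Y, b) - W(X, b)$ in every background $b$ over the other
two positions where both variants are measured: 361 backgrounds with
proline excluded, 400 without. The sign convention is mutant-minus-
original (a configuration switch flips it), so a detrimental substitution
has a negative typical effect.

Each $\Delta W$ distribution is summarised by the mode of a
maximum-likelihood skew-normal fit,
$f(x) = \tfrac{2}{\omega}\,\varphi(z)\,\Phi(\alpha z)$ with
$z = (x-\xi)/\omega$. The skew-normal is used because effect
distributions pile up against the assay's sensitivity limits (variants at
the top or bottom of the fitness range cannot move further) and are
therefore skewed toward zero change; the mode is a better "typical
effect" than the mean under that skew, while empirical mean, median and
IQR are reported alongside. Numerical choices:

* the likelihood is optimised over $(\xi, \log\omega, \alpha)$ on
  standardised data by L-BFGS-B from a method-of-moments start, with the
  compiled objective and analytic gradient; $|\alpha|$ is capped at 50 to
  keep fits off the half-normal boundary;
* on failure a second attempt starts from the normal fit ($\alpha = 0$);
  constant input is reported as a failed fit rather than $\omega \to 0$;
* profiles with fewer than 20 values get empirical summaries only;
* the mode is the unique root of the log-density derivative (the density
  is log-concave), solved by safeguarded Newton to far better than
  $10^{-6}\omega$; `alpha = 0` returns $\xi$ exactly;
* the ML fit of a negated sample is exactly the negated fit, so
  antisymmetric substitution pairs are fitted once and mirrored.

Significance is calibrated by permutation: fitness values are shuffled
across variant labels, all substitution modes recomputed, and the pooled
null's 5th/95th percentiles serve as two-sided cutoffs (1000 permutations
by default). The percentile rule is the primary procedure; the shuffles
are within one selection's table. An unpaired variant of the analysis —
comparing the fitness distribution of all variants carrying a residue at
a position against the distribution for the wild-type residue there — is
provided as a consistency check; under a purely additive landscape its
mode shift equals the additive coefficient difference exactly.

# Additive model and epistasis

The additive model regresses combined fitness on per-position residue
indicators (reference-cell encoding; stop variants excluded, since stops
measure expression failure rather than interface energetics). Five-fold
cross-validation uses a seeded uniform random fold assignment without
stratification; held-out $R^2 = 1 - SSE/SST$ with SST about the held-out
mean, and final coefficients with standard errors come from the full-data
fit. Epistasis is reported as observed minus additive prediction, where
the prediction for a multi-mutant is the reference fitness plus the sum
of its constituent single-mutant deviations measured in the reference
background; variants with unmeasured constituent singles are skipped and
counted.

# The synthetic generator

`simulateExperiment()` generates the study conditions end to end: a true
landscape per selection, a shared log-normal pre-selection library
($\sigma = 0.5$), deterministic growth re-weighting, and independent
multinomial read sampling per replicate and timepoint.

* **Landscape.** True fitness is $1 + \sum_p c(p, v_p)$ plus optional
  pairwise epistatic terms and $N(0, 0.05)$ noise. Coefficients for
  non-reference residues are drawn from $N(-0.3, 0.35)$: predominantly
  deleterious, leaving roughly a quarter of variants above half-maximal
  fitness, the regime the motivating selections display. Stops are 0 and
  the reference is exactly 1.
* **Rectification.** By default the landscape is clamped at the stop
  baseline (`fitnessFloor = 0`). The growth model weighs frequencies by
  $A^{\max(W,0)}$ — toxin-arrested cells do not shrink — so fitness below
  the stop baseline is unidentifiable in this assay; defining the truth
  on the same rectified scale keeps "truth" equal to what a perfect
  instrument could measure. Exactly-additive analyses (coefficient
  recovery, epistasis oracles) disable the floor with
  `fitnessFloor = -Inf`, because rectification would itself inject
  spurious epistasis.
* **Selection.** $f_{post} \propto f_{pre} \cdot A^{\max(W,0)}$ with
  $A = 50$: a fully rescuing variant expands 50-fold against a dead one
  over the selection window, consistent with the order of magnitude of
  wild-type enrichment and stop de-enrichment such competitions show.
* **Sampling.** Multinomial reads at `5e6` per sample, two replicates.
  Read emission (for exercising the extraction path) places each variant
  on a uniformly random NNK synonym, a random 4-6-nt spacer and the
  sample barcode; with zero error rate extraction round-trips exactly.

What the generator does *not* emulate: PCR jackpots and bottlenecks,
sequencing error beyond a uniform base-substitution option, codon-usage
bias, growth-curve dynamics (only the pre/post ratio is identified by the
assay, so an exponential weight is sufficient), and replicate-level
biological drift. Passing tests therefore demonstrate correctness of the
estimators under multinomial sampling noise and the stated growth model,
not robustness to those artefacts in real libraries.

# Problem sizes and Monte-Carlo design in the test-suite

The packaged checks run the full 9261-variant library at a depth of
`5e6` reads per sample where end-to-end recovery is asserted, and `1e6`
for general fixtures. Permutation calibration uses the position-1
substitution cells (342 ordered pairs) with a 150-200-shuffle null, and
averages the observed two-sided rate over several independent label
shuffles: cells within one shuffle are positively correlated, so a
single-shuffle rate has variance well above the naive binomial bound, and
averaging over shuffles (cheap) rather than nulls (expensive) restores
precision honestly. Monte-Carlo tolerances for the skew-normal
generate-and-refit oracle are 4 standard errors of the estimator spread
measured at the study's profile size ($n = 361$).

# Known limitations

* Fitness below the stop baseline is unidentifiable; rectified truth is a
  modelling choice, not a measurement.
* The permutation null pools modes across substitution cells, as the
  percentile-cutoff procedure prescribes; a per-cell empirical p-value
  with Benjamini-Hochberg correction would be a natural extension.
* The additive model is first-order by design; diminishing-returns
  curvature at the top of the fitness range shows up as reduced held-out
  $R^2$ rather than being modelled by a nonlinear link.
* Time-series (multi-timepoint) estimators, UMI handling and read-quality
  filtering are out of scope.
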