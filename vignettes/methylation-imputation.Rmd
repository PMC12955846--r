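---
title: "Imputing sporadic and systematic missingness in methylation beta matrices"
author: "morelimpute"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imputing sporadic and systematic missingness in methylation beta matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morelimpute)
```

## The problem

Illumina methylation arrays have evolved through several generations
(27K, 450K, EPIC 850K, EPIC v2 935K), each dropping a substantial set of
probes carried by its predecessors. When cohorts measured on different
generations are merged into one beta-value matrix (rows = CpGs, columns =
samples), the dropped probes are missing for *every* sample of one
platform. This *systematic* (structural) missingness is
missing-by-design, not missing-at-random: no amount of within-group
information can recover it, and classical imputers either fail to
converge or fall back on uninformative row statistics. The same
structure appears when integrating arrays with sequencing assays (RRBS)
that cover a different CpG universe.

`morelimpute` separates the two regimes. Randomly scattered (sporadic)
holes — failed probes, QC masking — are filled with standard imputers.
Whole-group (systematic) holes are treated as a supervised multi-output
problem: CpGs observed in both groups are training instances mapping one
group's beta vector to the other's, and a direction-specific model
predicts the missing block. Because methylation is strongly correlated
across samples at a CpG (and the two groups measure the same biology),
this mapping is learnable even at 50% structural missingness.

## The pipeline and its assumptions

1. **Group assignment** clusters samples with K-means (K = 2, 10 random
   restarts, best inertia, fixed seed) on binarized presence/absence
   vectors. The assumption is that exactly two platforms are mixed; more
   than two require iterative pairing, which is out of scope. If every
   sample shows the same pattern the clustering is degenerate and the
   package demands explicit labels.
2. **Categorization** is exact, not statistical: a CpG is group-specific
   only when *all* samples of that group are missing, because array
   incompatibility removes a probe from every sample run on that array.
   The boundary case "missing in all of A and sporadically in B" is
   classed A-specific; the B-side holes are filled in the sporadic stage
   restricted to B's columns. All-missing CpGs are dropped by default
   (`keep_all_missing = TRUE` retains them untouched).
3. **Sporadic fill** runs per group side so that group-specific rows
   (entirely absent on one side) never poison a row-wise imputer. The
   statistical imputers (EM, Buck, chained regression, random forest,
   KNN variants) treat samples as variables and CpGs as observations:
   methylation matrices have orders of magnitude more CpGs than samples,
   which makes sample-space models well posed. This orientation also
   matches the multi-output formulation of stage 4.
4. **MOREL fill** trains, by default, on all CpGs complete after the
   sporadic stage (maximizing training data); `strict = TRUE` restricts
   training to CpGs that never had a hole, for users worried about
   error propagation from stage 3.

## Learners and tunable parameters

| learner | implementation | defaults |
|---|---|---|
| `rf` | one `ranger` forest per target sample | 100 trees |
| `svr` | linear ε-insensitive SVR per target, fitted by iteratively reweighted ridge least squares | C = 1, ε = 0 |
| `knn` | natively multi-target: averages the Y-rows of the k nearest training X-rows | k = 5, unweighted |
| `dnn` | one network: input width = source samples, one ReLU hidden layer of width round((n_in + n_out)/2) (half-up, minimum 1), he-uniform initialisation, linear output | squared-error loss, Adam, learning rate 1e-3, 100 epochs, batch 256 |

The SVR solver deserves a note: with ε = 0 the objective is
L2-penalised least-absolute-deviation regression, which the
majorize-minimize iteration solves to high precision in a handful of
weighted ridge solves; with 16-dimensional inputs this is orders of
magnitude faster than an SMO-based solver at thousands of training CpGs
and has no tuning beyond C. The network's training regime (loss,
optimizer, epochs, batch size) is exposed in `morel_config()`; at these
settings convergence is deliberately conservative — at like-for-like
hyperparameters it tracks scikit-learn's `MLPRegressor` — and the
forest or SVR learner is usually the better default on small cohorts.

Every prediction is clipped to [0, 1]: beta values are proportions, and
clipping is applied uniformly after every imputer in the package.

Sporadic-stage parameters of note: KNN uses Euclidean distance over
mutually observed columns scaled by the number of shared columns (so
rows with different overlap are comparable) and inverse-distance weights
1/(d + 1e-9) in weighted mode; the moving window is centered, of odd
width, truncated at edges, with an all-missing window falling back to
the row mean; EM adds a ridge of 1e-6·trace/p to a near-singular
covariance and stops at a 1e-4 parameter change or 100 iterations;
SoftImpute's shrinkage defaults to 0.1 × the largest singular value of
the mean-filled matrix; truncated-SVD completion defaults to rank
min(10, min(dim) − 1); the nuclear-norm variant is a
singular-value-thresholding proximal iteration — an approximation of the
exact convex program — and is capped at 500 × 500 inputs.

## The synthetic benchmark generator

`simulate_beta_matrix()` emulates the two-array evaluation design used
throughout the package's tests: two groups of samples (default 15/15)
measuring the same CpGs, with structural missingness injected into a
configurable fraction of CpGs (the benchmark tiers are 10/30/50%,
and masking 50% of CpGs in one of two equal groups yields exactly 25%
missing cells overall) plus independent per-cell sporadic holes.

Each CpG draws a latent mean uniformly within one of the four beta tiers
([0, 0.25), [0.25, 0.5), [0.5, 0.75), [0.75, 1]) with bimodal default
proportions (0.4, 0.1, 0.1, 0.4), reflecting the concentration of array
betas near 0 and 1. Cell values add noise on the logit scale and map
back through the inverse logit: this keeps betas in (0, 1) without
clipping and automatically shrinks variance near the extremes, so
consistently (un)methylated CpGs vary less across samples — the pattern
real data show. A per-tier scale (0.7× outer, 1.3× inner tiers)
reinforces it. `noise_sd` is calibrated so that a mid-range CpG has
roughly that per-cell standard deviation on the beta scale (default
0.03).

Two further components make the generator honest about what the
learners exploit:

* **Cross-group offsets.** Each CpG receives independent per-group
  offsets scaled by √(1 − ρ) (`cross_group_correlation`, default 0.95).
  They are irreducible from the other group's perspective and set the
  noise floor of any cross-group imputer.
* **A latent per-sample factor.** One loading per sample and one
  coefficient per CpG add sample-level covariance of the kind real
  cohorts always carry (cell-type composition, tumour purity). This
  term is what separates multi-output learners from row statistics: a
  row mean predicts the same value for every target sample and misses
  the factor entirely, while the multi-output map recovers each target
  sample's position on it. Without such structure — i.e. with purely
  independent per-sample noise — the conditional expectation of a
  target cell given the source vector collapses to (a shrinkage of) the
  source average, and *no* learner can systematically beat row-mean
  fill; benchmarks built on such generators say nothing about real
  data. Conversely, the generator has a *single* factor, so only the
  first principal component of the samples carries structure;
  concordance of PC2 and beyond between imputed and observed CpGs is
  near the null and should not be over-read.

What the generator does *not* emulate: probe-chemistry (Infinium I/II)
effects, batch effects, SNP-affected probes, co-methylation that decays
with genomic distance, and multi-modal sample structure. Passing tests
therefore demonstrate correctness of the machinery and the expected
ordering of methods under realistic marginal distributions, not
real-data error levels.

## Numerical and design choices

* **Orientation.** CpGs are rows, samples are columns, matching GEO
  series matrices; readers reject values outside [0, 1] and duplicate
  identifiers. Values exactly 0 or 1 are legal betas, not sentinels.
  Annotation positions are 1-based (manifest convention); 0-based
  BED-style input is deliberately not accepted.
* **Tier boundaries** are left-closed with the last tier closed at 1, so
  a mean beta of exactly 0.25 falls in the second tier.
* **Welch t-tests** (unequal variances) with Benjamini–Hochberg
  adjustment select differential CpGs; the equal-variance test and other
  adjustments were not considered further since the stress test only
  needs a defensible selection, not an inferential claim.
* **PCA concordance** compares components by index and reports |r|,
  because eigenvector sign is arbitrary.
* **Determinism.** Every stochastic component (K-means restarts, random
  draws, forest fitting, factorization initialisation, network training,
  missingness injection) is driven by an explicit seed; forests run
  single-threaded so results are bit-reproducible. Derived stage seeds
  are kept below 2^31.
* **Degenerate inputs.** Rows with no observed value are an error for
  row-statistic fills ("uninformative row"); directional fills leave
  unreachable leading/trailing cells missing with a warning; Buck's
  method requires at least two complete-case rows and falls back to
  minimum-norm least squares on rank-deficient designs; EM and the
  completion methods return their last iterate with a warning when the
  iteration cap is hit.
* **Chromosome splitting.** `split_by_chromosome()` partitions an
  annotated matrix so the pipeline can run per chromosome; groups and
  categories are computed per piece, and the pieces concatenate back to
  the original CpG set. This bounds memory and time on full-array
  matrices without changing within-chromosome results.

## Problem sizes used in the test suite

The suite exercises the full pipeline at 2000–5000 CpGs × 30 samples
(ten replicates for the accuracy-band and ranking checks) and the
imputer-suite invariants at 500 × 20 — sizes at which every property of
interest (exact missingness arithmetic, group recovery, the [σ/2, 3σ]
recovery band at ρ = 0.95 and σ = 0.03, tier ordering, method ranking)
is already stable across seeds. The same design at full array scale
(450K–935K CpGs) only grows the training sets; the per-chromosome
splitter is the intended route there.

## Known limitations

* Exactly two groups; three-way integration needs iterative pairing.
* Single imputation only: no posterior draws, no pooled-variance
  (Rubin) inference, no uncertainty on imputed cells.
* The nuclear-norm solver is an approximation, not an exact
  interior-point solution.
* Genomic context (CpG islands, cCREs, probe distance) is not used as a
  feature; the learners see only cross-sample structure.
* SoftImpute and truncated-SVD completion with default shrinkage/rank
  can trail the row-mean baseline on strongly bimodal beta data — the
  poorest performers among the standard methods in our benchmarks as in
  published ones; prefer Buck, EM, KNN or chained regression for the
  sporadic stage.
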