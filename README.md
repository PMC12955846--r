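# morelimpute

Two-stage imputation of missing values in DNA methylation beta-value
matrices, with multi-output regression and learning (MOREL) for the
*systematic* missingness that arises when data from different Illumina
array generations (27K, 450K, EPIC 850K, EPIC v2 935K) — or from an array
and a sequencing assay such as RRBS — are integrated. Newer arrays drop
many probes carried by older ones, so in a merged matrix whole blocks of
CpGs are missing for *every* sample run on one platform. Classical
imputers assume missingness at random and degrade badly on such
structured holes; `morelimpute` treats them as a joint prediction problem
instead.

Intended users: epigenomics analysts merging methylation cohorts across
array versions or platforms, and methodologists benchmarking imputation
methods on beta-value (β ∈ [0, 1]) matrices.

## Method

For a matrix **B** (rows = CpG probes, columns = samples) the pipeline
runs four steps:

1. **Group assignment.** The matrix is binarized (1 = observed,
   0 = missing) and samples are clustered with K-means (K = 2) on their
   probe presence/absence vectors, recovering the array of origin;
   user-supplied labels override clustering.
2. **CpG categorization.** Each CpG is *non-missing*, *sporadic*,
   *A-specific* (missing in every group-A sample), *B-specific*, or
   *all-missing*.
3. **Sporadic fill.** Randomly scattered holes are filled with a standard
   imputer. Fifteen methods are implemented: trend statistics
   (mean/median/min/max/bfill/ffill), random draws, moving-window means,
   (weighted) K-nearest neighbours, reference-panel KNN,
   multivariate-normal EM, Buck's method, nuclear-norm / SoftImpute /
   truncated-SVD / factorization matrix completion, chained regression,
   and iterative random forests.
4. **MOREL fill.** For A-specific CpGs, the CpGs observed in both groups
   form a training set \(\{(x_g, y_g)\}\) with
   \(x_g \in \mathbb{R}^{n_B}\) (group-B betas) and
   \(y_g \in \mathbb{R}^{n_A}\); a direction-specific multi-output model
   \(\hat f: \mathbb{R}^{n_B} \to \mathbb{R}^{n_A}\) — random forest,
   linear SVR, K-nearest neighbours, or a one-hidden-layer neural network
   (hidden width = round((n_in + n_out)/2), ReLU, he-uniform
   initialisation, linear output) — predicts the missing group-A betas
   from the observed group-B betas. B-specific CpGs are handled
   symmetrically. Predictions are clipped to [0, 1]; observed cells are
   never altered.

Accuracy is scored over masked-then-imputed cells with

MAE = (1/n) Σ |y − ŷ|,  RAE = Σ|y − ŷ| / Σ|y − ȳ|,
RMSE = √((1/n) Σ (y − ŷ)²),  R² = 1 − SS_res / SS_tot,

optionally stratified by each CpG's mean-beta tier ([0, 0.25), [0.25,
0.5), [0.5, 0.75), [0.75, 1]), on differentially methylated CpGs (Welch
t-tests, BH-adjusted), or via the concordance of sample-space principal
components computed from imputed-only versus observed-only CpGs.

A seeded synthetic generator emulates two-group array data — bimodal beta
values with tier-dependent variance, cross-group correlation ρ, a latent
per-sample factor, and configurable structural (10/30/50% of CpGs) and
sporadic missingness — so the whole pipeline is testable without any
download.

## Worked example

```r
library(morelimpute)

cfg   <- simulation_config(n_cpgs = 2000, n_samples_a = 15,
                           n_samples_b = 15, seed = 42)
beta  <- simulate_beta_matrix(cfg)
truth <- attr(beta, "true_groups")

# remove 50% of CpGs from group A (25% of all cells), plus 1% sporadic holes
st <- inject_structural_missing(beta, truth, fraction = 0.5,
                                target_group = "A", seed = 1)
sp <- inject_sporadic_missing(st$matrix, rate = 0.01, seed = 2)
sp$matrix
#> BetaMatrix: 2000 CpGs x 30 samples, 15489 missing (25.82%), annotated

res <- impute_pipeline(sp$matrix, sporadic_method = "knn",
                       morel_config = morel_config("svr", seed = 3),
                       seed = 3)
#> categories: non_missing=727 sporadic=273 a_specific=1000 b_specific=0 all_missing=0

masked <- rbind(st$truth, sp$truth)
compute_metrics(masked$value, truth_values(res$matrix, masked))
#> EvaluationReport (n=15489): MAE=0.02234 RAE=0.06944 RMSE=0.0308 R2=0.9921
```

The pipeline clustered the samples into the two 15-sample groups from
their presence/absence patterns, filled the 273 sporadic CpGs with
row-space KNN, trained a B→A multi-output linear SVR on the CpGs complete
in both groups, and recovered the 15,489 masked cells with a mean
absolute error of 0.022 on the beta scale — explaining 99.2% of their
variance.

A command-line wrapper is installed as `exec/morelimpute` with
`simulate`, `impute` and `evaluate` subcommands over the same functions.

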