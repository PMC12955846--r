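# Synthetic two-array methylation data: beta values concentrated near 0
# and 1, tier-dependent variance, cross-group correlation, a latent
# per-sample factor emulating sample-level heterogeneity (cell
# composition, tumour purity), and injection of the structural and
# sporadic missingness patterns used for benchmarking.

#' Configuration of the synthetic beta-matrix generator
#'
#' @param n_cpgs number of CpG rows
#' @param n_samples_a,n_samples_b samples per group
#' @param tier_proportions fractions of CpGs whose latent mean falls in
#'   the four beta tiers \[0,0.25), \[0.25,0.5), \[0.5,0.75), \[0.75,1\];
#'   must sum to 1. The bimodal default reflects the concentration of
#'   array beta values near 0 and 1.
#' @param cross_group_correlation rho in \[0,1\]: group-level offsets are
#'   scaled by sqrt(1 - rho), so rho = 1 removes any systematic
#'   between-group difference
#' @param noise_sd sigma, the approximate beta-scale per-cell noise at a
#'   mid-range CpG (default 0.03)
#' @param sample_effect relative magnitude of the latent per-sample factor
#'   (0 disables it; default 1 = comparable to the per-cell noise)
#' @param seed integer seed
#' @return list of class `SimulationConfig`
#' @export
simulation_config <- function(n_cpgs = 1000L, n_samples_a = 15L,
                              n_samples_b = 15L,
                              tier_proportions = c(0.4, 0.1, 0.1, 0.4),
                              cross_group_correlation = 0.95,
                              noise_sd = 0.03, sample_effect = 1,
                              seed = 1L) {
  if (n_cpgs < 1 || n_samples_a < 1 || n_samples_b < 1)
    stopf("counts must be >= 1")
  if (length(tier_proportions) != 4 || any(tier_proportions < 0) ||
      abs(sum(tier_proportions) - 1) > 1e-9)
    stopf("tier_proportions must be 4 nonnegative fractions summing to 1")
  if (cross_group_correlation < 0 || cross_group_correlation > 1)
    stopf("cross_group_correlation must be in [0, 1]")
  if (noise_sd <= 0) stopf("noise_sd must be > 0")
  structure(list(n_cpgs = as.integer(n_cpgs),
                 n_samples_a = as.integer(n_samples_a),
                 n_samples_b = as.integer(n_samples_b),
                 tier_proportions = tier_proportions,
                 cross_group_correlation = cross_group_correlation,
                 noise_sd = noise_sd, sample_effect = sample_effect,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Simulate a methylation-like beta matrix for two sample groups
#'
#' Each CpG draws a latent mean uniformly within a beta tier chosen by
#' `tier_proportions`. Cell values are the latent mean plus logit-scale
#' noise mapped back to (0, 1): the inverse-logit mapping needs no
#' clipping and automatically concentrates variance mid-range, so
#' consistently unmethylated or methylated CpGs vary less across samples.
#' Per-tier noise scaling (0.7x for the outer tiers, 1.3x for the inner
#' ones) reinforces that pattern. Cross-group correlation `rho` is induced
#' by sharing the latent mean while adding per-group offsets scaled by
#' sqrt(1 - rho), and a latent per-sample factor (loading per sample,
#' coefficient per CpG) adds the sample-level covariance real cohorts
#' show. Deterministic under the configured seed.
#'
#' @param config a [simulation_config()]
#' @return a `BetaMatrix` with samples `A01..` / `B01..`, a chromosome
#'   annotation (CpGs dealt round-robin across 20 chromosomes), and the
#'   true group labels in attribute `"true_groups"`.
#' @export
simulate_beta_matrix <- function(config = simulation_config()) {
  stopifnot(inherits(config, "SimulationConfig"))
  n <- config$n_cpgs
  na_ <- config$n_samples_a; nb_ <- config$n_samples_b
  ns <- na_ + nb_
  rho <- config$cross_group_correlation
  sigma <- config$noise_sd
  with_seed(config$seed, {
    tier <- sample.int(4L, n, replace = TRUE,
                       prob = config$tier_proportions)
    lo <- c(0, 0.25, 0.5, 0.75)[tier]
    mu <- stats::runif(n, lo, lo + 0.25)
    tier_scale <- c(0.7, 1.3, 1.3, 0.7)[tier]
    # logit-scale sd giving ~ sigma * tier_scale on the beta scale
    slope <- pmin(pmax(mu * (1 - mu), 0.05), 0.25)
    sd_l <- sigma * tier_scale / slope
    s_load <- stats::rnorm(ns)                    # per-sample factor
    b_coef <- stats::rnorm(n, 0, sd_l) * config$sample_effect
    u_a <- stats::rnorm(n, 0, sd_l) * sqrt(1 - rho)
    u_b <- stats::rnorm(n, 0, sd_l) * sqrt(1 - rho)
    e <- array(stats::rnorm(n * ns), dim = c(n, ns)) * sd_l
    grp_off <- cbind(array(u_a, dim = c(n, na_)),
                     array(u_b, dim = c(n, nb_)))
    z <- stats::qlogis(mu) + outer(b_coef, s_load) + grp_off + e
    beta <- stats::plogis(z)
    ids <- sprintf("cg%07d", seq_len(n))
    samples <- c(sprintf("A%02d", seq_len(na_)),
                 sprintf("B%02d", seq_len(nb_)))
    dimnames(beta) <- list(ids, samples)
    ann <- data.frame(cpg_id = ids,
                      chrom = paste0("chr", ((seq_len(n) - 1) %% 20) + 1),
                      position = seq_len(n) * 1000L,
                      stringsAsFactors = FALSE)
    out <- beta_matrix(beta, annotation = ann)
    attr(out, "true_groups") <- stats::setNames(
      rep(c("A", "B"), c(na_, nb_)), samples)
    out
  })
}

#' Inject structural (group-specific) missingness
#'
#' Removes all values of the target group's samples at a uniformly chosen
#' fraction of CpGs, emulating probes absent from one array generation.
#'
#' @param matrix a complete (or partially observed) beta matrix
#' @param groups a [`GroupAssignment`][assign_groups] or named label
#'   vector
#' @param fraction fraction of CpGs to mask (floor(fraction * n) CpGs)
#' @param target_group label of the group losing its values
#' @param seed integer seed
#' @return list with `matrix` (masked) and `truth`, a `data.frame`
#'   (cpg_id, sample_id, value) of the removed cells
#' @export
inject_structural_missing <- function(matrix, groups, fraction,
                                      target_group = "A", seed = 1L) {
  if (fraction < 0 || fraction > 1) stopf("fraction must be in [0, 1]")
  labels <- if (inherits(groups, "GroupAssignment")) groups$labels else groups
  cols <- names(labels)[labels == target_group]
  if (length(cols) == 0) stopf("no sample carries label '%s'", target_group)
  m <- unclass(matrix)
  n_pick <- floor(fraction * nrow(m))
  picked <- with_seed(seed, sort(sample.int(nrow(m), n_pick)))
  ids <- rownames(m)[picked]
  sub <- m[ids, cols, drop = FALSE]
  keep <- !is.na(sub)
  truth <- data.frame(
    cpg_id = rep(ids, times = length(cols))[as.vector(keep)],
    sample_id = rep(cols, each = length(ids))[as.vector(keep)],
    value = as.vector(sub)[as.vector(keep)],
    stringsAsFactors = FALSE)
  m[ids, cols] <- NA_real_
  list(matrix = restore_beta(matrix, m), truth = truth)
}

#' Inject sporadic missingness
#'
#' Masks each currently observed cell independently with probability
#' `rate`; never touches already-missing cells.
#'
#' @inheritParams inject_structural_missing
#' @param rate per-cell missing probability in \[0, 1)
#' @return list with `matrix` and `truth` as in
#'   [inject_structural_missing()]
#' @export
inject_sporadic_missing <- function(matrix, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stopf("rate must be in [0, 1)")
  m <- unclass(matrix)
  obs <- which(!is.na(m))
  hit <- with_seed(seed, obs[stats::runif(length(obs)) < rate])
  idx <- arrayInd(hit, dim(m))
  truth <- data.frame(cpg_id = rownames(m)[idx[, 1]],
                      sample_id = colnames(m)[idx[, 2]],
                      value = m[hit],
                      stringsAsFactors = FALSE)
  m[hit] <- NA_real_
  list(matrix = restore_beta(matrix, m), truth = truth)
}

#' Extract imputed values for the cells of a truth record
#'
#' @param matrix an imputed beta matrix
#' @param truth a truth `data.frame` from the inject functions
#' @return numeric vector aligned with `truth$value`
#' @export
truth_values <- function(matrix, truth) {
  m <- unclass(matrix)
  m[cbind(match(truth$cpg_id, rownames(m)),
          match(truth$sample_id, colnames(m)))]
}
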