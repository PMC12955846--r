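# Accuracy metrics and evaluation designs: overall and tier-stratified
# error, differential-CpG selection, and principal-component concordance.

#' Imputation accuracy metrics
#'
#' Computes, over cells that were masked and then imputed:
#' MAE = mean(|y - yhat|); RAE = sum(|y - yhat|) / sum(|y - mean(y)|);
#' RMSE = sqrt(mean((y - yhat)^2)); R2 = 1 - SS_res / SS_tot with
#' SS_res = sum((y - yhat)^2) and SS_tot = sum((y - mean(y))^2).
#'
#' @param actual numeric vector of true (pre-masking) values
#' @param imputed numeric vector of imputed values, same length
#' @return list of class `EvaluationReport` with `mae`, `rae`, `rmse`,
#'   `r2`, `n`. A constant `actual` vector leaves RAE and R2 undefined;
#'   they are reported as `NaN` with a warning.
#' @export
compute_metrics <- function(actual, imputed) {
  if (length(actual) != length(imputed))
    stopf("actual and imputed must have equal length")
  if (length(actual) < 2) stopf("need at least 2 evaluated cells")
  if (anyNA(actual) || anyNA(imputed))
    stopf("metrics are computed over imputed cells; no NA allowed")
  err <- actual - imputed
  dev <- actual - mean(actual)
  ss_tot <- sum(dev^2)
  mae <- mean(abs(err))
  rmse <- sqrt(mean(err^2))
  if (ss_tot == 0) {
    warnf("constant actual vector; RAE and R2 are undefined")
    rae <- NaN; r2 <- NaN
  } else {
    rae <- sum(abs(err)) / sum(abs(dev))
    r2 <- 1 - sum(err^2) / ss_tot
  }
  structure(list(mae = mae, rae = rae, rmse = rmse, r2 = r2,
                 n = length(actual)),
            class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat(sprintf("EvaluationReport (n=%d): MAE=%.4g RAE=%.4g RMSE=%.4g R2=%.4g\n",
              x$n, x$mae, x$rae, x$rmse, x$r2))
  invisible(x)
}

#' Stratify masked CpGs by their original mean beta value
#'
#' Tiers are \[0, 0.25), \[0.25, 0.5), \[0.5, 0.75), \[0.75, 1\] on each
#' CpG's mean original beta across samples (left-closed; the last tier is
#' closed at 1). The tiers partition the masked CpGs.
#'
#' @param actual_matrix the original (pre-masking) beta matrix
#' @param masked_cpgs character vector of masked CpG ids
#' @return named list of four character vectors (`tier1` .. `tier4`)
#' @export
stratify_by_mean_beta <- function(actual_matrix, masked_cpgs) {
  m <- unclass(actual_matrix)
  mb <- rowMeans(m[masked_cpgs, , drop = FALSE], na.rm = TRUE)
  tier <- findInterval(mb, c(0, 0.25, 0.5, 0.75), rightmost.closed = FALSE)
  tier[mb >= 1] <- 4L
  out <- lapply(1:4, function(k) masked_cpgs[tier == k])
  names(out) <- paste0("tier", 1:4)
  out
}

#' Select differentially methylated CpGs between the two groups
#'
#' Per-CpG Welch (unequal-variance) two-sample t-tests on the original
#' beta values, Benjamini-Hochberg adjusted; CpGs with adjusted p below
#' `alpha` are returned. These are the hardest loci to impute from the
#' other group.
#'
#' @param matrix original beta matrix
#' @param groups a [`GroupAssignment`][assign_groups]
#' @param alpha adjusted-p threshold (default 0.05)
#' @return character vector of CpG ids
#' @export
select_differential_cpgs <- function(matrix, groups, alpha = 0.05) {
  lev <- group_levels(groups)
  m <- unclass(matrix)
  a <- m[, colnames(m) %in% group_samples(groups, lev[1]), drop = FALSE]
  b <- m[, colnames(m) %in% group_samples(groups, lev[2]), drop = FALSE]
  if (ncol(a) < 2 || ncol(b) < 2)
    stopf("each group needs >= 2 samples for a t-test")
  na_ <- rowSums(!is.na(a)); nb_ <- rowSums(!is.na(b))
  ma <- rowMeans(a, na.rm = TRUE); mb <- rowMeans(b, na.rm = TRUE)
  va <- rowSums((a - ma)^2, na.rm = TRUE) / pmax(na_ - 1, 1)
  vb <- rowSums((b - mb)^2, na.rm = TRUE) / pmax(nb_ - 1, 1)
  se2 <- va / na_ + vb / nb_
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na_)^2 / pmax(na_ - 1, 1) +
                   (vb / nb_)^2 / pmax(nb_ - 1, 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[!is.finite(p)] <- 1
  padj <- stats::p.adjust(p, method = "BH")
  rownames(m)[padj < alpha]
}

#' Concordance of principal components between two matrices
#'
#' Sample-space PCA (CpGs as features, centered, unscaled) is run
#' separately on each matrix; the absolute Pearson correlation between
#' matched component scores is returned. The absolute value is taken
#' because eigenvector signs are arbitrary. Typical use: components from
#' imputed-only CpGs versus components from originally observed CpGs.
#'
#' @param reference_matrix,comparison_matrix beta matrices over the same
#'   samples (CpG sets may differ)
#' @param n_components number of leading components to compare
#' @return numeric vector of absolute correlations, one per component
#' @export
pca_concordance <- function(reference_matrix, comparison_matrix,
                            n_components = 2L) {
  rm_ <- unclass(reference_matrix); cm_ <- unclass(comparison_matrix)
  if (!setequal(colnames(rm_), colnames(cm_)))
    stopf("both matrices must cover the same samples")
  cm_ <- cm_[, colnames(rm_), drop = FALSE]
  n <- ncol(rm_)
  if (n <= n_components)
    stopf("need more samples (%d) than components (%d)", n, n_components)
  if (anyNA(rm_) || anyNA(cm_))
    stopf("PCA requires complete matrices; impute or subset first")
  sc_r <- stats::prcomp(t(rm_), center = TRUE, scale. = FALSE)$x
  sc_c <- stats::prcomp(t(cm_), center = TRUE, scale. = FALSE)$x
  k <- min(n_components, ncol(sc_r), ncol(sc_c))
  sapply(seq_len(k), function(i) abs(stats::cor(sc_r[, i], sc_c[, i])))
}
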