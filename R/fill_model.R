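# Model-based imputers. All of them treat samples as variables and CpGs
# as observations: methylation matrices have vastly more CpG rows than
# sample columns, so models over the sample space are well posed.

# rows of `na` grouped by identical missingness pattern
missing_patterns <- function(na) {
  key <- apply(na, 1L, function(z) paste(as.integer(z), collapse = ""))
  split(seq_len(nrow(na)), key)
}

# conditional mean/covariance machinery shared by EM and Buck
cond_predict <- function(x_obs, mu, sigma, O, M, ridge_tol = 1e-10) {
  soo <- sigma[O, O, drop = FALSE]
  smo <- sigma[M, O, drop = FALSE]
  sol <- tryCatch(solve(soo, t(x_obs) - mu[O]),
                  error = function(e) NULL)
  if (is.null(sol)) {
    # rank-deficient observed block: minimum-norm solution via pseudoinverse
    sv <- svd(soo)
    pos <- sv$d > max(sv$d) * ridge_tol
    inv <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    sol <- inv %*% (t(x_obs) - mu[O])
    attr(sol, "pinv") <- TRUE
  }
  pred <- t(smo %*% sol) + rep(mu[M], each = nrow(x_obs))
  pred
}

obs_loglik <- function(m, na, mu, sigma) {
  ll <- 0
  for (idx in missing_patterns(na)) {
    O <- which(!na[idx[1], ])
    if (length(O) == 0) next
    soo <- sigma[O, O, drop = FALSE]
    ch <- chol(soo)
    xc <- sweep(m[idx, O, drop = FALSE], 2L, mu[O])
    z <- backsolve(ch, t(xc), transpose = TRUE)
    ll <- ll - 0.5 * (length(idx) * (length(O) * log(2 * pi) +
                                       2 * sum(log(diag(ch)))) + sum(z^2))
  }
  ll
}

#' Impute missing values with multivariate-normal EM
#'
#' Samples are the variables of a multivariate normal, CpG rows its
#' observations. The algorithm alternates conditional expectation of the
#' missing cells given the observed cells and the current mean/covariance
#' with re-estimation of mean and covariance (maximum-likelihood, divisor
#' n), until the largest absolute parameter change drops below `tol` or
#' `max_iter` is reached. Missing cells are replaced by their final
#' conditional means, clipped to \[0, 1\].
#'
#' @inheritParams fill_trend
#' @param tol convergence tolerance on the parameters (default 1e-4)
#' @param max_iter iteration cap (default 100)
#' @param seed unused (the algorithm is deterministic); kept for
#'   interface uniformity
#' @return imputed matrix; attribute `"em_info"` records iterations, the
#'   observed-data log-likelihood trace and whether ridge stabilisation of
#'   a near-singular covariance was needed.
#' @export
fill_em <- function(matrix, tol = 1e-4, max_iter = 100L, seed = NULL) {
  m <- unclass(matrix)
  na <- is.na(m)
  if (!any(na)) return(matrix)
  p <- ncol(m)
  if (any(rowSums(!na) == 0))
    stopf("uninformative row (no observed value)")
  mfill <- m
  cm <- colMeans(m, na.rm = TRUE)
  for (j in seq_len(p)) mfill[na[, j], j] <- cm[j]
  mu <- colMeans(mfill)
  sigma <- crossprod(sweep(mfill, 2L, mu)) / nrow(m)
  ridged <- FALSE
  pats <- missing_patterns(na)
  ll_trace <- numeric(0)
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    # guard against singular observed blocks
    if (rcond_est(sigma) < 1e-12) {
      sigma <- sigma + diag(1e-6 * sum(diag(sigma)) / p, p)
      if (!ridged) warnf("near-singular covariance; ridge-stabilized")
      ridged <- TRUE
    }
    ll_trace <- c(ll_trace, tryCatch(obs_loglik(m, na, mu, sigma),
                                     error = function(e) NA_real_))
    xc <- m
    cmat <- array(0, dim = c(p, p))
    for (idx in pats) {
      M <- which(na[idx[1], ])
      if (length(M) == 0) next
      O <- which(!na[idx[1], ])
      xc[idx, M] <- cond_predict(m[idx, O, drop = FALSE], mu, sigma, O, M)
      soo <- sigma[O, O, drop = FALSE]
      smo <- sigma[M, O, drop = FALSE]
      cc <- sigma[M, M, drop = FALSE] - smo %*% solve(soo, t(smo))
      cmat[M, M] <- cmat[M, M] + length(idx) * cc
    }
    mu_new <- colMeans(xc)
    sigma_new <- crossprod(sweep(xc, 2L, mu_new)) / nrow(m) + cmat / nrow(m)
    delta <- max(abs(mu_new - mu), abs(sigma_new - sigma))
    mu <- mu_new; sigma <- sigma_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged)
    warnf("EM did not converge in %d iterations; returning last iterate",
          max_iter)
  out <- m
  for (idx in pats) {
    M <- which(na[idx[1], ])
    if (length(M) == 0) next
    O <- which(!na[idx[1], ])
    out[idx, M] <- cond_predict(m[idx, O, drop = FALSE], mu, sigma, O, M)
  }
  out[na] <- clip01(out[na])
  out <- restore_beta(matrix, out)
  attr(out, "em_info") <- list(iterations = iter, loglik = ll_trace,
                               converged = converged, ridged = ridged)
  out
}

rcond_est <- function(sigma) {
  ev <- tryCatch(range(eigen(sigma, symmetric = TRUE,
                             only.values = TRUE)$values),
                 error = function(e) c(0, 1))
  if (ev[2] <= 0) return(0)
  max(ev[1], 0) / ev[2]
}

#' Impute missing values with Buck's method
#'
#' Classic conditional-mean imputation: mean and covariance are estimated
#' from the complete-case CpG rows; each missing cell is then predicted by
#' the least-squares regression of its sample-column on that row's
#' observed columns, derived from the complete-case covariance. Equivalent
#' to fitting, for every missingness pattern, an ordinary least-squares
#' model on the complete cases and predicting from the row's observed
#' covariates.
#'
#' @inheritParams fill_trend
#' @return imputed matrix, predictions clipped to \[0, 1\].
#' @export
fill_buck <- function(matrix) {
  m <- unclass(matrix)
  na <- is.na(m)
  if (!any(na)) return(matrix)
  cc <- rowSums(na) == 0
  if (sum(cc) == 0)
    stopf("no complete-case row; pre-fill with a trend method first")
  if (sum(cc) < 2)
    stopf("need >= 2 complete-case rows to estimate a covariance")
  mu <- colMeans(m[cc, , drop = FALSE])
  sigma <- crossprod(sweep(m[cc, , drop = FALSE], 2L, mu)) / sum(cc)
  out <- m
  pinv_used <- FALSE
  for (idx in missing_patterns(na)) {
    M <- which(na[idx[1], ])
    if (length(M) == 0) next
    O <- which(!na[idx[1], ])
    if (length(O) == 0) stopf("uninformative row (no observed value)")
    pred <- cond_predict(m[idx, O, drop = FALSE], mu, sigma, O, M)
    if (isTRUE(attr(pred, "pinv"))) pinv_used <- TRUE
    out[idx, M] <- pred
  }
  if (pinv_used)
    warnf("rank-deficient design; used minimum-norm least squares")
  out[na] <- clip01(out[na])
  restore_beta(matrix, out)
}

#' Impute missing values by chained column-wise regression
#'
#' A deterministic single-chain analogue of chained-equations imputation:
#' missing cells are initialised with column means, then each incomplete
#' sample-column is regressed in round-robin on all other columns (using
#' the current completed matrix) and its missing cells re-predicted, until
#' the largest cell change drops below `tol` or `max_rounds` is reached.
#' No posterior draws are taken.
#'
#' @inheritParams fill_trend
#' @param max_rounds round-robin cap (default 10)
#' @param tol convergence tolerance on cell changes (default 1e-4)
#' @param seed unused (deterministic); kept for interface uniformity
#' @export
fill_iterative <- function(matrix, max_rounds = 10L, tol = 1e-4,
                           seed = NULL) {
  m <- unclass(matrix)
  na <- is.na(m)
  if (!any(na)) return(matrix)
  if (any(rowSums(!na) == 0))
    stopf("uninformative row (no observed value)")
  cm <- colMeans(m, na.rm = TRUE)
  cur <- m
  for (j in seq_len(ncol(m))) cur[na[, j], j] <- cm[j]
  incomplete <- which(colSums(na) > 0)
  converged <- FALSE
  for (round in seq_len(max_rounds)) {
    delta <- 0
    for (j in incomplete) {
      obs <- !na[, j]
      X <- cbind(1, cur[, -j, drop = FALSE])
      fit <- qr.coef(qr(X[obs, , drop = FALSE]), m[obs, j])
      fit[is.na(fit)] <- 0   # collinear columns contribute nothing
      pred <- X[na[, j], , drop = FALSE] %*% fit
      delta <- max(delta, max(abs(pred - cur[na[, j], j])))
      cur[na[, j], j] <- pred
    }
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warnf("chained imputation did not converge in %d rounds; %s",
          max_rounds, "returning last iterate")
  cur[na] <- clip01(cur[na])
  restore_beta(matrix, cur)
}

#' Impute missing values with iterative random forests
#'
#' MissForest-style: missing cells are mean-initialised; incomplete
#' sample-columns, visited in order of ascending missingness, are each
#' regressed on all other columns with a random forest trained on the rows
#' observed for that column, and their missing cells re-predicted. The
#' procedure stops when the normalised change in imputed values rises or
#' after `max_rounds` sweeps, returning the previous iterate in the former
#' case.
#'
#' @inheritParams fill_trend
#' @param n_trees trees per forest (default 100)
#' @param max_rounds sweep cap (default 10)
#' @param seed integer seed (forests are seeded and single-threaded, so
#'   results are reproducible)
#' @export
fill_rf <- function(matrix, n_trees = 100L, max_rounds = 10L, seed = 1L) {
  m <- unclass(matrix)
  na <- is.na(m)
  if (!any(na)) return(matrix)
  if (any(rowSums(!na) == 0))
    stopf("uninformative row (no observed value)")
  cm <- colMeans(m, na.rm = TRUE)
  cur <- m
  for (j in seq_len(ncol(m))) cur[na[, j], j] <- cm[j]
  incomplete <- order(colSums(na))
  incomplete <- incomplete[colSums(na)[incomplete] > 0]
  prev <- cur
  prev_change <- Inf
  for (round in seq_len(max_rounds)) {
    before <- cur
    for (ji in seq_along(incomplete)) {
      j <- incomplete[ji]
      obs <- !na[, j]
      xtr <- cur[obs, -j, drop = FALSE]
      colnames(xtr) <- paste0("v", seq_len(ncol(xtr)))
      fit <- ranger::ranger(x = as.data.frame(xtr), y = m[obs, j],
                            num.trees = n_trees,
                            seed = derive_seed(seed, round * 100 + ji),
                            num.threads = 1L)
      xte <- cur[na[, j], -j, drop = FALSE]
      colnames(xte) <- colnames(xtr)
      cur[na[, j], j] <- stats::predict(fit,
                                        data = as.data.frame(xte),
                                        num.threads = 1L)$predictions
    }
    change <- sum((cur[na] - before[na])^2) / max(sum(cur[na]^2), 1e-12)
    if (change > prev_change) { cur <- before; break }
    prev_change <- change
    if (change < 1e-6) break
  }
  cur[na] <- clip01(cur[na])
  restore_beta(matrix, cur)
}
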