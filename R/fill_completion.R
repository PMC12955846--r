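# Low-rank matrix completion fills: soft-thresholded SVD, rank-truncated
# SVD refinement, a singular-value-thresholding approximation of nuclear
# norm minimization, and alternating-ridge matrix factorization.

mean_fill <- function(m, na) {
  cm <- colMeans(m, na.rm = TRUE)
  cm[is.nan(cm)] <- mean(m, na.rm = TRUE)
  for (j in seq_len(ncol(m))) m[na[, j], j] <- cm[j]
  m
}

svd_shrink <- function(z, lambda) {
  s <- svd(z)
  d <- pmax(s$d - lambda, 0)
  keep <- d > 0
  if (!any(keep)) return(array(0, dim = dim(z)))
  s$u[, keep, drop = FALSE] %*% (d[keep] * t(s$v[, keep, drop = FALSE]))
}

svd_truncate <- function(z, rank) {
  s <- svd(z, nu = rank, nv = rank)
  s$u %*% (s$d[seq_len(rank)] * t(s$v))
}

#' Impute missing values by low-rank matrix completion
#'
#' Four related algorithms exploiting the approximately low-rank structure
#' of methylation matrices:
#' \describe{
#'   \item{softimpute}{iterative soft-thresholded SVD: fill, SVD, shrink
#'     every singular value by `shrinkage`, restore the observed entries,
#'     repeat to tolerance. Default `shrinkage` is 0.1 times the largest
#'     singular value of the mean-filled matrix.}
#'   \item{iterative_svd}{rank-`rank` truncated-SVD refinement of the
#'     missing entries (default rank `min(10, min(dim) - 1)`).}
#'   \item{nnm}{a singular-value-thresholding proximal iteration that
#'     approximates the nuclear-norm minimization program; an
#'     approximation, not an exact convex solver. Restricted to matrices
#'     within `max_dim` on each side.}
#'   \item{mf}{rank-`rank` factorization U V' fitted to the observed
#'     entries by alternating ridge least squares (seeded random
#'     initialisation).}
#' }
#' All outputs restore observed entries exactly and clip imputed cells to
#' \[0, 1\].
#'
#' @inheritParams fill_trend
#' @param method one of `"softimpute"`, `"iterative_svd"`, `"nnm"`, `"mf"`
#' @param rank target rank for `iterative_svd` and `mf`
#' @param shrinkage singular-value shrinkage for `softimpute` (and the
#'   threshold scale for `nnm`)
#' @param tol relative-change convergence tolerance
#' @param max_iter iteration cap
#' @param seed seed for the `mf` initialisation
#' @param max_dim per-side size cap for `nnm` (default 500)
#' @export
fill_matrix_completion <- function(matrix,
                                   method = c("softimpute", "iterative_svd",
                                              "nnm", "mf"),
                                   rank = NULL, shrinkage = NULL,
                                   tol = 1e-5, max_iter = 200L, seed = 1L,
                                   max_dim = 500L) {
  method <- match.arg(method)
  m <- unclass(matrix)
  na <- is.na(m)
  if (!any(na)) return(matrix)
  if (is.null(rank)) rank <- max(1L, min(10L, min(dim(m)) - 1L))
  z <- mean_fill(m, na)
  converged <- FALSE
  if (method == "nnm" && (nrow(m) > max_dim || ncol(m) > max_dim))
    stopf("nnm is restricted to matrices within %d x %d; got %d x %d",
          max_dim, max_dim, nrow(m), ncol(m))
  if (method %in% c("softimpute", "iterative_svd", "nnm")) {
    s1 <- svd(z, nu = 0, nv = 0)$d[1]
    lambda <- shrinkage %||% (0.1 * s1)
    if (method == "nnm") lambda <- shrinkage %||% (0.01 * s1)
    for (it in seq_len(max_iter)) {
      znew <- switch(method,
        softimpute = svd_shrink(z, lambda),
        iterative_svd = svd_truncate(z, rank),
        nnm = svd_shrink(z - 0.99 * ifelse(na, 0, z - m), lambda))
      znew[!na] <- m[!na]
      rel <- sqrt(sum((znew[na] - z[na])^2) / max(sum(z[na]^2), 1e-12))
      z <- znew
      if (rel < tol) { converged <- TRUE; break }
    }
  } else {
    r <- rank
    nr <- nrow(m); nc <- ncol(m)
    reg <- 1e-2
    uv <- with_seed(seed, list(
      u = array(stats::runif(nr * r, -0.1, 0.1), dim = c(nr, r)),
      v = array(stats::runif(nc * r, -0.1, 0.1), dim = c(nc, r))))
    u <- uv$u; v <- uv$v
    u[, 1] <- 1  # start near a row-mean baseline
    obj_prev <- Inf
    obj_trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      for (i in seq_len(nr)) {
        o <- which(!na[i, ])
        vv <- v[o, , drop = FALSE]
        u[i, ] <- solve(crossprod(vv) + diag(reg, r), crossprod(vv, m[i, o]))
      }
      for (j in seq_len(nc)) {
        o <- which(!na[, j])
        uu <- u[o, , drop = FALSE]
        v[j, ] <- solve(crossprod(uu) + diag(reg, r), crossprod(uu, m[o, j]))
      }
      fit <- u %*% t(v)
      obj <- sum((fit[!na] - m[!na])^2) +
        reg * (sum(u^2) + sum(v^2))
      obj_trace <- c(obj_trace, obj)
      if (obj_prev - obj < tol * max(obj, 1)) { converged <- TRUE }
      if (converged || it == max_iter) { z <- fit; break }
      obj_prev <- obj
    }
    z <- u %*% t(v)
  }
  if (!converged)
    warnf("%s did not converge in %d iterations; returning last iterate",
          method, max_iter)
  out <- m
  out[na] <- clip01(z[na])
  out <- restore_beta(matrix, out)
  if (method == "mf") attr(out, "mf_objective") <- obj_trace
  out
}

# objective helper exposed for the block-coordinate-descent property test
mf_objective <- function(m, na, u, v, reg = 1e-2) {
  fit <- u %*% t(v)
  sum((fit[!na] - m[!na])^2) + reg * (sum(u^2) + sum(v^2))
}

#' Dispatch a sporadic-fill method by name
#'
#' Convenience front end mapping method names to the corresponding
#' `fill_*()` function; used by the imputation pipeline and the command
#' line.
#'
#' @inheritParams fill_trend
#' @param method one of `"mean"`, `"median"`, `"min"`, `"max"`, `"bfill"`,
#'   `"ffill"`, `"rand"`, `"mw"`, `"knn"`, `"fknn"` (weighted KNN),
#'   `"em"`, `"buck"`, `"iterative"`, `"rf"`, `"softimpute"`,
#'   `"iterative_svd"`, `"nnm"`, `"mf"`
#' @param seed integer seed passed to stochastic methods
#' @param ... further arguments for the selected method (e.g. `k`,
#'   `window`, `n_trees`)
#' @export
fill_sporadic <- function(matrix, method = "knn", seed = 1L, ...) {
  trend <- c("mean", "median", "min", "max", "bfill", "ffill")
  if (method %in% trend) return(fill_trend(matrix, mode = method, ...))
  switch(method,
    rand = fill_rand(matrix, seed = seed, ...),
    mw = fill_mw(matrix, ...),
    knn = fill_knn(matrix, weighted = FALSE, ...),
    fknn = fill_knn(matrix, weighted = TRUE, ...),
    em = fill_em(matrix, ...),
    buck = fill_buck(matrix),
    iterative = fill_iterative(matrix, ...),
    rf = fill_rf(matrix, seed = seed, ...),
    softimpute = fill_matrix_completion(matrix, method = "softimpute",
                                        seed = seed, ...),
    iterative_svd = fill_matrix_completion(matrix, method = "iterative_svd",
                                           seed = seed, ...),
    nnm = fill_matrix_completion(matrix, method = "nnm", seed = seed, ...),
    mf = fill_matrix_completion(matrix, method = "mf", seed = seed, ...),
    stopf("unknown sporadic fill method '%s'", method))
}
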