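# Trend, random-draw and moving-window fills. "Row" = CpG probe.
#
# Contract shared by every fill_*() function in the package: observed
# entries are never altered, targeted missing entries are replaced, and
# imputed values are clipped to [0, 1].

restore_beta <- function(template, values) {
  out <- template
  out[] <- values
  out
}

axis_arg <- function(axis) match.arg(axis, c("row", "column"))

#' Fill missing values with a per-row (or per-column) trend statistic
#'
#' @param matrix numeric matrix (CpGs x samples) with `NA` for missing
#' @param mode one of `"mean"`, `"median"`, `"min"`, `"max"`, `"bfill"`
#'   (backward fill) or `"ffill"` (forward fill)
#' @param axis `"row"` (default) computes the statistic along each CpG,
#'   `"column"` along each sample
#' @return matrix with targeted missing entries replaced. For `ffill` a
#'   missing leading stretch (and for `bfill` a trailing one) cannot be
#'   filled: those cells stay missing and a warning is emitted.
#' @export
fill_trend <- function(matrix, mode = c("mean", "median", "min", "max",
                                        "bfill", "ffill"),
                       axis = c("row", "column")) {
  mode <- match.arg(mode)
  axis <- axis_arg(axis)
  m <- unclass(matrix)
  if (axis == "column") return(restore_beta(matrix, t(fill_trend(t(m), mode))))
  na <- is.na(m)
  if (!any(na)) return(matrix)
  if (mode %in% c("mean", "median", "min", "max")) {
    bad <- rowSums(!na) == 0
    if (any(bad))
      stopf("uninformative row (no observed value): %s",
            rownames(m)[bad][1] %||% which(bad)[1])
    stat <- switch(mode,
      mean   = rowMeans(m, na.rm = TRUE),
      median = apply(m, 1L, stats::median, na.rm = TRUE),
      min    = apply(m, 1L, min, na.rm = TRUE),
      max    = apply(m, 1L, max, na.rm = TRUE))
    fill <- stat[row(m)[na]]
    m[na] <- clip01(fill)
  } else {
    if (mode == "bfill") m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
    left <- 0L
    for (i in which(rowSums(is.na(m)) > 0)) {
      x <- m[i, ]
      obs <- which(!is.na(x))
      if (length(obs) == 0 || obs[1] > 1)
        left <- left + 1L
      if (length(obs)) {
        idx <- cummax(ifelse(is.na(x), 0L, seq_along(x)))
        filled <- ifelse(idx > 0, x[pmax(idx, 1L)], NA_real_)
        m[i, ] <- filled
      }
    }
    if (left > 0)
      warnf("%d row(s) start with a missing value that %s cannot fill",
            left, mode)
    if (mode == "bfill") m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  }
  restore_beta(matrix, m)
}

#' Fill missing values with random draws from the same row or column
#'
#' Each missing cell receives a value sampled uniformly from the observed
#' values of its own row (or column). Deterministic under a fixed seed.
#'
#' @inheritParams fill_trend
#' @param seed integer seed
#' @export
fill_rand <- function(matrix, axis = c("row", "column"), seed = 1L) {
  axis <- axis_arg(axis)
  m <- unclass(matrix)
  if (axis == "column")
    return(restore_beta(matrix, t(fill_rand(t(m), seed = seed))))
  na <- is.na(m)
  if (!any(na)) return(matrix)
  bad <- rowSums(!na) == 0
  if (any(bad))
    stopf("uninformative row (no observed value): %s",
          rownames(m)[bad][1] %||% which(bad)[1])
  with_seed(seed, {
    for (i in which(rowSums(na) > 0)) {
      obs <- m[i, !na[i, ]]
      k <- sum(na[i, ])
      m[i, na[i, ]] <- obs[sample.int(length(obs), k, replace = TRUE)]
    }
  })
  restore_beta(matrix, m)
}

#' Fill missing values with a centered moving-window mean
#'
#' A centered window of odd width slides along each row (or column); each
#' missing cell is replaced by the mean of the observed values inside its
#' window, truncated asymmetrically at the edges. A window containing no
#' observed value besides the target falls back to the row mean.
#'
#' @inheritParams fill_trend
#' @param window odd window width (even values are bumped up with a
#'   warning; windows longer than the axis are clamped with a warning)
#' @export
fill_mw <- function(matrix, window = 5L, axis = c("row", "column")) {
  axis <- axis_arg(axis)
  m <- unclass(matrix)
  if (axis == "column")
    return(restore_beta(matrix, t(fill_mw(t(m), window = window))))
  if (window < 1) stopf("window must be >= 1")
  if (window %% 2 == 0) {
    warnf("even window %d bumped to %d (centered windows are odd)",
          window, window + 1)
    window <- window + 1
  }
  p <- ncol(m)
  if (window > p) {
    warnf("window %d exceeds axis length %d; clamped", window, p)
    window <- if (p %% 2 == 1) p else p - 1
    window <- max(window, 1L)
  }
  na <- is.na(m)
  if (!any(na)) return(matrix)
  bad <- rowSums(!na) == 0
  if (any(bad))
    stopf("uninformative row (no observed value): %s",
          rownames(m)[bad][1] %||% which(bad)[1])
  half <- (window - 1) %/% 2
  rmeans <- rowMeans(m, na.rm = TRUE)
  out <- m
  for (i in which(rowSums(na) > 0)) {
    for (j in which(na[i, ])) {
      lo <- max(1L, j - half); hi <- min(p, j + half)
      vals <- m[i, lo:hi]
      vals <- vals[!is.na(vals)]
      out[i, j] <- if (length(vals)) mean(vals) else rmeans[i]
    }
  }
  out[na] <- clip01(out[na])
  restore_beta(matrix, out)
}
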