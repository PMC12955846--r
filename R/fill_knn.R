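# Nearest-neighbour fills: within-matrix KNN (weighted or plain) and
# reference-panel KNN.

# Scaled Euclidean distance from row `i` to every other row of `m`,
# computed over mutually observed columns and divided by the number of
# shared columns (so rows with different overlap are comparable).
# Returns Inf where no column is shared.
row_distances <- function(m, na, i) {
  obs <- which(!na[i, ])
  sub <- m[, obs, drop = FALSE]
  shared <- !na[, obs, drop = FALSE]
  diff <- sweep(sub, 2L, m[i, obs])
  diff[!shared] <- 0
  ssq <- rowSums(diff^2)
  nsh <- rowSums(shared)
  d <- sqrt(ssq / nsh)
  d[nsh == 0] <- Inf
  d[i] <- Inf
  d
}

#' Fill missing values from K-nearest-neighbour CpG rows
#'
#' For each missing cell the k nearest CpG rows (Euclidean distance over
#' mutually observed columns, scaled by the number of shared columns) that
#' are observed in that column supply the estimate: their plain mean, or
#' an inverse-distance weighted mean (`weighted = TRUE`, weights
#' 1 / (d + 1e-9)).
#'
#' @inheritParams fill_trend
#' @param k number of neighbours
#' @param weighted use inverse-distance weights
#' @param seed accepted for interface uniformity; the method is
#'   deterministic (ties broken by row order)
#' @export
fill_knn <- function(matrix, k = 5L, weighted = FALSE, seed = NULL) {
  if (k < 1) stopf("k must be >= 1")
  m <- unclass(matrix)
  na <- is.na(m)
  if (!any(na)) return(matrix)
  bad <- rowSums(!na) == 0
  if (any(bad))
    stopf("uninformative row (no observed value): %s",
          rownames(m)[bad][1] %||% which(bad)[1])
  eps <- 1e-9
  short <- 0L
  out <- m
  for (i in which(rowSums(na) > 0)) {
    d <- row_distances(m, na, i)
    ord <- order(d)
    for (j in which(na[i, ])) {
      usable <- ord[!na[ord, j] & is.finite(d[ord])]
      if (length(usable) == 0)
        stopf("no usable neighbour for cell (%s, %s)",
              rownames(m)[i] %||% i, colnames(m)[j] %||% j)
      if (length(usable) < k) short <- short + 1L
      nb <- usable[seq_len(min(k, length(usable)))]
      out[i, j] <- if (weighted) {
        w <- 1 / (d[nb] + eps)
        sum(w * m[nb, j]) / sum(w)
      } else mean(m[nb, j])
    }
  }
  if (short > 0)
    warnf("%d cell(s) had fewer than k usable neighbours; used all available",
          short)
  out[na] <- clip01(out[na])
  restore_beta(matrix, out)
}

#' Fill missing values from an external reference panel
#'
#' Neighbours are reference *samples*: for each incomplete target sample,
#' the k reference samples nearest to it over the shared CpG ids (scaled
#' Euclidean distance over mutually observed CpGs) are found, and each
#' missing cell is replaced by the mean of those reference samples' values
#' at that CpG.
#'
#' @inheritParams fill_knn
#' @param reference a `BetaMatrix` sharing CpG ids with `matrix`; its
#'   samples form the neighbour pool
#' @export
fill_ref <- function(matrix, reference, k = 5L) {
  if (k < 1) stopf("k must be >= 1")
  m <- unclass(matrix)
  r <- unclass(reference)
  shared <- intersect(rownames(m), rownames(r))
  if (length(shared) == 0)
    stopf("reference shares no CpG ids with the matrix")
  na <- is.na(m)
  if (!any(na)) return(matrix)
  if (k > ncol(r)) {
    warnf("k = %d exceeds the %d reference samples; using all", k, ncol(r))
    k <- ncol(r)
  }
  tm <- t(m[shared, , drop = FALSE])   # target samples x shared CpGs
  tr <- t(r[shared, , drop = FALSE])   # reference samples x shared CpGs
  tna <- is.na(tm)
  out <- m
  unfilled <- 0L
  for (j in which(colSums(na) > 0)) {
    obs <- which(!tna[j, ])
    if (length(obs) == 0)
      stopf("sample %s shares no observed CpG with the reference",
            colnames(m)[j] %||% j)
    sub <- tr[, obs, drop = FALSE]
    sh <- !is.na(sub)
    diff <- sweep(sub, 2L, tm[j, obs])
    diff[!sh] <- 0
    nsh <- rowSums(sh)
    d <- sqrt(rowSums(diff^2) / nsh)
    d[nsh == 0] <- Inf
    ord <- order(d)
    for (i in which(na[, j])) {
      id <- rownames(m)[i]
      if (!id %in% shared) { unfilled <- unfilled + 1L; next }
      vals <- r[id, ord]
      vals <- vals[!is.na(vals) & is.finite(d[ord])]
      if (length(vals) == 0) { unfilled <- unfilled + 1L; next }
      out[i, j] <- mean(vals[seq_len(min(k, length(vals)))])
    }
  }
  if (unfilled > 0)
    warnf("%d cell(s) had no reference coverage and remain missing", unfilled)
  out[na] <- clip01(out[na])
  restore_beta(matrix, out)
}
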