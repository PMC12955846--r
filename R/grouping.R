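#' Assign samples to two groups from their probe presence/absence patterns
#'
#' Samples run on different array generations differ in which probes they
#' carry at all. Binarizing the matrix (1 = observed, 0 = missing) and
#' clustering samples on those binary vectors with K-means (K = 2)
#' recovers the array-of-origin split. User-supplied labels override
#' clustering entirely.
#'
#' @param matrix a `BetaMatrix` or numeric matrix with sample column names
#' @param seed integer seed making the clustering deterministic
#' @param user_labels optional named character vector (names = sample ids)
#'   with exactly two distinct labels covering all samples; returned
#'   verbatim with provenance `"user-provided"`.
#' @return object of class `GroupAssignment`: list with `labels` (named
#'   character vector of `"A"`/`"B"` or the user labels) and `provenance`.
#' @details K-means uses 10 random restarts, keeping the best inertia.
#'   The first sample's cluster is labelled `"A"`. If every sample shares
#'   an identical presence pattern the clustering is degenerate and an
#'   error advises supplying `user_labels`.
#' @export
assign_groups <- function(matrix, seed = 1L, user_labels = NULL) {
  samples <- colnames(matrix)
  if (length(samples) < 2) stopf("need at least 2 samples")
  if (!is.null(user_labels)) {
    if (!setequal(names(user_labels), samples))
      stopf("user_labels must cover exactly the matrix's samples")
    user_labels <- user_labels[samples]
    lev <- unique(user_labels)
    if (length(lev) != 2)
      stopf("user_labels must contain exactly 2 distinct labels, got %d",
            length(lev))
    return(structure(list(labels = user_labels, provenance = "user-provided"),
                     class = "GroupAssignment"))
  }
  pts <- t(!is.na(unclass(matrix))) * 1
  if (nrow(unique(pts)) < 2)
    stopf(paste("all samples share one identical presence/absence pattern;",
                "clustering is degenerate - supply user_labels"))
  km <- with_seed(seed, stats::kmeans(pts, centers = 2L, nstart = 10L))
  lab <- ifelse(km$cluster == km$cluster[1], "A", "B")
  names(lab) <- samples
  structure(list(labels = lab, provenance = "clustered"),
            class = "GroupAssignment")
}

#' @export
print.GroupAssignment <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("GroupAssignment (%s): %s\n", x$provenance,
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

group_samples <- function(groups, label) {
  names(groups$labels)[groups$labels == label]
}

group_levels <- function(groups) {
  # stable order: lexicographically first label plays the "A" role
  sort(unique(unname(groups$labels)))
}

#' Partition CpGs into the five missingness categories
#'
#' Given a two-group assignment, each CpG falls into exactly one of:
#' \describe{
#'   \item{non_missing}{no value missing in either group}
#'   \item{sporadic}{some values missing, but neither group fully missing}
#'   \item{a_specific}{missing in every group-A sample, observed in at
#'     least one group-B sample (structural absence of the probe from A's
#'     array)}
#'   \item{b_specific}{symmetric to a_specific}
#'   \item{all_missing}{missing everywhere}
#' }
#' A CpG missing in all of A and sporadically in B is classed a_specific:
#' the array lacking a probe removes it from every sample run on that
#' array, and the B-side holes are handled in the sporadic stage. This
#' boundary case is a package convention.
#'
#' @param matrix a `BetaMatrix` or numeric matrix
#' @param groups a [`GroupAssignment`][assign_groups]
#' @return object of class `CategorizedSites`: list of five disjoint
#'   character vectors of CpG ids that together cover all rows.
#' @export
categorize_cpgs <- function(matrix, groups) {
  if (!setequal(names(groups$labels), colnames(matrix)))
    stopf("group assignment does not cover the matrix's samples")
  lev <- group_levels(groups)
  na <- is.na(unclass(matrix))
  a_cols <- colnames(matrix) %in% group_samples(groups, lev[1])
  miss_a <- rowSums(na[, a_cols, drop = FALSE])
  miss_b <- rowSums(na[, !a_cols, drop = FALSE])
  n_a <- sum(a_cols); n_b <- sum(!a_cols)
  ids <- rownames(matrix)
  all_a <- miss_a == n_a
  all_b <- miss_b == n_b
  cat_all <- all_a & all_b
  cat_aspec <- all_a & !all_b
  cat_bspec <- all_b & !all_a
  cat_non <- miss_a + miss_b == 0
  cat_spor <- !(cat_all | cat_aspec | cat_bspec | cat_non)
  structure(list(non_missing = ids[cat_non],
                 sporadic = ids[cat_spor],
                 a_specific = ids[cat_aspec],
                 b_specific = ids[cat_bspec],
                 all_missing = ids[cat_all]),
            class = "CategorizedSites")
}

#' @export
print.CategorizedSites <- function(x, ...) {
  cat("CategorizedSites:",
      paste(sprintf("%s=%d", names(x), lengths(x)), collapse = ", "), "\n")
  invisible(x)
}

#' Read a two-column sample group-label file
#'
#' Tab-delimited `sample_id`, `label`; a header line is skipped when its
#' first field is `sample_id`.
#'
#' @param path file path
#' @return named character vector of labels suitable for
#'   `assign_groups(user_labels = ...)`.
#' @export
read_group_labels <- function(path) {
  dat <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(dat) < 2) stopf("%s: group file needs 2 columns", path)
  if (identical(dat[1, 1], "sample_id")) dat <- dat[-1, , drop = FALSE]
  stats::setNames(dat[[2]], dat[[1]])
}
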