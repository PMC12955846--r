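#' Construct a validated beta-value matrix
#'
#' A `BetaMatrix` is a numeric matrix of DNA methylation beta values in
#' \[0, 1\] with CpG probes as rows and samples as columns. Missing values
#' are `NA`. Row names are CpG identifiers, column names are sample
#' identifiers; both must be unique. Values of exactly 0 or 1 are legal
#' beta values, not sentinels. An optional per-CpG annotation carries
#' chromosome and 1-based position.
#'
#' @param values numeric matrix with unique row (CpG) and column (sample)
#'   names; non-missing entries must lie in \[0, 1\].
#' @param annotation optional `data.frame` with columns `cpg_id`, `chrom`,
#'   `position` covering exactly the CpGs of `values` (any order).
#' @return a matrix of class `BetaMatrix` (annotation stored as an
#'   attribute, reordered to match the rows).
#' @examples
#' m <- matrix(runif(6), 3, 2,
#'             dimnames = list(paste0("cg", 1:3), c("s1", "s2")))
#' b <- beta_matrix(m)
#' @export
beta_matrix <- function(values, annotation = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("`values` must be a numeric matrix")
  if ((is.null(rownames(values)) && nrow(values) > 0) ||
      (is.null(colnames(values)) && ncol(values) > 0))
    stopf("`values` must have CpG row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stopf("duplicate CpG id: %s",
          rownames(values)[duplicated(rownames(values))][1])
  if (anyDuplicated(colnames(values)))
    stopf("duplicate sample id: %s",
          colnames(values)[duplicated(colnames(values))][1])
  v <- values[!is.na(values)]
  if (length(v) && (min(v) < 0 || max(v) > 1))
    stopf("beta values must lie in [0, 1]; found %g", v[v < 0 | v > 1][1])
  if (!is.null(annotation)) {
    annotation <- validate_annotation(annotation, rownames(values))
    attr(values, "annotation") <- annotation
  }
  class(values) <- c("BetaMatrix", class(matrix()))
  values
}

validate_annotation <- function(annotation, cpg_ids) {
  need <- c("cpg_id", "chrom", "position")
  if (!is.data.frame(annotation) || !all(need %in% names(annotation)))
    stopf("annotation must be a data.frame with columns cpg_id, chrom, position")
  if (!setequal(annotation$cpg_id, cpg_ids) ||
      nrow(annotation) != length(cpg_ids))
    stopf("annotation must cover exactly the matrix's CpG ids")
  if (any(annotation$position < 1))
    stopf("positions are 1-based and must be >= 1")
  rownames(annotation) <- annotation$cpg_id
  annotation[cpg_ids, , drop = FALSE]
}

#' @export
print.BetaMatrix <- function(x, ...) {
  n_mis <- sum(is.na(x))
  cat(sprintf("BetaMatrix: %d CpGs x %d samples, %d missing (%.2f%%)%s\n",
              nrow(x), ncol(x), n_mis,
              if (length(x)) 100 * n_mis / length(x) else 0,
              if (is.null(attr(x, "annotation"))) "" else ", annotated"))
  invisible(x)
}

#' Per-CpG genomic annotation of a beta matrix
#'
#' @param x a `BetaMatrix`
#' @return the annotation `data.frame` (cpg_id, chrom, position) or `NULL`.
#' @export
cpg_annotation <- function(x) attr(x, "annotation")

#' Missingness mask of a beta matrix
#'
#' The mask is derived from the matrix itself: `TRUE` exactly where a value
#' is missing. It is never free-standing; recompute it after imputation.
#'
#' @param matrix a `BetaMatrix` or plain numeric matrix
#' @return logical matrix of the same shape and dimnames.
#' @export
compute_mask <- function(matrix) {
  m <- is.na(unclass(matrix))
  attr(m, "annotation") <- NULL
  m
}

#' Read a beta-value matrix from delimited text
#'
#' Expects a header row naming an id column followed by the sample ids, and
#' a first column of CpG ids. Cells matching one of `na_tokens` become
#' missing; every other cell must parse as a number in \[0, 1\].
#'
#' @param path file path
#' @param delimiter field separator (default tab)
#' @param na_tokens character vector of tokens treated as missing
#' @param annotation optional annotation `data.frame` attached after
#'   validation (see [beta_matrix()])
#' @return a `BetaMatrix`
#' @export
read_beta_matrix <- function(path, delimiter = "\t",
                             na_tokens = c("NA", "NaN", "nan", ""),
                             annotation = NULL) {
  dat <- utils::read.table(path, sep = delimiter, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "",
                           na.strings = character(0),
                           stringsAsFactors = FALSE)
  if (ncol(dat) < 1) stopf("%s: no columns found", path)
  ids <- dat[[1]]
  samples <- colnames(dat)[-1]
  if (anyDuplicated(ids))
    stopf("duplicate CpG id in %s: %s", path, ids[duplicated(ids)][1])
  if (anyDuplicated(samples))
    stopf("duplicate sample id in %s: %s", path,
          samples[duplicated(samples)][1])
  raw <- as.matrix(dat[, -1, drop = FALSE])
  is_na_tok <- matrix(raw %in% na_tokens, nrow(raw), ncol(raw))
  num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(is.na(num) & !is_na_tok, arr.ind = TRUE)
  if (nrow(bad))
    stopf("%s: cell (%s, %s) is not numeric and not an NA token: '%s'",
          path, ids[bad[1, 1]], samples[bad[1, 2]], raw[bad[1, 1], bad[1, 2]])
  num[is_na_tok] <- NA_real_
  out <- which(!is.na(num) & (num < 0 | num > 1), arr.ind = TRUE)
  if (nrow(out))
    stopf("%s: cell (%s, %s) = %g is outside [0, 1]",
          path, ids[out[1, 1]], samples[out[1, 2]], num[out[1, 1], out[1, 2]])
  dimnames(num) <- list(ids, samples)
  beta_matrix(num, annotation = annotation)
}

#' Write a beta-value matrix to delimited text
#'
#' Values are printed with 17 significant digits so that a read/write
#' round trip reproduces them exactly.
#'
#' @param matrix a `BetaMatrix` or numeric matrix with dimnames
#' @param path output file path
#' @param na_token token written for missing cells (default `"NA"`)
#' @param delimiter field separator
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(matrix, path, na_token = "NA",
                              delimiter = "\t") {
  header <- paste(c("cpg_id", colnames(matrix)), collapse = delimiter)
  if (nrow(matrix) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  txt <- array(sprintf("%.17g", matrix), dim = dim(matrix))
  txt[is.na(matrix)] <- na_token
  body <- apply(cbind(rownames(matrix), txt), 1L, paste,
                collapse = delimiter)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read a 3-column CpG annotation table
#'
#' Tab-delimited `cpg_id`, `chrom`, `position` with positions 1-based
#' (Illumina manifest convention). BED-style 0-based input is not
#' accepted. A header line is detected and skipped when the third field of
#' the first line is non-numeric.
#'
#' @param path file path
#' @return `data.frame` with columns cpg_id, chrom, position
#' @export
read_cpg_annotation <- function(path) {
  dat <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(dat) < 3) stopf("%s: annotation needs 3 columns", path)
  if (is.na(suppressWarnings(as.numeric(dat[1, 3]))))
    dat <- dat[-1, , drop = FALSE]
  out <- data.frame(cpg_id = dat[[1]], chrom = dat[[2]],
                    position = as.integer(dat[[3]]),
                    stringsAsFactors = FALSE)
  if (any(is.na(out$position))) stopf("%s: non-numeric position", path)
  if (any(out$position < 1)) stopf("%s: positions are 1-based (>= 1)", path)
  out
}

#' Split a beta matrix by chromosome
#'
#' Requires annotation. Each sub-matrix keeps the full sample set and the
#' within-chromosome CpG order of the input; concatenating the pieces
#' recovers the original CpG set.
#'
#' @param matrix an annotated `BetaMatrix`
#' @return named list of `BetaMatrix`, one per chromosome (input order of
#'   first appearance).
#' @export
split_by_chromosome <- function(matrix) {
  ann <- attr(matrix, "annotation")
  if (is.null(ann))
    stopf("split_by_chromosome() requires per-CpG annotation")
  chroms <- unique(ann$chrom)
  out <- lapply(chroms, function(ch) {
    ids <- ann$cpg_id[ann$chrom == ch]
    beta_matrix(unclass(matrix)[ids, , drop = FALSE],
                annotation = ann[ann$chrom == ch, , drop = FALSE])
  })
  names(out) <- chroms
  out
}
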