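# Fixture builders shared across the suite. Everything is generated in
# code; no data files.

# small named beta matrix from a vector (byrow)
bm <- function(values, nrow, ncol, cpgs = NULL, samples = NULL) {
  m <- matrix(values, nrow, ncol, byrow = TRUE)
  dimnames(m) <- list(cpgs %||% sprintf("cg%05d", seq_len(nrow)),
                      samples %||% sprintf("s%02d", seq_len(ncol)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random beta matrix with sporadic missingness
random_beta <- function(n_cpg, n_smp, miss = 0.05, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(n_cpg * n_smp), n_cpg, n_smp)
  dimnames(m) <- list(sprintf("cg%05d", seq_len(n_cpg)),
                      sprintf("s%02d", seq_len(n_smp)))
  if (miss > 0) m[sample(length(m), floor(miss * length(m)))] <- NA
  m
}

# group assignment object over given samples
fixed_groups <- function(samples, labels) {
  assign_groups(bm(runif(2 * length(samples)), 2, length(samples),
                   samples = samples),
                user_labels = stats::setNames(labels, samples))
}

# observed cells untouched & imputed cells within [0,1]
expect_fill_contract <- function(filled, original) {
  obs <- !is.na(unclass(original))
  expect_identical(unclass(filled)[obs], unclass(original)[obs])
  imp <- unclass(filled)[!obs]
  imp <- imp[!is.na(imp)]
  if (length(imp)) {
    expect_gte(min(imp), 0)
    expect_lte(max(imp), 1)
  }
}
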