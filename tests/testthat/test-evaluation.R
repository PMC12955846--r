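# independent brute-force metric implementation used as oracle
metrics_oracle <- function(y, yhat) {
  n <- length(y)
  ybar <- sum(y) / n
  abs_err <- 0; sq_err <- 0; abs_dev <- 0; sq_dev <- 0
  for (i in seq_len(n)) {
    abs_err <- abs_err + abs(y[i] - yhat[i])
    sq_err <- sq_err + (y[i] - yhat[i])^2
    abs_dev <- abs_dev + abs(y[i] - ybar)
    sq_dev <- sq_dev + (y[i] - ybar)^2
  }
  list(mae = abs_err / n, rae = abs_err / abs_dev,
       rmse = sqrt(sq_err / n), r2 = 1 - sq_err / sq_dev)
}

test_that("metrics satisfy their definitional identities", {
  y <- c(0.1, 0.4, 0.8, 0.3)
  perfect <- compute_metrics(y, y)
  expect_identical(c(perfect$mae, perfect$rae, perfect$rmse), c(0, 0, 0))
  expect_identical(perfect$r2, 1)
  meanpred <- compute_metrics(y, rep(mean(y), 4))
  expect_equal(meanpred$rae, 1)
  expect_equal(meanpred$r2, 0)
  hand <- compute_metrics(c(0, 1), c(0.5, 0.5))
  expect_equal(c(hand$mae, hand$rmse, hand$r2), c(0.5, 0.5, 0))
  expect_warning(const <- compute_metrics(c(0.3, 0.3), c(0.2, 0.4)),
                 "undefined")
  expect_true(is.nan(const$rae) && is.nan(const$r2))
})

test_that("metrics agree with the brute-force oracle", {
  set.seed(17)
  for (rep in 1:25) {
    y <- runif(sample(5:50, 1))
    yhat <- pmin(pmax(y + rnorm(length(y), 0, 0.1), 0), 1)
    got <- compute_metrics(y, yhat)
    want <- metrics_oracle(y, yhat)
    for (nm in names(want)) expect_equal(got[[nm]], want[[nm]],
                                         tolerance = 1e-12)
  }
})

test_that("tier stratification uses left-closed intervals and partitions", {
  m <- bm(c(0.25, 0.25,
            1.00, 1.00,
            0.10, 0.20,
            0.60, 0.70), 4, 2)
  tiers <- stratify_by_mean_beta(m, rownames(m))
  expect_identical(tiers$tier2, rownames(m)[1])   # mean 0.25 -> second tier
  expect_identical(tiers$tier4, rownames(m)[2])   # mean 1.0 -> fourth tier
  expect_identical(tiers$tier1, rownames(m)[3])
  expect_identical(tiers$tier3, rownames(m)[4])
  set.seed(18)
  big <- random_beta(200, 6, miss = 0)
  ids <- sample(rownames(big), 120)
  t2 <- stratify_by_mean_beta(big, ids)
  expect_equal(sum(lengths(t2)), 120)
  expect_setequal(unlist(t2, use.names = FALSE), ids)
})

test_that("differential-CpG selection has power and controls the null", {
  samples <- sprintf("s%02d", 1:30)
  groups <- fixed_groups(samples, rep(c("A", "B"), each = 15))
  set.seed(19)
  null_frac <- sapply(1:8, function(s) {
    set.seed(100 + s)
    m <- matrix(runif(200 * 30, 0.2, 0.8), 200, 30,
                dimnames = list(sprintf("cg%04d", 1:200), samples))
    length(select_differential_cpgs(m, groups)) / 200
  })
  expect_lte(stats::median(null_frac), 0.05)

  set.seed(20)
  m <- matrix(runif(50 * 30, 0.3, 0.7), 50, 30,
              dimnames = list(sprintf("cg%04d", 1:50), samples))
  m[1, ] <- c(rnorm(15, 0.1, 0.02), rnorm(15, 0.9, 0.02))
  sel <- select_differential_cpgs(m, groups)
  expect_true("cg0001" %in% sel)
  expect_length(select_differential_cpgs(m, groups, alpha = 0), 0)
})

test_that("Welch statistics match t.test", {
  samples <- sprintf("s%02d", 1:10)
  groups <- fixed_groups(samples, rep(c("A", "B"), each = 5))
  set.seed(21)
  m <- matrix(runif(40 * 10), 40, 10,
              dimnames = list(sprintf("cg%04d", 1:40), samples))
  ref_p <- apply(m, 1, function(r)
    stats::t.test(r[1:5], r[6:10])$p.value)
  # selection at alpha = 1 on raw BH-adjusted p must match t.test-based BH
  sel <- select_differential_cpgs(m, groups, alpha = 0.5)
  ref_sel <- rownames(m)[stats::p.adjust(ref_p, "BH") < 0.5]
  expect_setequal(sel, ref_sel)
})

test_that("PCA concordance is 1 for identical or sign-flipped data", {
  set.seed(22)
  m <- random_beta(150, 12, miss = 0)
  expect_equal(unname(pca_concordance(m, m)), c(1, 1), tolerance = 1e-10)
  flipped <- 1 - m
  expect_equal(pca_concordance(m, flipped)[1], 1, tolerance = 1e-10)
  expect_error(pca_concordance(m[, 1:2], m[, 1:2], n_components = 2),
               "more samples")
  m2 <- m; m2[1, 1] <- NA
  expect_error(pca_concordance(m, m2), "complete")
})
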