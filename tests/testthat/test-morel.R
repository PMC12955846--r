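make_two_group <- function(n_cpg = 60, n_a = 3, n_b = 3, seed = 1) {
  m <- random_beta(n_cpg, n_a + n_b, miss = 0, seed = seed)
  samples <- c(sprintf("a%d", seq_len(n_a)), sprintf("b%d", seq_len(n_b)))
  colnames(m) <- samples
  groups <- fixed_groups(samples, rep(c("A", "B"), c(n_a, n_b)))
  list(m = m, groups = groups)
}

test_that("training sets have the direction's shapes and swap with it", {
  tg <- make_two_group(5, 2, 2)
  cats <- categorize_cpgs(tg$m, tg$groups)
  ts <- build_training_set(tg$m, cats, tg$groups, c("B", "A"))
  expect_equal(dim(ts$x), c(5L, 2L))
  expect_equal(dim(ts$y), c(5L, 2L))
  expect_identical(colnames(ts$x), c("b1", "b2"))
  rev_ <- build_training_set(tg$m, cats, tg$groups, c("A", "B"))
  expect_identical(rev_$x, ts$y)
  expect_identical(rev_$y, ts$x)

  # a residually incomplete CpG is excluded from the training rows
  m2 <- tg$m; m2[2, 1] <- NA
  cats2 <- categorize_cpgs(m2, tg$groups)
  ts2 <- build_training_set(m2, cats2, tg$groups, c("B", "A"))
  expect_false(rownames(tg$m)[2] %in% ts2$cpg_ids)

  m3 <- tg$m; m3[, 1] <- NA
  cats3 <- categorize_cpgs(m3, tg$groups)
  expect_error(build_training_set(m3[0, , drop = FALSE],
                                  list(non_missing = character(0),
                                       sporadic = character(0)),
                                  tg$groups, c("B", "A")),
               "no complete training CpG")
})

test_that("hidden width is the half-up mean of layer widths", {
  expect_identical(dnn_hidden_units(15, 15), 15L)
  expect_identical(dnn_hidden_units(1, 1), 1L)
  expect_identical(dnn_hidden_units(2, 3), 3L)
  expect_identical(dnn_hidden_units(4, 4), 4L)
  expect_error(dnn_hidden_units(0, 3), ">= 1")
})

test_that("KNN predicts training points exactly when targets copy sources", {
  set.seed(11)
  x <- matrix(runif(40 * 3), 40, 3)
  model <- fit_morel(x, x, morel_config("knn", k = 1))
  expect_equal(predict(model, x[7, , drop = FALSE]),
               structure(x[7, , drop = FALSE], dimnames = NULL),
               ignore_attr = TRUE)
})

test_that("linear SVR recovers a linear teacher", {
  set.seed(12)
  x <- matrix(runif(200 * 4), 200, 4)
  y <- 0.5 * x + 0.1
  model <- fit_morel(x, y, morel_config("svr", seed = 1))
  expect_lt(mean(abs(predict(model, x) - y)), 0.02)
})

test_that("the DNN builds the prescribed architecture and learns", {
  set.seed(13)
  x <- matrix(runif(300 * 4), 300, 4)
  y <- x
  model <- fit_morel(x, y, morel_config("dnn", seed = 2, epochs = 500,
                                        batch_size = 32))
  expect_identical(model$fit$hidden, 4L)
  expect_equal(dim(model$fit$w1), c(4L, 4L))
  # clearly below the mean-prediction error E|x - 0.5| = 0.25
  expect_lt(mean(abs(predict(model, x) - y)), 0.2)
  # he-uniform initial weights respect the fan-in limit
  init <- morelimpute:::he_uniform(100, 50)
  expect_lte(max(abs(init)), sqrt(6 / 100))
})

test_that("too few training rows raise an error", {
  x <- matrix(runif(8), 4, 2)
  expect_error(fit_morel(x, x, morel_config("rf")), "too few")
})

test_that("systematic imputation fills only group-specific cells, clipped", {
  tg <- make_two_group(80, 3, 3, seed = 14)
  m <- tg$m
  m[1:10, 1:3] <- NA                       # a_specific block
  cats <- categorize_cpgs(m, tg$groups)
  expect_length(cats$a_specific, 10)
  out <- impute_systematic(m, cats, tg$groups, morel_config("knn", seed = 3))
  expect_false(anyNA(out))
  obs <- !is.na(m)
  expect_identical(unclass(out)[obs], m[obs])
  expect_true(all(out >= 0 & out <= 1))

  # no group-specific CpGs: identity
  cats0 <- categorize_cpgs(tg$m, tg$groups)
  expect_identical(unclass(impute_systematic(tg$m, cats0, tg$groups)),
                   unclass(tg$m))
})

test_that("predictions outside [0,1] are clipped", {
  set.seed(15)
  # teacher y = x + 0.5 pushes predictions above 1 for large x
  x <- matrix(runif(100, 0.6, 1.0), 100, 1)
  y <- matrix(pmin(x + 0.5, 1), 100, 1)
  samples <- c("a1", "b1", "b2")
  m <- cbind(y[, 1], x[, 1], x[, 1])
  dimnames(m) <- list(sprintf("cg%03d", 1:100), samples)
  groups <- fixed_groups(samples, c("A", "B", "B"))
  m[1:20, 1] <- NA
  cats <- categorize_cpgs(m, groups)
  out <- impute_systematic(m, cats, groups, morel_config("svr", seed = 1))
  expect_true(all(out[1:20, 1] <= 1 & out[1:20, 1] >= 0))
})

test_that("the full pipeline runs the four stages deterministically", {
  cfg <- simulation_config(n_cpgs = 300, n_samples_a = 8, n_samples_b = 8,
                           seed = 31)
  b <- simulate_beta_matrix(cfg)
  truth <- attr(b, "true_groups")
  inj <- inject_structural_missing(b, truth, 0.3, "A", seed = 32)
  inj2 <- inject_sporadic_missing(inj$matrix, 0.03, seed = 33)
  res1 <- suppressMessages(
    impute_pipeline(inj2$matrix, sporadic_method = "knn",
                    morel_config = morel_config("knn", seed = 5), seed = 5))
  expect_false(anyNA(res1$matrix))
  obs <- !is.na(unclass(inj2$matrix))
  expect_identical(unclass(res1$matrix)[obs], unclass(inj2$matrix)[obs])
  res2 <- suppressMessages(
    impute_pipeline(inj2$matrix, sporadic_method = "knn",
                    morel_config = morel_config("knn", seed = 5), seed = 5))
  expect_identical(unclass(res1$matrix), unclass(res2$matrix))

  # complete input: identity
  full <- random_beta(10, 4, miss = 0)
  resf <- suppressMessages(impute_pipeline(full))
  expect_identical(unclass(resf$matrix)[, ], full[, ])
})

test_that("all-missing CpGs are dropped by default and kept on request", {
  tg <- make_two_group(30, 3, 3, seed = 16)
  m <- tg$m
  m[5, ] <- NA
  m[1:8, 1:3] <- NA
  lab <- stats::setNames(rep(c("A", "B"), each = 3), colnames(m))
  res <- suppressMessages(
    impute_pipeline(m, user_labels = lab,
                    morel_config = morel_config("knn", k = 3, seed = 1)))
  expect_false(rownames(m)[5] %in% rownames(res$matrix))
  expect_equal(nrow(res$matrix), 29)
  res_keep <- suppressMessages(
    impute_pipeline(m, user_labels = lab, keep_all_missing = TRUE,
                    morel_config = morel_config("knn", k = 3, seed = 1)))
  expect_true(all(is.na(res_keep$matrix[5, ])))
  expect_equal(nrow(res_keep$matrix), 30)
})
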