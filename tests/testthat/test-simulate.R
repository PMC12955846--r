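test_that("simulated betas are in range, seeded, and tier-calibrated", {
  cfg <- simulation_config(n_cpgs = 10000, n_samples_a = 5, n_samples_b = 5,
                           tier_proportions = c(0.4, 0.1, 0.1, 0.4),
                           seed = 41)
  b1 <- simulate_beta_matrix(cfg)
  expect_true(all(b1 >= 0 & b1 <= 1))
  b2 <- simulate_beta_matrix(cfg)
  expect_identical(unclass(b1)[, ], unclass(b2)[, ])

  mb <- rowMeans(unclass(b1))
  realized <- c(mean(mb < 0.25), mean(mb >= 0.25 & mb < 0.5),
                mean(mb >= 0.5 & mb < 0.75), mean(mb >= 0.75))
  expect_true(all(abs(realized - c(0.4, 0.1, 0.1, 0.4)) < 0.02))

  expect_error(simulation_config(tier_proportions = c(0.5, 0.5, 0.5, 0.5)),
               "summing to 1")
  expect_error(simulation_config(noise_sd = 0), "noise_sd")
})

test_that("outer beta tiers vary less across samples than inner tiers", {
  cfg <- simulation_config(n_cpgs = 4000, seed = 43)
  b <- simulate_beta_matrix(cfg)
  mb <- rowMeans(unclass(b))
  sds <- apply(unclass(b), 1, sd)
  outer_sd <- mean(sds[mb < 0.25 | mb >= 0.75])
  inner_sd <- mean(sds[mb >= 0.25 & mb < 0.75])
  expect_lt(outer_sd, inner_sd)
})

test_that("structural injection masks whole group blocks and records truth", {
  cfg <- simulation_config(n_cpgs = 200, n_samples_a = 4, n_samples_b = 4,
                           seed = 44)
  b <- simulate_beta_matrix(cfg)
  g <- attr(b, "true_groups")

  id0 <- inject_structural_missing(b, g, 0, "A", seed = 1)
  expect_identical(unclass(id0$matrix)[, ], unclass(b)[, ])
  expect_equal(nrow(id0$truth), 0)

  inj <- inject_structural_missing(b, g, 0.5, "A", seed = 2)
  expect_equal(mean(is.na(inj$matrix)), 0.25)
  # restoring the truth triples reproduces the original exactly
  m <- unclass(inj$matrix)
  m[cbind(match(inj$truth$cpg_id, rownames(m)),
          match(inj$truth$sample_id, colnames(m)))] <- inj$truth$value
  expect_identical(m[, ], unclass(b)[, ])

  all_inj <- inject_structural_missing(b, g, 1, "A", seed = 3)
  ga <- assign_groups(all_inj$matrix, seed = 4)
  cats <- categorize_cpgs(all_inj$matrix, ga)
  expect_length(c(cats$a_specific, cats$b_specific), 200)
  expect_error(inject_structural_missing(b, g, 1.2), "fraction")
})

test_that("sporadic injection is Bernoulli per observed cell", {
  cfg <- simulation_config(n_cpgs = 5000, n_samples_a = 10, n_samples_b = 10,
                           seed = 45)
  b <- simulate_beta_matrix(cfg)
  r0 <- inject_sporadic_missing(b, 0, seed = 1)
  expect_identical(unclass(r0$matrix)[, ], unclass(b)[, ])

  inj <- inject_sporadic_missing(b, 0.05, seed = 2)
  expect_lt(abs(mean(is.na(inj$matrix)) - 0.05), 0.005)

  # never masks an already-missing cell
  pre <- inject_structural_missing(b, attr(b, "true_groups"), 0.3, "A",
                                   seed = 3)
  post <- inject_sporadic_missing(pre$matrix, 0.05, seed = 4)
  expect_false(any(paste(post$truth$cpg_id, post$truth$sample_id) %in%
                     paste(pre$truth$cpg_id, pre$truth$sample_id)))
  expect_error(inject_sporadic_missing(b, 1), "rate")
})

test_that("simulate -> inject -> impute -> score runs end to end", {
  cfg <- simulation_config(n_cpgs = 2000, seed = 46)
  b <- simulate_beta_matrix(cfg)
  g <- attr(b, "true_groups")
  s1 <- inject_structural_missing(b, g, 0.5, "A", seed = 47)
  s2 <- inject_sporadic_missing(s1$matrix, 0.01, seed = 48)
  res <- suppressMessages(
    impute_pipeline(s2$matrix, sporadic_method = "knn",
                    morel_config = morel_config("knn", seed = 8), seed = 8))
  expect_false(anyNA(res$matrix))
  truth <- rbind(s1$truth, s2$truth)
  rep_ <- compute_metrics(truth$value, truth_values(res$matrix, truth))
  expect_lt(rep_$mae, 0.1)
  expect_gt(rep_$r2, 0.5)
})
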