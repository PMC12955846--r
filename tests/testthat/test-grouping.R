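test_that("clustering on presence patterns separates disjoint probe sets", {
  set.seed(7)
  m <- random_beta(40, 4, miss = 0)
  m[1:10, 1:2] <- NA    # samples 1-2 miss probe set S
  m[11:25, 3:4] <- NA   # samples 3-4 miss disjoint set T
  g <- assign_groups(m, seed = 1)
  expect_identical(g$provenance, "clustered")
  expect_identical(g$labels[["s01"]], g$labels[["s02"]])
  expect_identical(g$labels[["s03"]], g$labels[["s04"]])
  expect_false(g$labels[["s01"]] == g$labels[["s03"]])
})

test_that("user labels override clustering verbatim", {
  m <- random_beta(5, 3, miss = 0.2)
  lab <- c(s01 = "A", s02 = "A", s03 = "B")
  g <- assign_groups(m, user_labels = lab)
  expect_identical(g$labels, lab)
  expect_identical(g$provenance, "user-provided")
  expect_error(assign_groups(m, user_labels = c(s01 = "A", s02 = "A",
                                                s03 = "A")),
               "2 distinct")
  expect_error(assign_groups(m, user_labels = c(s01 = "A", s02 = "B")),
               "cover")
})

test_that("identical presence patterns raise a degenerate-clustering error", {
  m <- random_beta(10, 4, miss = 0)
  expect_error(assign_groups(m), "degenerate")
  m[3, ] <- NA  # still identical across samples
  expect_error(assign_groups(m), "degenerate")
})

test_that("clustering recovers a 15/15 split under 50% structural masking", {
  cfg <- simulation_config(n_cpgs = 400, seed = 21)
  b <- simulate_beta_matrix(cfg)
  truth <- attr(b, "true_groups")
  inj <- inject_structural_missing(b, truth, 0.5, "A", seed = 22)
  g <- assign_groups(inj$matrix, seed = 23)
  same <- unname(g$labels == g$labels[[1]])
  expect_true(identical(same, unname(truth == truth[[1]])) ||
                identical(same, unname(truth != truth[[1]])))
})

test_that("categorization follows the five-class rule", {
  g <- fixed_groups(paste0("s", 1:4), c("A", "A", "B", "B"))
  m <- bm(runif(8), 2, 4, samples = paste0("s", 1:4))
  cats <- categorize_cpgs(m, g)
  expect_identical(cats$non_missing, rownames(m))

  # missing in all A and one of three B samples -> a_specific
  g3 <- fixed_groups(paste0("s", 1:5), c("A", "A", "B", "B", "B"))
  m3 <- bm(runif(5), 1, 5, samples = paste0("s", 1:5))
  m3[1, 1:2] <- NA; m3[1, 3] <- NA
  expect_identical(categorize_cpgs(m3, g3)$a_specific, rownames(m3))
})

test_that("categories always partition the CpG set (random masks)", {
  g <- fixed_groups(paste0("s", 1:6), c("A", "A", "A", "B", "B", "B"))
  for (seed in 1:20) {
    m <- random_beta(50, 6, miss = 0.35, seed = seed)
    colnames(m) <- paste0("s", 1:6)
    cats <- categorize_cpgs(m, g)
    all_ids <- unlist(cats, use.names = FALSE)
    expect_length(all_ids, nrow(m))
    expect_false(anyDuplicated(all_ids) > 0)
    expect_setequal(all_ids, rownames(m))
  }
})

test_that("categorization is invariant to column order and label swap", {
  samples <- paste0("s", 1:6)
  g <- fixed_groups(samples, c("A", "A", "A", "B", "B", "B"))
  g_swap <- fixed_groups(samples, c("B", "B", "B", "A", "A", "A"))
  m <- random_beta(60, 6, miss = 0.3, seed = 9)
  colnames(m) <- samples
  cats <- categorize_cpgs(m, g)
  perm <- c(4, 1, 6, 2, 3, 5)
  cats_perm <- categorize_cpgs(m[, perm], g)
  for (nm in names(cats)) expect_setequal(cats[[nm]], cats_perm[[nm]])
  cats_swap <- categorize_cpgs(m, g_swap)
  expect_setequal(cats_swap$a_specific, cats$b_specific)
  expect_setequal(cats_swap$b_specific, cats$a_specific)
  expect_setequal(cats_swap$sporadic, cats$sporadic)
})

test_that("group-label files round-trip", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tlabel", "s1\tA", "s2\tB"), p)
  expect_identical(read_group_labels(p), c(s1 = "A", s2 = "B"))
})
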