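test_that("stratified folds preserve class balance and partition the samples", {
  y <- rep(c(0L, 1L), c(60, 40))
  folds <- stratified_folds(y, 5, seed = 1)
  expect_setequal(unique(folds), 1:5)
  for (f in 1:5) {
    expect_equal(sum(y[folds == f]), 8)   # 40 cases / 5
    expect_equal(sum(folds == f), 20)
  }
  expect_error(stratified_folds(c(0, 0, 1), 5), "stratify")
  # deterministic
  expect_identical(folds, stratified_folds(y, 5, seed = 1))
  expect_false(identical(folds, stratified_folds(y, 5, seed = 2)))
})

test_that("repeated nested CV yields one row per split with disjoint, covering partitions", {
  fx <- make_toy_fixture(20, n_samples = 150, n_snps = 40)
  g <- fx$genotypes
  w <- truth_weight_table(fx$truth)
  scheme <- cv_scheme(n_repetitions = 10, seed = 3)
  res <- repeated_nested_cv(g, method = "prs", scheme = scheme, weights = w)
  expect_s3_class(res, "snp_cv")
  expect_equal(nrow(res), 50)
  expect_true(all(res$ap >= 0 & res$ap <= 1))
  # within each repetition the test folds are disjoint and cover everyone
  for (r in unique(res$repetition)) {
    ids <- unlist(res$test_ids[res$repetition == r])
    expect_equal(sort(ids), sort(g$sample_id))
  }
  # leakage: test ids never intersect the training fold, in all 50 splits
  for (i in seq_len(nrow(res))) {
    expect_length(intersect(res$test_ids[[i]], res$train_fold_ids[[i]]), 0)
  }
})

test_that("the proposed method runs end to end and keeps validation inside the training fold", {
  fx <- make_toy_fixture(21, n_samples = 150, n_snps = 60)
  g <- fx$genotypes
  res <- repeated_nested_cv(
    g, method = "proposed", scheme = cv_scheme(n_repetitions = 1, seed = 5),
    boost_params = test_boost(n_trees = 40),
    search = search_config(window_sizes = 2, window_increments = 5,
                           k_grid = c(1, 5, 10))
  )
  expect_equal(nrow(res), 5)
  for (i in 1:5) {
    expect_length(intersect(res$test_ids[[i]], res$train_fold_ids[[i]]), 0)
    expect_true(all(res$valid_ids[[i]] %in% res$train_fold_ids[[i]]))
    expect_gte(length(res$selected_snps[[i]]), 1)
    expect_true(res$chosen_M[i] == 2 && res$chosen_W[i] == 5)
  }
  gl <- glance(res)
  expect_equal(gl$n_splits, 5L)
  expect_equal(gl$map, 100 * mean(res$ap))
  td <- tidy(res)
  expect_false(any(vapply(td, is.list, logical(1))))
})

test_that("the no-search ablation skips the adaptive search and uses all candidates", {
  fx <- make_toy_fixture(22, n_samples = 150, n_snps = 60)
  res <- repeated_nested_cv(
    fx$genotypes, method = "proposed_no_search",
    scheme = cv_scheme(n_repetitions = 1, seed = 6),
    boost_params = test_boost(n_trees = 40)
  )
  expect_equal(nrow(res), 5)
  expect_true(all(is.na(res$chosen_M)))
  # group = all positive-gain candidates (capped), so much larger than a
  # typical searched group
  expect_true(all(res$group_size > 10))
})

test_that("penalized and fixed-panel methods evaluate through the same protocol", {
  fx <- make_toy_fixture(23, n_samples = 150, n_snps = 50)
  g <- fx$genotypes
  res_l1 <- repeated_nested_cv(g, method = "l1",
                               scheme = cv_scheme(n_repetitions = 1, seed = 7))
  expect_equal(nrow(res_l1), 5)
  res_fp <- repeated_nested_cv(g, method = "fixed_panel",
                               scheme = cv_scheme(n_repetitions = 1, seed = 7),
                               panel = fx$truth$causal_snps)
  expect_equal(unique(res_fp$group_size), 4L)
  expect_error(repeated_nested_cv(g, method = "prs",
                                  scheme = cv_scheme(n_repetitions = 1)),
               "weight")
  expect_error(repeated_nested_cv(g, method = "fixed_panel",
                                  scheme = cv_scheme(n_repetitions = 1)),
               "panel")
})

test_that("ER subtype protocol discards zero-gain SNPs and scores per group size", {
  cfg <- sim_config(
    n_samples = 350, n_snps = 60, target_prevalence = 0.6,
    er_effects = tibble::tibble(snp = c(10L, 20L), beta = c(2, 2)),
    seed = 31
  )
  study <- simulate_study(cfg)
  g <- study$genotypes
  union <- paste0("snp", 1:40)
  res <- er_subtype_task(g, union, k_grid = c(2, 5, 10),
                         boost_params = test_boost(n_trees = 60),
                         n_folds = 5, seed = 31)
  surviving <- attr(res, "er_ranking")
  expect_true(all(surviving %in% union))
  expect_true(all(res$map >= 0 & res$map <= 100))
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 100))
  # consistency: k clipped to the surviving set reuses all surviving SNPs
  res_full <- er_subtype_task(g, union, k_grid = length(surviving),
                              boost_params = test_boost(n_trees = 60),
                              n_folds = 5, seed = 31)
  expect_equal(res_full$k, length(surviving))

  g_noer <- g
  g_noer$er_status <- "unknown"
  expect_error(er_subtype_task(g_noer, union, seed = 1), "ER")
})

test_that("planted ER-informative SNPs survive the gain discarding in most seeds", {
  hits <- 0
  for (s in 1:10) {
    cfg <- sim_config(
      n_samples = 320, n_snps = 50, target_prevalence = 0.6,
      er_effects = tibble::tibble(snp = c(7L, 33L), beta = c(2.5, 2.5)),
      seed = 500 + s
    )
    g <- simulate_study(cfg)$genotypes
    res <- er_subtype_task(g, paste0("snp", 1:50), k_grid = 5,
                           boost_params = test_boost(n_trees = 60, seed = s),
                           n_folds = 5, seed = s)
    surv <- attr(res, "er_ranking")
    if (all(c("snp7", "snp33") %in% surv)) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("all-noise ER labels give mAP near the ER-positive prevalence", {
  cfg <- sim_config(n_samples = 600, n_snps = 40, target_prevalence = 0.7,
                    er_effects = NULL, seed = 35)
  g <- simulate_study(cfg)$genotypes
  g <- simulate_er_status(g, cfg)
  prev <- mean(g$er_status[g$status == 1] == "positive")
  res <- er_subtype_task(g, paste0("snp", 1:40), k_grid = c(5, 10),
                         boost_params = test_boost(n_trees = 40),
                         n_folds = 5, seed = 35)
  se <- res$sd / sqrt(5)
  expect_true(all(abs(res$map - 100 * prev) < 3 * se + 10))
})
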