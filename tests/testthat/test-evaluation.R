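test_that("fold plans are balanced and enumerate all permutations", {
  set.seed(1)
  plan <- kfold_split(1:10, k = 5)
  expect_equal(as.integer(table(plan$assignment$fold)), rep(2L, 5))
  expect_equal(nrow(plan$permutations), choose(5, 3))
  set.seed(2)
  plan11 <- kfold_split(1:11, k = 5)
  expect_setequal(as.integer(table(plan11$assignment$fold)), c(3L, 2L))
  expect_equal(sum(table(plan11$assignment$fold)), 11)
  # every sample in exactly one fold; train and test partition the folds
  expect_equal(sort(plan$assignment$sample_id), 1:10)
  for (j in seq_len(nrow(plan$permutations))) {
    expect_setequal(c(plan$permutations$train_folds[[j]],
                      plan$permutations$test_folds[[j]]), 1:5)
  }
  expect_error(kfold_split(1:3, k = 5), "fewer samples")
})

test_that("trait t-tests match hand-derived statistics and handle degeneracy", {
  expect_equal(trait_ttest(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_lt(trait_ttest(c(0, 0, 0, 0) + c(0, 1e-9, 0, -1e-9),
                        c(10, 10, 10, 10)), 1e-6)
  # hand oracle: means 3 vs 4, both var 2.5, n = 5 -> t = -1, Welch df = 8
  p <- trait_ttest(1:5, 2:6)
  expect_equal(p, 2 * pt(-1, 8), tolerance = 1e-10)
  # degenerate variances resolved without exceptions
  expect_equal(trait_ttest(rep(2, 4), rep(2, 5)), 1)
  expect_equal(trait_ttest(rep(0, 4), rep(10, 4)), 0)
  # pooled variant agrees with stats::t.test var.equal
  expect_equal(trait_ttest(1:6, c(2, 5, 3, 8, 1, 9), var_equal = TRUE),
               t.test(1:6, c(2, 5, 3, 8, 1, 9), var.equal = TRUE)$p.value)
})

test_that("Bonferroni adjustment is the capped product and monotone", {
  expect_equal(bonferroni_adjust(c(0.01, 0.5)), c(0.02, 1.0))
  expect_equal(bonferroni_adjust(0.3), 0.3)
  expect_equal(bonferroni_adjust(rep(0.004, 39)), rep(0.156, 39))
  set.seed(5)
  p <- runif(25)
  adj <- bonferroni_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_error(bonferroni_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("sensitivity rate reproduces the published crown-root values", {
  expect_equal(round(sensitivity_rate(39, 20), 1), 48.7)
  expect_equal(round(sensitivity_rate(39, 24), 1), 38.5)
  expect_equal(sensitivity_rate(39, 0), 100)
  # agrees with an independent confusion-matrix computation
  set.seed(8)
  for (i in 1:25) {
    n <- sample(5:60, 1); m <- sample(0:n, 1)
    conf <- c(tp = n - m, fn = m)           # correct vs misclassified
    expect_equal(sensitivity_rate(n, m),
                 100 * conf[["tp"]] / (conf[["tp"]] + conf[["fn"]]))
  }
  expect_error(sensitivity_rate(10, 11), "n_misclassified")
  expect_error(sensitivity_rate(0, 0), "n_traits")
})

test_that("self-comparison is perfectly sensitive", {
  set.seed(3)
  obs <- tibble::as_tibble(matrix(rnorm(12 * 20), 12, 20,
                                  dimnames = list(NULL, paste0("t", 1:20))))
  rep <- evaluate_traits(obs, obs)
  expect_equal(rep$n_misclassified, 0)
  expect_equal(rep$sensitivity_rate, 100)
  expect_true(all(rep$traits$adjusted_p >= rep$traits$raw_p))
})

test_that("shifted traits are detected with high power", {
  set.seed(4)
  hits <- vapply(1:40, function(i) {
    obs <- matrix(rnorm(12 * 20), 12, 20)
    sim <- matrix(rnorm(12 * 20), 12, 20)
    obs[, 1:5] <- obs[, 1:5] + 10          # +10 pooled sd on 5 traits
    colnames(obs) <- colnames(sim) <- paste0("t", 1:20)
    evaluate_traits(tibble::as_tibble(obs),
                    tibble::as_tibble(sim))$n_misclassified
  }, numeric(1))
  expect_gte(mean(hits >= 5), 0.95)
})

test_that("null family-wise misclassification stays at the alpha level", {
  set.seed(6)
  n_rep <- 400
  fam <- vapply(seq_len(n_rep), function(i) {
    obs <- matrix(rnorm(10 * 20), 10, 20)
    sim <- matrix(rnorm(10 * 20), 10, 20)
    colnames(obs) <- colnames(sim) <- paste0("t", 1:20)
    evaluate_traits(tibble::as_tibble(obs),
                    tibble::as_tibble(sim))$n_misclassified > 0
  }, logical(1))
  fwer <- mean(fam)
  mc_se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lte(fwer, 0.05 + 3 * mc_se)
})

test_that("cross-validation runs the full pipeline over all permutations", {
  obs <- synth_observed_cohort(
    10, config = simulation_config(8, seed = 31, n_primary_roots = 2,
                                   sd_frac = 0.15))
  cv <- cross_validate(dplyr::select(obs, -sample_id, -empty),
                       simulation_config(8, seed = 13, n_primary_roots = 2,
                                         sd_frac = 0.15),
                       t_days = 8, orders = 1:2)
  expect_equal(nrow(tidy(cv)), 10)          # C(5,3) fold permutations
  expect_true(all(tidy(cv)$ok))
  expect_true(all(tidy(cv)$sensitivity_rate >= 0 &
                    tidy(cv)$sensitivity_rate <= 100))
  g <- glance(cv)
  expect_equal(g$mean_misclassified,
               mean(tidy(cv)$n_misclassified))
  # reports round-trip to disk
  f <- withr::local_tempfile(fileext = ".csv")
  fj <- withr::local_tempfile(fileext = ".json")
  write_evaluation_report(cv$reports[[1]], f, fj)
  back <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(nrow(back), cv$reports[[1]]$n_traits)
  js <- jsonlite::read_json(fj)
  expect_equal(js$sensitivity_rate, cv$reports[[1]]$sensitivity_rate)
})

test_that("pipeline failures are flagged, never silently dropped", {
  obs <- tibble::tibble(number_of_root_tips = rep(0, 10),
                        total_root_length = rnorm(10, 300, 30),
                        network_area = rnorm(10, 400, 40),
                        convex_area = rnorm(10, 1600, 100),
                        solidity = runif(10, 0.2, 0.3),
                        max_depth = rnorm(10, 80, 5),
                        avg_diameter = rnorm(10, 1, 0.05),
                        max_diameter = rnorm(10, 3, 0.2),
                        surface_area = rnorm(10, 900, 50),
                        avg_root_orientation = rnorm(10, 30, 4))
  cv <- cross_validate(obs, simulation_config(5, seed = 2,
                                              n_primary_roots = 1),
                       t_days = 5, orders = 1)
  expect_true(all(!tidy(cv)$ok))
  expect_true(all(grepl("number_of_root_tips", tidy(cv)$error)))
})
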