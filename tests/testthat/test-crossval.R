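test_that("stratified folds partition subjects and balance labels", {
  # 10 subjects, 10 folds: every validation fold holds exactly 1 subject
  f <- stratified_folds(rep("a", 10), 10, seed = 1)
  expect_equal(sort(f), 1:10)

  # 100 subjects, two labels 50/50, 10 folds: every fold gets 5 + 5
  labels <- rep(c("ucla", "corr"), each = 50)
  f2 <- stratified_folds(labels, 10, seed = 2)
  tab <- table(labels, f2)
  expect_true(all(tab == 5))

  # a label smaller than the fold count falls back with a warning
  expect_warning(stratified_folds(c(rep("big", 20), rep("small", 3)), 10,
                                  seed = 3),
                 "fewer subjects")
  expect_error(stratified_folds(rep("a", 5), 10), "at least as many")
})

test_that("cross-validation reports per-fold medians and the gap", {
  set.seed(11)
  X <- matrix(rnorm(40 * 91), 40, 91)
  labels <- rep(c("ucla", "corr"), each = 20)
  cv <- cross_validate(tiny_spec(epochs = 30), X, labels, fold_count = 4)
  expect_equal(nrow(cv$fold), 4)
  expect_true(all(is.finite(cv$fold$median_train)))
  expect_true(all(is.finite(cv$fold$median_val)))
  expect_equal(cv$mean_train_median, mean(cv$fold$median_train))
  expect_equal(cv$gap, cv$mean_val_median - cv$mean_train_median)
})

test_that("a constant cohort cross-validates to ~zero error", {
  v <- seq(-1, 1, length.out = 91)
  X <- matrix(rep(v, each = 20), 20, 91)
  spec <- autoencoder_spec(epochs = 250, dropout_rate = 0, seed = 4)
  cv <- cross_validate(spec, X, fold_count = 4, standardize = FALSE)
  expect_lt(max(cv$fold$median_train), 0.02)
  expect_lt(max(cv$fold$median_val), 0.02)
  expect_lt(abs(cv$gap), 0.02)
})

test_that("validation error exceeds training error on average", {
  # overfitting direction on a small synthetic healthy cohort
  cohort <- generate_cohort(
    cohort_config(n_per_group = c("H-Train" = 40, "H-Test" = 2),
                  train_group = "H-Train", n_timepoints = 60,
                  perturbations = list(), seed = 21))
  feats <- cohort_features(cohort)
  X <- feats$features[feats$manifest$group == "H-Train", ]
  cv <- cross_validate(tiny_spec(epochs = 120, seed = 3), X,
                       fold_count = 5)
  expect_gt(cv$gap, -0.05)  # tolerance for noise
})

test_that("model-selection metrics are min-max normalized and summed", {
  cand <- data.frame(performance = c(0.2, 0.6, 1.0),
                     gap = c(0.30, 0.15, 0.00))
  ns <- normalize_selection_metrics(cand)
  expect_equal(ns$normalized$performance, c(0, 0.5, 1))
  expect_equal(ns$normalized$gap, c(1, 0.5, 0))
  # all candidates tie on the sum; the first (lowest index) wins
  expect_equal(ns$selected, 1L)

  cand2 <- data.frame(performance = c(0.5, 0.1, 0.9),
                      gap = c(0.2, 0.4, 0.9))
  expect_equal(normalize_selection_metrics(cand2)$selected, 2L)

  expect_warning(
    ns3 <- normalize_selection_metrics(
      data.frame(performance = c(1, 1), gap = c(0, 1))),
    "constant")
  expect_equal(ns3$normalized$performance, c(0, 0))
  expect_error(normalize_selection_metrics(
    data.frame(performance = 1, gap = 1)), "at least 2")
})
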