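test_that("subject time series reproduce the template at large T", {
  atlas3 <- tiny_atlas()
  tpl <- diag(3); dimnames(tpl) <- list(atlas3$labels, atlas3$labels)
  ts <- sample_subject_timeseries(tpl, subject_sd = 0, n_timepoints = 1e5,
                                  seed = 42)
  r <- cor(ts)
  expect_true(all(abs(r[lower.tri(r)]) < 0.02))

  tpl2 <- matrix(c(1, 0.8, 0, 0.8, 1, 0, 0, 0, 1), 3, 3)
  dimnames(tpl2) <- list(atlas3$labels, atlas3$labels)
  ts2 <- sample_subject_timeseries(tpl2, subject_sd = 0,
                                   n_timepoints = 2e4, seed = 43)
  expect_equal(cor(ts2)[2, 1], 0.8, tolerance = 0.05)
})

test_that("time-series sampling is deterministic and standardized", {
  tpl <- make_base_correlation(seed = 3)
  a <- sample_subject_timeseries(tpl, 0.1, 100, seed = 9)
  b <- sample_subject_timeseries(tpl, 0.1, 100, seed = 9)
  expect_identical(a, b)
  expect_equal(unname(colMeans(a)), rep(0, 14), tolerance = 1e-10)
  expect_equal(unname(apply(a, 2, sd)), rep(1, 14), tolerance = 1e-10)
  expect_error(sample_subject_timeseries(tpl, 0.1, 10, seed = 1),
               ">= 30")
})

test_that("cohort generation books subjects and truth correctly", {
  cfg <- cohort_config(
    n_per_group = c("H-Train" = 4, "H-Test" = 2),
    train_group = "H-Train", n_timepoints = 40,
    perturbations = list(), seed = 1)
  cohort <- generate_cohort(cfg)
  expect_equal(nrow(cohort$manifest), 6)
  expect_length(cohort$timeseries, 6)
  expect_length(cohort$truth, 0)

  cfg2 <- tiny_cohort_config()
  cohort2 <- generate_cohort(cfg2)
  expect_equal(sort(cohort2$truth[["SCZ"]]$k),
               sort(c(pair_to_k("ASN", "BGN"), pair_to_k("BGN", "HVN"))))
  expect_equal(cohort2$truth[["BD"]]$k, pair_to_k("BGN", "LN"))

  # identical config => byte-identical outputs
  cohort3 <- generate_cohort(tiny_cohort_config())
  expect_identical(cohort2$timeseries, cohort3$timeseries)

  expect_error(cohort_config(
    n_per_group = c("H-Train" = 4, "H-Test" = 2),
    perturbations = list("GHOST" = list(list(pair = c("ASN", "BGN"),
                                             delta = 0.1)))),
    "unknown group")
})

test_that("extending a cohort never reshuffles existing subjects", {
  base_groups <- c("H-Train" = 5, "H-Test" = 3)
  cfg_small <- cohort_config(n_per_group = base_groups,
                             train_group = "H-Train", n_timepoints = 40,
                             perturbations = list(), seed = 2)
  cfg_big <- cohort_config(n_per_group = c(base_groups, "EXTRA" = 4),
                           train_group = "H-Train", n_timepoints = 40,
                           perturbations = list(), seed = 2)
  small <- generate_cohort(cfg_small)
  big <- generate_cohort(cfg_big)
  shared <- names(small$timeseries)
  expect_identical(big$timeseries[shared], small$timeseries)
})

test_that("injected pairs deviate more than non-injected pairs", {
  # Monte-Carlo separation check: mean |empirical r - healthy template r|
  # larger at injected pairs than elsewhere (delta 0.4, T = 150, n = 30)
  atlas <- fbn_atlas()
  cfg <- cohort_config(
    n_per_group = c("H-Train" = 2, "H-Test" = 2, "P" = 30),
    train_group = "H-Train", n_timepoints = 150,
    perturbations = list("P" = default_perturbations()[["SCZ-Test-U"]]),
    seed = 77)
  cohort <- generate_cohort(cfg)
  tpl_vec <- vectorize(cfg$base_correlation, atlas)
  p_ids <- cohort$manifest$subject_id[cohort$manifest$group == "P"]
  devs <- sapply(p_ids, function(sid) {
    r <- vectorize(correlation_matrix(cohort$timeseries[[sid]], atlas),
                   atlas)
    abs(r - tpl_vec)
  })
  mean_dev <- rowMeans(devs)
  injected <- cohort$truth[["P"]]$k
  expect_gt(min(mean_dev[injected]), max(0, mean(mean_dev[-injected])))
  expect_gt(mean(mean_dev[injected]), 2 * mean(mean_dev[-injected]))
})

test_that("cohort files round-trip through the on-disk format", {
  cfg <- cohort_config(n_per_group = c("H-Train" = 3, "H-Test" = 2),
                       train_group = "H-Train", n_timepoints = 40,
                       perturbations = list(), seed = 4)
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(cfg, out_dir = dir)
  man <- read.delim(file.path(dir, "manifest.tsv"))
  expect_equal(nrow(man), 5)
  ts <- as.matrix(read.delim(file.path(dir,
                                       paste0(man$subject_id[1], ".tsv"))))
  expect_equal(dim(ts), c(40, 14))
  expect_equal(unname(ts),
               unname(round(cohort$timeseries[[man$subject_id[1]]], 6)))
})

test_that("motion tables honor the contamination switch", {
  clean <- generate_motion_table(100, contaminate = FALSE, seed = 8)
  expect_true(motion_qc(clean)$pass)
  expect_true(all(clean$fd >= 0))

  dirty <- generate_motion_table(100, contaminate = TRUE, seed = 8)
  qc <- motion_qc(dirty)
  expect_false(qc$pass)
  expect_gt(length(qc$violated), 0)

  expect_identical(generate_motion_table(50, TRUE, seed = 3),
                   generate_motion_table(50, TRUE, seed = 3))
  expect_error(generate_motion_table(1), ">= 2")
})
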