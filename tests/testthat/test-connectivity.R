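test_that("motion QC reads 'exceeded' as a strict inequality", {
  zero <- data.frame(trans_x = 0, trans_y = 0, trans_z = 0,
                     rot_x = 0, rot_y = 0, rot_z = 0, fd = 0)
  zero <- zero[rep(1, 10), ]
  qc <- motion_qc(zero)
  expect_true(qc$pass)
  expect_length(qc$violated, 0)

  # max FD exactly at the 3 mm bound still passes
  at_bound <- zero; at_bound$fd[5] <- 3.0
  expect_true(motion_qc(at_bound)$pass)

  rot <- zero; rot$rot_y[3] <- 3.5
  qc_rot <- motion_qc(rot)
  expect_false(qc_rot$pass)
  expect_identical(qc_rot$violated, "rotation")

  trans <- zero; trans$trans_z[2] <- -3.2
  expect_identical(motion_qc(trans)$violated, "translation")

  fd <- zero; fd$fd[4] <- 3.01
  expect_identical(motion_qc(fd)$violated, "fd")

  expect_error(motion_qc(zero[, -1]), "malformed")
})

test_that("framewise displacement is the Power-style parameter sum", {
  m <- data.frame(trans_x = c(0, 1), trans_y = c(0, 0), trans_z = c(0, 0),
                  rot_x = c(0, 0), rot_y = c(0, 0), rot_z = c(0, 0))
  expect_equal(framewise_displacement(m), c(0, 1))
  # one degree of rotation = pi/180 * 50 mm of arc on the 50 mm sphere
  m2 <- data.frame(trans_x = 0, trans_y = 0, trans_z = 0,
                   rot_x = c(0, 1), rot_y = 0, rot_z = 0)
  expect_equal(framewise_displacement(m2), c(0, pi / 180 * 50))
})

test_that("correlation_matrix computes Pearson r with exact symmetry", {
  atlas3 <- tiny_atlas()
  x <- c(1, 2, 3, 4)
  y <- c(1, 2, 2, 4)
  ts <- cbind(A = x, B = y, C = c(4, 1, 3, 2))
  cm <- correlation_matrix(ts, atlas3)
  # hand evaluation of the Pearson formula for (x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cm$values["B", "A"], r_hand)
  # 4.5 / sqrt(5 * 4.75) by direct evaluation
  expect_equal(r_hand, 4.5 / sqrt(23.75), tolerance = 1e-12)
  expect_identical(cm$values, t(cm$values))
  expect_equal(unname(diag(cm$values)), rep(1, 3))

  # perfect correlation and anticorrelation
  ts2 <- cbind(A = x, B = x, C = -x)
  cm2 <- correlation_matrix(ts2, atlas3)
  expect_equal(cm2$values["B", "A"], 1)
  expect_equal(cm2$values["C", "A"], -1)

  expect_error(correlation_matrix(cbind(A = x, B = y, C = rep(1, 4)),
                                  atlas3),
               "degenerate signal.*C")
  expect_error(correlation_matrix(ts[1:2, ], atlas3), "3 time points")
  expect_error(correlation_matrix(ts[, 1:2], atlas3), "3 columns")
})

test_that("Pearson r is invariant under affine rescaling of a column", {
  atlas3 <- tiny_atlas()
  set.seed(10)
  ts <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, atlas3$labels))
  base <- correlation_matrix(ts, atlas3)$values
  for (s in 1:5) {
    set.seed(s)
    a <- runif(1, 0.1, 5); b <- rnorm(1, sd = 10)
    ts2 <- ts; ts2[, 2] <- a * ts[, 2] + b
    expect_equal(correlation_matrix(ts2, atlas3)$values, base,
                 tolerance = 1e-10)
  }
  expect_true(all(abs(base) <= 1))
})

test_that("cohort feature matrices have one 91-vector per subject", {
  cohort <- generate_cohort(
    cohort_config(n_per_group = c("H-Train" = 3, "H-Test" = 2),
                  train_group = "H-Train", n_timepoints = 40,
                  perturbations = list(), seed = 5))
  feats <- cohort_features(cohort)
  expect_equal(dim(feats$features), c(5, 91))
  expect_identical(rownames(feats$features),
                   cohort$manifest$subject_id)
  path <- file.path(withr::local_tempdir(), "features.tsv")
  write_features(feats$features, path)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".pairs.json")))
  back <- as.matrix(read.delim(path, row.names = 1))
  expect_equal(unname(back), unname(feats$features), tolerance = 1e-12)
})
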