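test_that("Mann-Whitney exact path matches exhaustive enumeration", {
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)

  set.seed(12)
  for (n1 in c(3, 5, 7)) for (n2 in c(3, 6, 7)) {
    x <- rnorm(n1)
    y <- rnorm(n2)
    got <- mann_whitney(x, y)
    want <- oracle_mann_whitney(x, y)
    expect_equal(got$U, want$U)
    expect_equal(got$p_value, want$p_value)
    # with ties
    xt <- sample(1:3, n1, replace = TRUE)
    yt <- sample(1:3, n2, replace = TRUE)
    if (length(unique(c(xt, yt))) > 1) {
      got_t <- mann_whitney(xt, yt)
      want_t <- oracle_mann_whitney(xt, yt)
      expect_equal(got_t$U, want_t$U)
      expect_equal(got_t$p_value, want_t$p_value)
    }
  }

  # tie-free small samples also agree with wilcox.test's exact p
  set.seed(13)
  x <- rnorm(6); y <- rnorm(7)
  expect_equal(mann_whitney(x, y)$p_value,
               wilcox.test(x, y, exact = TRUE)$p.value)

  expect_warning(res <- mann_whitney(rep(1, 5), rep(1, 4)), "identical")
  expect_equal(res$p_value, 1)
  expect_equal(res$U, 5 * 4 / 2)
})

test_that("group comparison table reports Shapiro, medians and raw p", {
  set.seed(14)
  groups <- list(H = rnorm(20, 0), SCZ = rnorm(20, 3), BD = rnorm(20, 3))
  cmp <- compare_groups(groups)
  expect_equal(nrow(cmp), 3)  # all pairwise
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
  expect_true(all(cmp$shapiro_p_i >= 0 & cmp$shapiro_p_i <= 1))
  expect_equal(cmp$median_i[1], median(groups$H))
  h_scz <- cmp[cmp$group_i == "H" & cmp$group_j == "SCZ", ]
  expect_lt(h_scz$p_value, 0.01)
  expect_error(compare_groups(list(a = 1:2, b = 1:5)), "at least 3")
})

test_that("merged threshold retains the requested top fraction", {
  thr <- merged_threshold(1:10, top_fraction = 0.2)
  expect_equal(sum(1:10 >= thr), 2)
  expect_true(all(c(9, 10) >= thr))

  expect_warning(thr2 <- merged_threshold(rep(2, 5), 0.2), "identical")
  expect_equal(as.numeric(thr2), 2)
  expect_equal(attr(thr2, "retained_fraction"), 1)

  set.seed(15)
  thr3 <- merged_threshold(rnorm(1000), 0.2)
  expect_equal(as.numeric(thr3), qnorm(0.8), tolerance = 0.1)

  expect_error(merged_threshold(numeric(0)), "empty")
  expect_error(merged_threshold(1:5, 1.5), "top_fraction")
})

test_that("thresholding is monotone in the retained fraction", {
  set.seed(16)
  v <- rnorm(500)
  retained <- function(f) sum(v >= merged_threshold(v, f))
  fr <- c(0.05, 0.1, 0.2, 0.4, 0.8)
  counts <- vapply(fr, retained, 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("binarized graphs count degrees correctly", {
  atlas <- fbn_atlas()
  g_full <- binarize_and_degree(rep(1, 91), threshold = 0.5, atlas)
  expect_true(all(g_full$degree == 13))
  g_none <- binarize_and_degree(rep(0, 91), threshold = 0.5, atlas)
  expect_true(all(g_none$degree == 0))

  v <- numeric(91); v[pair_to_k("ASN", "BGN", atlas)] <- 1
  g_one <- binarize_and_degree(v, threshold = 0.5, atlas)
  expect_equal(g_one$degree[["ASN"]], 1)
  expect_equal(g_one$degree[["BGN"]], 1)
  expect_equal(sum(g_one$degree), 2)
  expect_identical(g_one$adjacency, t(g_one$adjacency))
  expect_true(all(diag(g_one$adjacency) == 0))
})

test_that("group degree summaries take per-network medians", {
  atlas <- fbn_atlas()
  v1 <- numeric(91); v1[pair_to_k("ASN", "BGN", atlas)] <- 1
  g1 <- binarize_and_degree(v1, 0.5, atlas)
  s1 <- group_degree_summary(list(g1))
  expect_equal(unname(s1$median_degree), unname(g1$degree))
  expect_equal(sum(s1$histogram), 14)

  g2 <- binarize_and_degree(rep(1, 91), 0.5, atlas)  # degrees all 13
  v3 <- numeric(91)
  ks <- c(pair_to_k("ASN", "BGN", atlas), pair_to_k("ASN", "AN", atlas),
          pair_to_k("ASN", "HVN", atlas))
  v3[ks] <- 1
  g3 <- binarize_and_degree(v3, 0.5, atlas)  # ASN degree 3
  s2 <- group_degree_summary(list(g3, g2))
  # medians of two subjects: even count -> midpoint
  expect_equal(s2$median_degree[["ASN"]], (3 + 13) / 2)
  expect_equal(s2$median_degree[["PVN"]], (0 + 13) / 2)
})

test_that("MSE_f is the per-feature group mean of squared residuals", {
  atlas <- fbn_atlas()
  one <- matrix(rnorm(91), 1, 91)
  gem1 <- mse_per_feature(one, "g", atlas)
  expect_equal(unname(gem1$mse_f), as.numeric(one^2))
  expect_false(gem1$subtracted)

  two <- rbind(rep(1, 91), rep(-1, 91))
  gem2 <- mse_per_feature(two, "g", atlas)
  expect_equal(unname(gem2$mse_f), rep(1, 91))

  # conservation identity against per-subject MSE_s
  set.seed(17)
  resid <- matrix(rnorm(30 * 91), 30, 91)
  gem3 <- mse_per_feature(resid, "g", atlas)
  expect_equal(mean(gem3$mse_f), mean(rowMeans(resid^2)),
               tolerance = 1e-12)
})

test_that("healthy subtraction is elementwise and flagged", {
  atlas <- fbn_atlas()
  set.seed(18)
  p <- mse_per_feature(matrix(rnorm(10 * 91, 2), 10, 91), "P", atlas)
  h <- mse_per_feature(matrix(rnorm(10 * 91), 10, 91), "H", atlas)
  d <- subtract_healthy(p, h)
  expect_true(d$subtracted)
  expect_equal(d$mse_f, p$mse_f - h$mse_f)
  expect_equal(d$matrix, p$matrix - h$matrix)

  # patient == healthy -> exactly zero
  z <- subtract_healthy(p, p)
  expect_true(all(z$mse_f == 0))

  # healthy == 0 -> patient unchanged
  h0 <- h; h0$mse_f[] <- 0; h0$matrix[] <- 0
  expect_equal(subtract_healthy(p, h0)$mse_f, p$mse_f)

  # spot arithmetic at one pair
  p2 <- p; p2$mse_f[3] <- 0.9
  h2 <- h; h2$mse_f[3] <- 0.4
  expect_equal(unname(subtract_healthy(p2, h2)$mse_f[3]), 0.5)

  expect_error(subtract_healthy(d, h), "unsubtracted")
})

test_that("top-fraction selection keeps floor(f * 91) pairs, ties broken
          deterministically", {
  atlas <- fbn_atlas()
  set.seed(19)
  for (s in 1:5) {
    gem <- mse_per_feature(matrix(rnorm(5 * 91), 5, 91), "g", atlas)
    expect_equal(nrow(top_fraction_pairs(gem, 0.10)), 9)
  }
  gem <- mse_per_feature(matrix(rnorm(5 * 91), 5, 91), "g", atlas)
  all_pairs <- top_fraction_pairs(gem, 1.0)
  expect_equal(nrow(all_pairs), 91)
  expect_true(all(diff(all_pairs$value) <= 0))

  # a unique maximum is ranked first
  gem$mse_f[pair_to_k("HVN", "RECN", atlas)] <- max(gem$mse_f) + 1
  expect_equal(top_fraction_pairs(gem, 0.10)$pair[1], "RECN-HVN")

  # exact ties resolve by ascending pair index
  gem2 <- gem; gem2$mse_f[] <- 1
  top <- top_fraction_pairs(gem2, 0.10)
  expect_equal(top$k, 1:9)
})

test_that("characterization applies rules (1) and (3) across conditions", {
  ch <- characterize_group(
    a_before = c("p1", "p2", "p5"), a_after = c("p1", "p3", "p5"),
    b_before = c("p1", "p2", "p6"), b_after = c("p1", "p3", "p6"))
  expect_equal(ch$rule1, "p1")          # in all four sets
  expect_equal(ch$rule3, "p3")          # after-only, both conditions
  expect_equal(ch$rule2, "p2")          # before-only, both conditions
  expect_setequal(ch$characteristic, c("p1", "p3"))
  expect_length(intersect(ch$rule1, ch$rule3), 0)
  expect_error(characterize_group(c("p1"), NULL, c("p1"), c("p1")),
               "missing")
})

test_that("individual-level matrices flag subjects above healthy medians", {
  abs_diff <- rbind(H1 = c(a = 0, b = 0), H2 = c(a = 0.2, b = 0.2),
                    H3 = c(a = 0.4, b = 0.4), P1 = c(a = 1, b = 1),
                    P2 = c(a = 0, b = 0))
  res <- individual_level_matrix(c("a", "b"), abs_diff,
                                 groups = c("H", "H", "H", "P", "P"),
                                 healthy_group = "H")
  expect_equal(dim(res$matrix), c(5, 2))
  expect_true(res$exceeds_healthy_median[["P1"]])
  expect_false(res$exceeds_healthy_median[["P2"]])
  # a perfectly reconstructed healthy subject keeps an all-zero row
  expect_true(all(res$matrix["H1", ] == 0))
  expect_error(individual_level_matrix(character(0), abs_diff,
                                       rep("H", 5), "H"),
               "no characteristic pairs")
  expect_error(individual_level_matrix(c("zz"), abs_diff, rep("H", 5),
                                       "H"),
               "unknown pair")
})

test_that("null calibration of the approximate test is honest", {
  # smaller companion to the acceptance-scale calibration: 400 null
  # simulations at n = 20 per group
  set.seed(20)
  rej <- mean(replicate(400, {
    mann_whitney(rnorm(20), rnorm(20))$p_value < 0.05
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})
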