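#' Mann-Whitney U test with exact small-sample enumeration
#'
#' For min(n1, n2) <= `exact_max` the permutation null of U is enumerated
#' exhaustively over all choose(n1+n2, n1) group assignments (midranks, so
#' ties are handled exactly); the two-sided p-value is
#' min(1, 2 * min(P(U <= u), P(U >= u))). Larger samples use the
#' tie-corrected normal approximation of [stats::wilcox.test()].
#'
#' @param x,y Numeric samples.
#' @param alternative "two.sided" (default), "less" or "greater".
#' @param exact_max Largest min(n1, n2) for which the exact null is
#'   enumerated (default 8).
#' @return List: `U` (statistic for `x`), `p_value`, `method`.
#' @export
mann_whitney <- function(x, y, alternative = "two.sided", exact_max = 8L) {
  alternative <- match.arg(alternative, c("two.sided", "less", "greater"))
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both samples must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(pooled)) == 1) {
    warning("all values identical in both groups; test undefined, p = 1")
    return(list(U = u_obs, p_value = 1, method = "degenerate"))
  }
  if (min(n1, n2) <= exact_max) {
    combs <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    tol <- 1e-9
    p_le <- mean(u_all <= u_obs + tol)
    p_ge <- mean(u_all >= u_obs - tol)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge,
                less = p_le)
    return(list(U = u_obs, p_value = p, method = "exact enumeration"))
  }
  wt <- stats::wilcox.test(x, y, alternative = alternative, exact = FALSE,
                           correct = TRUE)
  list(U = unname(wt$statistic), p_value = wt$p.value,
       method = "normal approximation (tie-corrected)")
}

#' Group comparisons of per-subject reconstruction error
#'
#' For each requested pair of groups, reports Shapiro-Wilk normality
#' p-values per group (reported only, never used to gate), the
#' Mann-Whitney U test on the MSE_s values, and the group medians. No
#' multiple-testing correction is applied across comparisons; p-values
#' are raw.
#'
#' @param mse_by_group Named list: group -> numeric vector of MSE_s.
#' @param pairs List of length-2 character vectors; defaults to all
#'   pairwise combinations in order.
#' @param alternative Passed to [mann_whitney()].
#' @return data.frame: group_i, group_j, shapiro_p_i, shapiro_p_j,
#'   median_i, median_j, U, p_value.
#' @export
compare_groups <- function(mse_by_group, pairs = NULL,
                           alternative = "two.sided") {
  groups <- names(mse_by_group)
  if (any(vapply(mse_by_group, length, 0L) < 3))
    stop("each group needs at least 3 subjects")
  if (is.null(pairs)) {
    cb <- utils::combn(groups, 2)
    pairs <- lapply(seq_len(ncol(cb)), function(i) cb[, i])
  }
  shapiro_p <- vapply(mse_by_group, function(v) {
    if (stats::sd(v) == 0) return(NA_real_)
    stats::shapiro.test(v)$p.value
  }, 0)
  rows <- lapply(pairs, function(pr) {
    g1 <- pr[1]; g2 <- pr[2]
    if (!all(pr %in% groups)) stop("unknown group in pairs: ",
                                   paste(pr, collapse = ", "))
    mw <- mann_whitney(mse_by_group[[g1]], mse_by_group[[g2]],
                       alternative = alternative)
    data.frame(group_i = g1, group_j = g2,
               shapiro_p_i = shapiro_p[[g1]], shapiro_p_j = shapiro_p[[g2]],
               median_i = stats::median(mse_by_group[[g1]]),
               median_j = stats::median(mse_by_group[[g2]]),
               U = mw$U, p_value = mw$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Threshold retaining the top fraction of merged deviation values
#'
#' Merges the per-feature absolute reconstruction differences of all test
#' subjects into one vector and returns its (1 - top_fraction) quantile
#' (linear-interpolation quantile); values >= the threshold are retained.
#' Ties at the threshold are all retained; the realized retained fraction
#' is attached as an attribute.
#'
#' @param abs_diff Matrix (subjects x features) or numeric vector of
#'   absolute differences, in standardized units.
#' @param top_fraction Fraction to retain (default 0.20).
#' @return The threshold (numeric scalar) with attribute
#'   `retained_fraction`.
#' @export
merged_threshold <- function(abs_diff, top_fraction = 0.20) {
  v <- as.numeric(abs_diff)
  if (!length(v)) stop("empty input")
  if (top_fraction <= 0 || top_fraction >= 1)
    stop("top_fraction must be in (0, 1)")
  if (min(v) == max(v)) {
    warning("all merged values identical; every entry retained")
    thr <- v[1]
  } else {
    thr <- unname(stats::quantile(v, 1 - top_fraction, type = 7))
  }
  attr(thr, "retained_fraction") <- mean(v >= thr)
  thr
}

#' Binarize one subject's deviation vector and compute node degrees
#'
#' An edge joins two networks when the absolute reconstruction difference
#' of their pair is at or above the threshold; degrees count edges per
#' network on the symmetrized graph (0..13 for 14 networks).
#'
#' @param abs_diff_vector Numeric vector of length `atlas$n_pairs`.
#' @param threshold From [merged_threshold()].
#' @param atlas An `fbn_atlas`.
#' @return List of class `deviation_graph`: `adjacency` (symmetric 0/1
#'   matrix), `threshold`, `degree` (named integer vector).
#' @export
binarize_and_degree <- function(abs_diff_vector, threshold,
                                atlas = fbn_atlas()) {
  adj <- devectorize(as.numeric(abs_diff_vector >= threshold), atlas,
                     symmetric = TRUE)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  structure(list(adjacency = adj, threshold = as.numeric(threshold),
                 degree = igraph::degree(g)),
            class = "deviation_graph")
}

#' Median node degree per network and its distribution for a group
#'
#' @param graphs List of `deviation_graph`s (one subject each) from one
#'   group.
#' @return List: `median_degree` (named length-14 vector),
#'   `histogram` (counts of networks at each median degree 0..n-1).
#' @export
group_degree_summary <- function(graphs) {
  if (!length(graphs)) stop("need at least one subject")
  deg <- t(vapply(graphs, function(g) g$degree,
                  numeric(length(graphs[[1]]$degree))))
  med <- apply(deg, 2, stats::median)
  n_nodes <- ncol(deg)
  hist_counts <- table(factor(med, levels = 0:(n_nodes - 1)))
  list(median_degree = med, histogram = hist_counts)
}

#' Per-feature mean squared reconstruction error of a group
#'
#' MSE_f for feature k is the mean over the group's subjects of the
#' squared reconstruction residual at k; the 91 values are reshaped to
#' the lower-triangular network-pair layout.
#'
#' @param abs_diff Group's subjects x features matrix of absolute (or
#'   signed) residuals; they are squared here.
#' @param group Group name.
#' @param atlas An `fbn_atlas`.
#' @return List of class `group_error_matrix`: `group`, `mse_f` (named
#'   length-91 vector), `matrix` (14 x 14 lower-triangular),
#'   `n_subjects`, `subtracted` (FALSE).
#' @export
mse_per_feature <- function(abs_diff, group = "group",
                            atlas = fbn_atlas()) {
  x <- as.matrix(abs_diff)
  if (nrow(x) < 1) stop("need at least one subject")
  mse_f <- colMeans(x^2)
  names(mse_f) <- pair_index(atlas)$pair
  structure(list(group = group, mse_f = mse_f,
                 matrix = devectorize(mse_f, atlas),
                 n_subjects = nrow(x), subtracted = FALSE),
            class = "group_error_matrix")
}

#' Subtract the healthy group's error matrix from a patient group's
#'
#' Removes pairs that are hard to reconstruct even for healthy subjects,
#' isolating patient-specific error. Entries may be negative after
#' subtraction.
#'
#' @param patient,healthy `group_error_matrix` objects on the same atlas,
#'   both unsubtracted.
#' @return A `group_error_matrix` with `subtracted = TRUE`.
#' @export
subtract_healthy <- function(patient, healthy) {
  stopifnot(inherits(patient, "group_error_matrix"),
            inherits(healthy, "group_error_matrix"))
  if (patient$subtracted || healthy$subtracted)
    stop("inputs must be unsubtracted error matrices")
  if (!identical(names(patient$mse_f), names(healthy$mse_f)))
    stop("atlas/pair mismatch between the two error matrices")
  out <- patient
  out$mse_f <- patient$mse_f - healthy$mse_f
  out$matrix <- patient$matrix - healthy$matrix
  out$subtracted <- TRUE
  out
}

#' Worst-reconstructed network pairs (top fraction of MSE_f)
#'
#' Selects the floor(fraction * 91) pairs with the largest values — 9
#' pairs at the default 10%. Ties break deterministically: descending
#' value, then ascending pair index.
#'
#' @param gem A `group_error_matrix` (subtracted or not).
#' @param fraction Fraction of pairs to keep (default 0.10).
#' @return data.frame: `pair`, `k`, `value`, ordered worst-first.
#' @export
top_fraction_pairs <- function(gem, fraction = 0.10) {
  stopifnot(inherits(gem, "group_error_matrix"))
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  v <- gem$mse_f
  n_keep <- max(1L, floor(fraction * length(v)))
  ord <- order(-v, seq_along(v))
  sel <- ord[seq_len(n_keep)]
  data.frame(pair = names(v)[sel], k = sel, value = unname(v[sel]),
             stringsAsFactors = FALSE)
}

#' Characteristic pairs of a patient group under two healthy-split
#' conditions
#'
#' A pair characterizes a patient group when, for BOTH healthy-test-set
#' conditions (a) and (b), it is either (rule 1) in the top-10% set both
#' before and after healthy subtraction, or (rule 3) absent before but
#' present after. Pairs highlighted only before subtraction (rule 2) are
#' unstable even among healthy subjects and are reported separately as
#' non-characteristic.
#'
#' @param a_before,a_after,b_before,b_after Character vectors of pair
#'   labels (or the data.frames from [top_fraction_pairs()]).
#' @return List of class `characterization`: `rule1`, `rule3`,
#'   `characteristic` (their union), `rule2`.
#' @export
characterize_group <- function(a_before, a_after, b_before, b_after) {
  as_set <- function(x) {
    if (is.data.frame(x)) x <- x$pair
    if (is.null(x)) stop("missing condition set")
    unique(as.character(x))
  }
  ab <- as_set(a_before); aa <- as_set(a_after)
  bb <- as_set(b_before); ba <- as_set(b_after)
  rule1 <- intersect(intersect(ab, aa), intersect(bb, ba))
  rule3 <- intersect(setdiff(aa, ab), setdiff(ba, bb))
  rule2 <- intersect(setdiff(ab, aa), setdiff(bb, ba))
  structure(list(rule1 = rule1, rule3 = rule3,
                 characteristic = union(rule1, rule3), rule2 = rule2),
            class = "characterization")
}

#' Individual-level deviation at the characteristic pairs
#'
#' Restricts every test subject's absolute-difference vector to the
#' characteristic pairs, and flags subjects whose deviation exceeds the
#' healthy-group median at half or more of those pairs (a simple
#' within-group heterogeneity summary).
#'
#' @param characteristic_pairs Character vector of pair labels.
#' @param abs_diff All test subjects x 91 matrix (rownames = subject ids,
#'   colnames = pair labels).
#' @param groups Per-subject group labels aligned with `abs_diff` rows.
#' @param healthy_group Name of the healthy test group.
#' @return List: `matrix` (subjects x pairs), `groups`,
#'   `exceeds_healthy_median` (logical per subject).
#' @export
individual_level_matrix <- function(characteristic_pairs, abs_diff,
                                    groups, healthy_group) {
  if (!length(characteristic_pairs)) stop("no characteristic pairs given")
  missing_p <- setdiff(characteristic_pairs, colnames(abs_diff))
  if (length(missing_p)) stop("unknown pair label(s): ",
                              paste(missing_p, collapse = ", "))
  m <- abs_diff[, characteristic_pairs, drop = FALSE]
  if (length(groups) != nrow(m)) stop("groups must align with subjects")
  if (!healthy_group %in% groups) stop("healthy group absent")
  healthy_med <- apply(m[groups == healthy_group, , drop = FALSE], 2,
                       stats::median)
  flag <- rowMeans(sweep(m, 2, healthy_med, ">")) >= 0.5
  list(matrix = m, groups = groups, exceeds_healthy_median = flag)
}

#' Export a selected-pairs table as a connectogram edge list
#'
#' @param top_pairs data.frame from [top_fraction_pairs()].
#' @param path Output path (tab-delimited: node_i, node_j, weight).
#' @param atlas An `fbn_atlas`.
#' @export
write_edge_list <- function(top_pairs, path, atlas = fbn_atlas()) {
  pi <- pair_index(atlas)
  m <- pi[match(top_pairs$k, pi$k), ]
  utils::write.table(data.frame(node_i = m$label_i, node_j = m$label_j,
                                weight = top_pairs$value),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
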