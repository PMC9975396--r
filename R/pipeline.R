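#' Full-run configuration
#'
#' Bundles the cohort definition, the autoencoder spec and the analysis
#' parameters for [run_pipeline()]. One master seed is fanned out to the
#' simulation, the model and the fold assignment.
#'
#' @param cohort A [cohort_config()].
#' @param spec An [autoencoder_spec()].
#' @param healthy_test Name of the healthy test group used for baseline
#'   subtraction and group comparisons.
#' @param top_fraction_degree Fraction of merged deviation values retained
#'   when binarizing (default 0.20).
#' @param top_fraction_pairs Fraction of worst-reconstructed pairs
#'   selected (default 0.10: 9 of 91).
#' @param alpha Nominal significance level reported alongside the group
#'   comparisons (default 0.05).
#' @param condition_b Also run the doubled-healthy-test condition (b)
#'   (re-split the healthy pool, retrain from scratch) and characterize
#'   groups across both conditions? Default TRUE.
#' @param seed Master seed; overrides the cohort and spec seeds.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       spec = autoencoder_spec(),
                       healthy_test = NULL,
                       top_fraction_degree = 0.20,
                       top_fraction_pairs = 0.10,
                       alpha = 0.05,
                       condition_b = TRUE,
                       seed = 1L) {
  seed <- as.integer(seed)
  cohort$seed <- seed
  spec$seed <- seed + 1L
  if (is.null(healthy_test)) {
    ht <- setdiff(names(cohort$n_per_group),
                  c(cohort$train_group, names(cohort$perturbations)))
    healthy_test <- if (length(ht)) ht[1] else NA_character_
  }
  cfg <- structure(list(cohort = cohort, spec = spec,
                        healthy_test = healthy_test,
                        top_fraction_degree = top_fraction_degree,
                        top_fraction_pairs = top_fraction_pairs,
                        alpha = alpha, condition_b = condition_b,
                        seed = seed),
                   class = "run_config")
  diag <- validate_config(cfg)
  if (length(diag)) stop("invalid run config: ",
                         paste(diag, collapse = "; "))
  cfg
}

#' Validate a run configuration
#'
#' Schema and cross-field checks; returns diagnostics instead of
#' throwing, so callers can present them.
#'
#' @param config A `run_config` (or bare list with the same fields).
#' @return Character vector of diagnostics; empty when the config is ok.
#' @export
validate_config <- function(config) {
  diag <- character(0)
  if (!inherits(config$cohort, "cohort_config"))
    diag <- c(diag, "cohort must be a cohort_config")
  else {
    diag <- c(diag, validate_cohort_config(config$cohort))
    if (is.null(config$cohort$train_group))
      diag <- c(diag, "the pipeline needs a healthy training group")
  }
  for (f in c("top_fraction_degree", "top_fraction_pairs")) {
    v <- config[[f]]
    if (!is.numeric(v) || v <= 0 || v >= 1)
      diag <- c(diag, paste0(f, " must be in (0, 1)"))
  }
  if (!is.numeric(config$alpha) || config$alpha <= 0 || config$alpha >= 1)
    diag <- c(diag, "alpha must be in (0, 1)")
  if (inherits(config$cohort, "cohort_config")) {
    ht <- config$healthy_test
    if (is.na(ht) || !ht %in% names(config$cohort$n_per_group))
      diag <- c(diag, "healthy_test group missing from the cohort")
    else if (ht %in% names(config$cohort$perturbations))
      diag <- c(diag, "healthy_test group must be unperturbed")
  }
  diag
}

# fit standardizer + train + reconstruct each test group; shared by the
# two healthy-split conditions
fit_and_score <- function(spec, features, manifest, train_group) {
  train_rows <- manifest$group == train_group
  std <- fit_standardizer(features[train_rows, , drop = FALSE])
  z <- apply_standardizer(std, features)
  model <- train_autoencoder(spec, z[train_rows, , drop = FALSE],
                             standardizer = std)
  rec <- reconstruct(model, z)
  list(model = model, standardizer = std, z = z, recon = rec,
       train_rows = train_rows)
}

#' Run the whole normative-modeling pipeline on a synthetic cohort
#'
#' Simulation -> connectivity features -> standardization (training set
#' only) -> autoencoder training -> deviation analysis: per-subject MSE_s
#' boxd data and Mann-Whitney group comparisons, merged-vector
#' thresholding with graph degrees, per-feature MSE_f matrices, healthy
#' subtraction, top-10% pair selection, and (with `condition_b = TRUE`)
#' group characterization across the two healthy-split conditions plus
#' individual-level matrices.
#'
#' @param config A [run_config()].
#' @param out_dir If non-NULL, artifacts (feature matrix, comparison
#'   table, MSE_f matrices, edge lists, characterization JSON, run record)
#'   are written there.
#' @return A list of class `run_report`; see the fields in the examples
#'   and the methods vignette.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  diag <- validate_config(config)
  if (length(diag)) stop("invalid run config: ",
                         paste(diag, collapse = "; "))
  atlas <- config$cohort$atlas
  t0 <- Sys.time()

  cohort <- generate_cohort(config$cohort)
  feats <- cohort_features(cohort)
  manifest <- feats$manifest
  groups <- names(config$cohort$n_per_group)
  test_groups <- setdiff(groups, config$cohort$train_group)
  patient_groups <- intersect(names(config$cohort$perturbations),
                              test_groups)

  cond_a <- fit_and_score(config$spec, feats$features, manifest,
                          config$cohort$train_group)

  test_rows <- !cond_a$train_rows
  test_groups_v <- manifest$group[test_rows]
  abs_diff_test <- cond_a$recon$abs_diff[test_rows, , drop = FALSE]
  colnames(abs_diff_test) <- pair_index(atlas)$pair

  mse_by_group <- split(cond_a$recon$mse_s[test_rows], test_groups_v)
  cmp_pairs <- c(lapply(patient_groups, function(g)
                   c(config$healthy_test, g)),
                 if (length(patient_groups) >= 2) {
                   cb <- utils::combn(patient_groups, 2)
                   lapply(seq_len(ncol(cb)), function(i) cb[, i])
                 })
  comparisons <- compare_groups(mse_by_group, cmp_pairs)

  threshold <- merged_threshold(abs_diff_test, config$top_fraction_degree)
  graphs <- lapply(seq_len(nrow(abs_diff_test)), function(i)
    binarize_and_degree(abs_diff_test[i, ], threshold, atlas))
  degree_summary <- lapply(split(seq_along(graphs), test_groups_v),
                           function(ix) group_degree_summary(graphs[ix]))

  gem <- lapply(test_groups, function(g)
    mse_per_feature(abs_diff_test[test_groups_v == g, , drop = FALSE],
                    g, atlas))
  names(gem) <- test_groups
  gem_sub <- lapply(patient_groups, function(g)
    subtract_healthy(gem[[g]], gem[[config$healthy_test]]))
  names(gem_sub) <- patient_groups

  top_before <- lapply(gem[patient_groups], top_fraction_pairs,
                       fraction = config$top_fraction_pairs)
  top_after <- lapply(gem_sub, top_fraction_pairs,
                      fraction = config$top_fraction_pairs)

  # conservation identity: mean over subjects of MSE_s == mean over
  # features of MSE_f, per group
  conservation_gap <- max(vapply(test_groups, function(g) {
    abs(mean(mse_by_group[[g]]) - mean(gem[[g]]$mse_f))
  }, 0))

  characterization <- NULL
  individual <- NULL
  cond_b <- NULL
  if (config$condition_b && length(patient_groups)) {
    b <- run_condition_b(config, cohort, feats)
    cond_b <- b
    characterization <- lapply(patient_groups, function(g)
      characterize_group(top_before[[g]], top_after[[g]],
                         b$top_before[[g]], b$top_after[[g]]))
    names(characterization) <- patient_groups
    individual <- lapply(patient_groups, function(g) {
      cp <- characterization[[g]]$characteristic
      if (!length(cp)) return(NULL)
      individual_level_matrix(cp, abs_diff_test, test_groups_v,
                              config$healthy_test)
    })
    names(individual) <- patient_groups
  }

  report <- structure(list(
    config = config,
    truth = cohort$truth,
    manifest = manifest,
    mse_s = cond_a$recon$mse_s,
    mse_by_group = mse_by_group,
    comparisons = comparisons,
    threshold = threshold,
    degree_summary = degree_summary,
    error_matrices = gem,
    error_matrices_subtracted = gem_sub,
    top_pairs_before = top_before,
    top_pairs_after = top_after,
    characterization = characterization,
    individual = individual,
    condition_b = cond_b,
    model = cond_a$model,
    abs_diff_test = abs_diff_test,
    test_groups = test_groups_v,
    conservation_gap = conservation_gap,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "run_report")
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

# condition (b): double the healthy test set by moving subjects from the
# training pool (deterministically, the last ones by counter order) and
# retrain from scratch
run_condition_b <- function(config, cohort, feats) {
  manifest_b <- feats$manifest
  tg <- config$cohort$train_group
  ht <- config$healthy_test
  n_move <- sum(manifest_b$group == ht)
  train_idx <- which(manifest_b$group == tg)
  if (length(train_idx) <= n_move)
    stop("training pool too small to double the healthy test set")
  moved <- utils::tail(train_idx, n_move)
  manifest_b$group[moved] <- ht

  cond <- fit_and_score(config$spec, feats$features, manifest_b, tg)
  test_rows <- !cond$train_rows
  tg_v <- manifest_b$group[test_rows]
  abs_diff <- cond$recon$abs_diff[test_rows, , drop = FALSE]
  colnames(abs_diff) <- pair_index(config$cohort$atlas)$pair
  patient_groups <- intersect(names(config$cohort$perturbations),
                              unique(tg_v))
  gem <- lapply(c(ht, patient_groups), function(g)
    mse_per_feature(abs_diff[tg_v == g, , drop = FALSE], g,
                    config$cohort$atlas))
  names(gem) <- c(ht, patient_groups)
  top_before <- lapply(gem[patient_groups], top_fraction_pairs,
                       fraction = config$top_fraction_pairs)
  top_after <- lapply(patient_groups, function(g)
    top_fraction_pairs(subtract_healthy(gem[[g]], gem[[ht]]),
                       fraction = config$top_fraction_pairs))
  names(top_after) <- patient_groups
  list(manifest = manifest_b, top_before = top_before,
       top_after = top_after, n_train = sum(cond$train_rows),
       n_healthy_test = sum(tg_v == ht))
}

#' Score an independently simulated cohort with an already-trained model
#'
#' The generalization check: the trained normative model (with its stored
#' standardizer and stored binarization threshold) is applied unchanged
#' to a second, independently simulated cohort.
#'
#' @param model A `trained_model` carrying its standardizer.
#' @param cohort A second [generate_cohort()] result.
#' @param threshold The stored merged threshold from the training run.
#' @param top_fraction Fraction of worst-reconstructed pairs selected
#'   (default 0.10).
#' @return List: `mse_by_group`, `abs_diff` (subjects x 91), `groups`,
#'   `error_matrices` (per group), `top_pairs` (per group, unsubtracted),
#'   `degree_summary`.
#' @export
score_independent_cohort <- function(model, cohort, threshold,
                                     top_fraction = 0.10) {
  feats <- cohort_features(cohort)
  atlas <- cohort$config$atlas
  z <- apply_standardizer(model$standardizer, feats$features)
  rec <- reconstruct(model, z)
  groups_v <- feats$manifest$group
  abs_diff <- rec$abs_diff
  colnames(abs_diff) <- pair_index(atlas)$pair
  gem <- lapply(unique(groups_v), function(g)
    mse_per_feature(abs_diff[groups_v == g, , drop = FALSE], g, atlas))
  names(gem) <- unique(groups_v)
  graphs <- lapply(seq_len(nrow(abs_diff)), function(i)
    binarize_and_degree(abs_diff[i, ], threshold, atlas))
  list(mse_by_group = split(rec$mse_s, groups_v),
       abs_diff = abs_diff, groups = groups_v,
       error_matrices = gem,
       top_pairs = lapply(gem, top_fraction_pairs,
                          fraction = top_fraction),
       degree_summary = lapply(split(seq_along(graphs), groups_v),
                               function(ix)
                                 group_degree_summary(graphs[ix])))
}

write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  atlas <- report$config$cohort$atlas
  write_features(report$abs_diff_test,
                 file.path(out_dir, "abs_diff_test.tsv"), atlas)
  utils::write.table(report$comparisons,
                     file.path(out_dir, "group_comparisons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (g in names(report$error_matrices))
    utils::write.table(report$error_matrices[[g]]$matrix,
                       file.path(out_dir, paste0("mse_f_", g, ".tsv")),
                       sep = "\t", quote = FALSE, col.names = NA)
  for (g in names(report$error_matrices_subtracted))
    utils::write.table(report$error_matrices_subtracted[[g]]$matrix,
                       file.path(out_dir,
                                 paste0("mse_f_", g, "_subtracted.tsv")),
                       sep = "\t", quote = FALSE, col.names = NA)
  for (g in names(report$top_pairs_after))
    write_edge_list(report$top_pairs_after[[g]],
                    file.path(out_dir, paste0("top_pairs_", g, ".tsv")),
                    atlas)
  summary_list <- list(
    seed = report$config$seed,
    threshold = as.numeric(report$threshold),
    retained_fraction = attr(report$threshold, "retained_fraction"),
    conservation_gap = report$conservation_gap,
    median_mse_s = lapply(report$mse_by_group, stats::median),
    characterization = lapply(report$characterization, function(ch)
      ch[c("rule1", "rule3", "characteristic", "rule2")]),
    elapsed_s = report$elapsed_s)
  jsonlite::write_json(summary_list, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed", x$config$seed, "\n")
  cat("  median MSE_s by group:\n")
  for (g in names(x$mse_by_group))
    cat(sprintf("    %-12s %.4f\n", g, stats::median(x$mse_by_group[[g]])))
  cat("  merged threshold:", signif(as.numeric(x$threshold), 4), "\n")
  cat("  conservation gap:", format(x$conservation_gap, digits = 3), "\n")
  invisible(x)
}
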