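#' Multi-seed recovery and generalization study
#'
#' Repeats the whole pipeline over several master seeds under the default
#' study conditions and collects, per seed: the median per-subject
#' reconstruction error of each test group, the Mann-Whitney p-value of
#' healthy-vs-patient comparisons, how many of the injected
#' (ground-truth) pairs fall in each patient group's healthy-subtracted
#' top-10% set, and — optionally — the overlap between the top-10% sets
#' of two independently simulated patient cohorts with identical injected
#' pairs, scored by the same trained model (the generalization check).
#'
#' @param seeds Integer vector of master seeds.
#' @param make_config Function(seed) returning a [run_config()]; defaults
#'   to the package's default study conditions with `condition_b = FALSE`
#'   (healthy subtraction needs only condition (a)).
#' @param generalization_group Patient group replicated in the
#'   independent cohort (default "SCZ-Test-U"); NULL skips the check.
#' @param progress Print one line per seed?
#' @return List: `per_seed` (data.frame, one row per seed x patient
#'   group: median MSE_s healthy/patient, p-value, n injected pairs
#'   recovered), `generalization` (data.frame per seed: shared pairs out
#'   of the 9 selected), `seeds`.
#' @export
seed_study <- function(seeds,
                       make_config = function(s)
                         run_config(seed = s, condition_b = FALSE),
                       generalization_group = "SCZ-Test-U",
                       progress = FALSE) {
  rows <- list(); gen_rows <- list()
  for (s in seeds) {
    cfg <- make_config(s)
    rep <- run_pipeline(cfg)
    ht <- cfg$healthy_test
    med_h <- stats::median(rep$mse_by_group[[ht]])
    for (g in names(rep$top_pairs_after)) {
      cmp <- rep$comparisons
      p <- cmp$p_value[cmp$group_i == ht & cmp$group_j == g]
      rows[[length(rows) + 1L]] <- data.frame(
        seed = s, group = g,
        median_healthy = med_h,
        median_patient = stats::median(rep$mse_by_group[[g]]),
        p_value = p,
        n_injected = nrow(rep$truth[[g]]),
        n_recovered = length(intersect(rep$top_pairs_after[[g]]$k,
                                       rep$truth[[g]]$k)),
        conservation_gap = rep$conservation_gap,
        stringsAsFactors = FALSE)
    }
    if (!is.null(generalization_group)) {
      gen <- independent_cohort_overlap(rep, cfg, generalization_group,
                                        seed = s + 500000L)
      gen_rows[[length(gen_rows) + 1L]] <- data.frame(
        seed = s, shared = gen$shared, n_top = gen$n_top,
        stringsAsFactors = FALSE)
    }
    if (progress)
      message("seed ", s, " done (",
              round(rep$elapsed_s, 1), "s)")
  }
  list(per_seed = do.call(rbind, rows),
       generalization = if (length(gen_rows)) do.call(rbind, gen_rows),
       seeds = seeds)
}

#' Overlap of worst-reconstructed pairs across independent cohorts
#'
#' Simulates a second, independent cohort carrying the same injected
#' pairs for one patient group, scores it with the already-trained model
#' (stored standardizer and threshold), and counts how many of the
#' top-10% worst-reconstructed pairs the two patient cohorts share.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param config The [run_config()] that produced it.
#' @param group Patient group to replicate.
#' @param seed Seed for the independent cohort.
#' @param n_per_group Subjects per group in the independent cohort.
#' @return List: `shared`, `n_top`, `top_independent` (data.frame),
#'   `scored` (full [score_independent_cohort()] result).
#' @export
independent_cohort_overlap <- function(report, config, group,
                                       seed, n_per_group = 30L) {
  pert <- config$cohort$perturbations[group]
  names(pert) <- "P-Indep"
  cfg2 <- cohort_config(
    n_per_group = stats::setNames(c(n_per_group, n_per_group),
                                  c("H-Indep", "P-Indep")),
    train_group = NULL,
    n_timepoints = config$cohort$n_timepoints,
    base_correlation = config$cohort$base_correlation,
    subject_sd = config$cohort$subject_sd,
    perturbations = pert,
    seed = seed,
    atlas = config$cohort$atlas)
  cohort2 <- generate_cohort(cfg2)
  scored <- score_independent_cohort(report$model, cohort2,
                                     report$threshold,
                                     top_fraction = config$top_fraction_pairs)
  top_u <- report$top_pairs_before[[group]]$k
  top_c <- scored$top_pairs[["P-Indep"]]$k
  list(shared = length(intersect(top_u, top_c)), n_top = length(top_u),
       top_independent = scored$top_pairs[["P-Indep"]],
       scored = scored)
}
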