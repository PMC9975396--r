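#' Structured subject-level variability of functional connectivity
#'
#' Healthy subjects do not scatter around the population template with
#' independent noise per network pair: individual differences in FC are
#' structured (shared trait-like components) and some pairs are far more
#' variable across healthy subjects than others. This model captures
#' both: each subject's deviation at pair k is
#' `loadings[k, ] %*% u + indep_sd[k] * eps_k`, with `u` a small vector of
#' subject-level latent factors and `eps_k` independent noise. Designated
#' "unstable" pairs get their independent noise inflated, making them
#' stably harder to model from the rest — the synthetic analogue of
#' connectivity that varies even among healthy individuals.
#'
#' @param atlas An `fbn_atlas`.
#' @param shared_sd SD of the factor-driven (predictable) component per
#'   pair (default 0.15).
#' @param indep_sd Baseline SD of the pair-specific noise (default 0.05).
#' @param n_factors Number of latent factors (default 2).
#' @param unstable_pairs List of label pairs with inflated pair-specific
#'   noise; defaults to pairs whose connectivity is reported unstable
#'   among healthy subjects (HVN-LN, LN-SN, PN-VDMN, ASN-LN).
#' @param unstable_multiplier Noise multiplier for unstable pairs
#'   (default 5).
#' @param seed Seed fixing the factor loadings; this is population
#'   structure, so it stays fixed across cohorts drawn from the same
#'   template.
#' @return List of class `fc_variability`: `loadings` (n_pairs x
#'   n_factors), `indep_sd` (length n_pairs), `atlas`.
#' @export
fc_variability <- function(atlas = fbn_atlas(), shared_sd = 0.15,
                           indep_sd = 0.05, n_factors = 2L,
                           unstable_pairs = list(c("HVN", "LN"),
                                                 c("LN", "SN"),
                                                 c("PN", "VDMN"),
                                                 c("ASN", "LN")),
                           unstable_multiplier = 5,
                           seed = 2024L) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  np <- atlas$n_pairs
  lam <- matrix(stats::rnorm(np * n_factors), np, n_factors)
  lam <- lam / sqrt(rowSums(lam^2)) * shared_sd  # each pair: shared var = shared_sd^2
  sds <- rep(indep_sd, np)
  for (p in unstable_pairs)
    sds[pair_to_k(p[1], p[2], atlas)] <- indep_sd * unstable_multiplier
  structure(list(loadings = lam, indep_sd = sds, atlas = atlas),
            class = "fc_variability")
}

# one subject's 14x14 symmetric deviation matrix (zero diagonal); uses
# the current RNG stream
draw_subject_deviation <- function(variability) {
  u <- stats::rnorm(ncol(variability$loadings))
  d <- as.numeric(variability$loadings %*% u) +
    stats::rnorm(length(variability$indep_sd)) * variability$indep_sd
  devectorize(d, variability$atlas, symmetric = TRUE)
}

#' Draw one subject's network time series from a correlation template
#'
#' The generative law is multivariate Gaussian: the subject's own
#' correlation matrix is the template plus seeded subject-level jitter on
#' the off-diagonal entries (re-projected to a valid correlation matrix),
#' and T time points are drawn i.i.d. from N(0, Sigma_subject). Columns
#' are standardized to zero mean / unit variance; Pearson correlation is
#' scale-invariant so this is cosmetic but numerically tidy.
#'
#' @param template Valid correlation matrix (the population template).
#' @param subject_sd Either a scalar — SD of independent Gaussian jitter
#'   per off-diagonal entry, 0 giving every subject exactly the
#'   template — or an [fc_variability()] model for structured
#'   variability.
#' @param n_timepoints Number of time points T (>= 30).
#' @param seed Integer seed: fixes both the jitter and the series.
#' @return A T x n numeric matrix, columns named by the template dimnames.
#' @export
sample_subject_timeseries <- function(template, subject_sd = 0.1,
                                      n_timepoints = 150, seed = 1L) {
  if (n_timepoints < 30) stop("n_timepoints must be >= 30")
  n <- nrow(template)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  sigma <- template
  structured <- inherits(subject_sd, "fc_variability")
  if (structured || subject_sd > 0) {
    z <- if (structured) {
      draw_subject_deviation(subject_sd)
    } else {
      z0 <- matrix(stats::rnorm(n * n, sd = subject_sd), n, n)
      z0[upper.tri(z0)] <- t(z0)[upper.tri(z0)]
      diag(z0) <- 0
      z0
    }
    sigma <- pmin(pmax(template + z, -0.99), 0.99)
    diag(sigma) <- 1
    sigma <- as_valid_correlation(sigma)
  }
  ts <- MASS::mvrnorm(n_timepoints, mu = rep(0, n), Sigma = sigma)
  ts <- scale(ts)
  attr(ts, "scaled:center") <- NULL
  attr(ts, "scaled:scale") <- NULL
  colnames(ts) <- colnames(template)
  ts
}

#' Default healthy-population block structure
#'
#' Groups the 14 networks into functional families (salience, default
#' mode, visual, executive, auditory/language, basal ganglia,
#' sensorimotor) so within-family connectivity is higher than
#' between-family, the qualitative structure expected of resting-state
#' network correlation matrices.
#' @param atlas An `fbn_atlas`.
#' @return A list of label vectors partitioning the atlas.
#' @export
default_blocks <- function(atlas = fbn_atlas()) {
  list(c("ASN", "PSN"),
       c("AN", "LN"),
       c("BGN"),
       c("DDMN", "VDMN", "PN"),
       c("HVN", "PVN", "VN"),
       c("LECN", "RECN"),
       c("SN"))
}

#' Configuration of a synthetic cohort
#'
#' Bundles everything [generate_cohort()] needs. The defaults are the
#' study conditions exercised throughout the package: 200 healthy training
#' subjects, 30 subjects per test group, T = 150 time points, the default
#' structured subject variability ([fc_variability()]), and three injected
#' pairs per patient group at delta = +0.4 (pairs chosen among those
#' reported abnormal for each disorder).
#'
#' @param n_per_group Named integer vector of subject counts.
#' @param train_group Name of the healthy training set. NULL is allowed
#'   for score-only cohorts (e.g. an independent test cohort evaluated
#'   with an already-trained model); such a cohort still needs at least
#'   one unperturbed (healthy) group.
#' @param n_timepoints Time points per subject (>= 30).
#' @param base_correlation Population correlation template; defaults to
#'   [make_base_correlation()] over [default_blocks()].
#' @param subject_sd Subject-level variability: a scalar jitter SD or an
#'   [fc_variability()] model; NULL (default) builds the default
#'   structured model for the atlas.
#' @param perturbations Named list: patient group -> list of
#'   `list(pair = c(label, label), delta = )` offsets.
#' @param seed Master seed; per-subject seeds are derived by a counter
#'   scheme (subject i gets `(seed + 1000003 * i) mod (2^31 - 2) + 1`) so
#'   extending the cohort never reshuffles existing subjects.
#' @param atlas An `fbn_atlas`.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c("H-Train" = 200, "H-Test-U" = 30,
                                          "SCZ-Test-U" = 30, "BD-Test-U" = 30,
                                          "ADHD-Test-U" = 30),
                          train_group = "H-Train",
                          n_timepoints = 150,
                          base_correlation = NULL,
                          subject_sd = NULL,
                          perturbations = default_perturbations(),
                          seed = 1L,
                          atlas = fbn_atlas()) {
  if (is.null(base_correlation))
    base_correlation <- make_base_correlation(atlas, default_blocks(atlas),
                                              seed = 2024L)
  if (is.null(subject_sd)) subject_sd <- fc_variability(atlas)
  cfg <- structure(list(n_per_group = n_per_group,
                        train_group = train_group,
                        n_timepoints = n_timepoints,
                        base_correlation = base_correlation,
                        subject_sd = subject_sd,
                        perturbations = perturbations,
                        seed = as.integer(seed),
                        atlas = atlas),
                   class = "cohort_config")
  diag <- validate_cohort_config(cfg)
  if (length(diag)) stop("invalid cohort config: ",
                         paste(diag, collapse = "; "))
  cfg
}

#' Default injected perturbations for the three synthetic patient groups
#'
#' Three network pairs per group, offset by +0.4, chosen among the pairs
#' reported abnormal for schizophrenia, bipolar disorder and ADHD.
#' @param delta Edge offset applied to every injected pair.
#' @return Named list of perturbation lists keyed by group name.
#' @export
default_perturbations <- function(delta = 0.4) {
  mk <- function(...) lapply(list(...), function(p)
    list(pair = p, delta = delta))
  list("SCZ-Test-U" = mk(c("ASN", "BGN"), c("BGN", "HVN"), c("HVN", "RECN")),
       "BD-Test-U"  = mk(c("BGN", "DDMN"), c("BGN", "LN"), c("HVN", "PVN")),
       "ADHD-Test-U" = mk(c("ASN", "LN"), c("ASN", "PN"), c("LN", "RECN")))
}

validate_cohort_config <- function(cfg) {
  diag <- character(0)
  if (is.null(names(cfg$n_per_group)) || any(names(cfg$n_per_group) == ""))
    diag <- c(diag, "n_per_group must be a named vector")
  if (any(cfg$n_per_group < 1))
    diag <- c(diag, "all group sizes must be >= 1")
  unknown <- setdiff(names(cfg$perturbations), names(cfg$n_per_group))
  if (length(unknown))
    diag <- c(diag, paste0("perturbations reference unknown group(s): ",
                           paste(unknown, collapse = ", ")))
  if (!is.null(cfg$train_group)) {
    if (!cfg$train_group %in% names(cfg$n_per_group))
      diag <- c(diag, paste0("train group '", cfg$train_group,
                             "' missing from n_per_group"))
    if (cfg$train_group %in% names(cfg$perturbations))
      diag <- c(diag, "the training group must be healthy (unperturbed)")
    healthy_test <- setdiff(names(cfg$n_per_group),
                            c(cfg$train_group, names(cfg$perturbations)))
    if (!length(healthy_test))
      diag <- c(diag, "need at least one healthy (unperturbed) test group")
  } else {
    if (!length(setdiff(names(cfg$n_per_group), names(cfg$perturbations))))
      diag <- c(diag, "need at least one healthy (unperturbed) group")
  }
  if (cfg$n_timepoints < 30)
    diag <- c(diag, "n_timepoints must be >= 30")
  diag
}

subject_seed <- function(master, counter) {
  as.integer((as.numeric(master) + 1000003 * counter) %% (2^31 - 2)) + 1L
}

#' Generate a full synthetic cohort with ground truth
#'
#' For each named group, draws `n_per_group[g]` subjects' time series from
#' the group's correlation template (the base template, perturbed for
#' patient groups). Deterministic given the config: each subject's seed is
#' derived from the master seed and the subject's global counter.
#'
#' @param config A [cohort_config()].
#' @param out_dir If non-NULL, one delimited file per subject
#'   (tab-separated, header = atlas labels), a `manifest.tsv` and a
#'   `truth.json` are written there.
#' @return A list of class `cohort`: `manifest` (data.frame subject_id,
#'   group, file), `timeseries` (named list of T x 14 matrices), `truth`
#'   (per perturbed group, a data.frame of injected pairs with feature
#'   index `k` and `delta`), and `config`.
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  atlas <- config$atlas
  templates <- list()
  for (g in names(config$n_per_group)) {
    pert <- config$perturbations[[g]]
    templates[[g]] <- if (is.null(pert)) config$base_correlation
      else perturb_correlation(config$base_correlation, pert, atlas)
  }
  manifest <- data.frame(subject_id = character(0), group = character(0),
                         file = character(0), stringsAsFactors = FALSE)
  timeseries <- list()
  counter <- 0L
  for (g in names(config$n_per_group)) {
    for (i in seq_len(config$n_per_group[[g]])) {
      counter <- counter + 1L
      sid <- sprintf("%s_%03d", gsub("[^A-Za-z0-9]", "", g), i)
      ts <- sample_subject_timeseries(templates[[g]], config$subject_sd,
                                      config$n_timepoints,
                                      seed = subject_seed(config$seed,
                                                          counter))
      timeseries[[sid]] <- ts
      manifest <- rbind(manifest,
                        data.frame(subject_id = sid, group = g, file = NA,
                                   stringsAsFactors = FALSE))
    }
  }
  truth <- lapply(config$perturbations, function(pl) {
    data.frame(label_i = vapply(pl, function(p) p$pair[1], ""),
               label_j = vapply(pl, function(p) p$pair[2], ""),
               k = vapply(pl, function(p)
                 pair_to_k(p$pair[1], p$pair[2], atlas), 0),
               delta = vapply(pl, function(p) p$delta, 0.0),
               stringsAsFactors = FALSE)
  })
  cohort <- structure(list(manifest = manifest, timeseries = timeseries,
                           truth = truth, config = config),
                      class = "cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(cohort$manifest))) {
    sid <- cohort$manifest$subject_id[i]
    f <- file.path(out_dir, paste0(sid, ".tsv"))
    utils::write.table(round(cohort$timeseries[[sid]], 6), f, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cohort$manifest$file[i] <- f
  }
  utils::write.table(cohort$manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth_json <- lapply(cohort$truth, function(df)
    lapply(seq_len(nrow(df)), function(r)
      list(pair = c(df$label_i[r], df$label_j[r]), delta = df$delta[r])))
  jsonlite::write_json(truth_json, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(cohort)
}

#' Simulate a per-volume head-motion table
#'
#' Produces the six rigid-body motion parameters (3 translations in mm, 3
#' rotations in degrees) plus Power-style framewise displacement. With
#' `contaminate = TRUE` a motion spike is injected so at least one
#' rejection criterion (FD > 3 mm, |translation| > 3 mm, |rotation| > 3
#' degrees) is violated; with `FALSE` none is.
#'
#' @param n_volumes Number of volumes (>= 2).
#' @param contaminate Inject a motion spike?
#' @param seed Integer seed.
#' @return A data.frame of class `motion_params` with columns trans_x/y/z,
#'   rot_x/y/z, fd.
#' @export
generate_motion_table <- function(n_volumes = 150, contaminate = FALSE,
                                  seed = 1L) {
  if (n_volumes < 2) stop("n_volumes must be >= 2")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  trans <- matrix(stats::rnorm(3 * n_volumes, sd = 0.08), n_volumes, 3)
  rot <- matrix(stats::rnorm(3 * n_volumes, sd = 0.04), n_volumes, 3)
  # keep the clean table safely inside every criterion
  trans <- pmin(pmax(trans, -1), 1)
  rot <- pmin(pmax(rot, -1), 1)
  if (contaminate) {
    v <- sample.int(n_volumes - 1L, 1L) + 1L
    trans[v, 1] <- 4.5   # violates translation and (via the jump) FD
  }
  m <- data.frame(trans_x = trans[, 1], trans_y = trans[, 2],
                  trans_z = trans[, 3], rot_x = rot[, 1], rot_y = rot[, 2],
                  rot_z = rot[, 3])
  m$fd <- framewise_displacement(m)
  class(m) <- c("motion_params", "data.frame")
  m
}
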