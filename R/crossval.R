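#' Stratified fold assignment
#'
#' Assigns each subject to exactly one validation fold, keeping the
#' proportion of dataset labels similar across folds (shuffled round-robin
#' within each label). Labels with fewer members than folds trigger a
#' warning and fall back to best-effort proportional assignment.
#'
#' @param labels Character vector of per-subject dataset labels.
#' @param fold_count Number of folds.
#' @param seed Integer seed for the within-label shuffles.
#' @return Integer vector of fold ids in 1..fold_count.
#' @export
stratified_folds <- function(labels, fold_count = 10L, seed = 1L) {
  n <- length(labels)
  if (n < fold_count) stop("need at least as many subjects as folds")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  folds <- integer(n)
  offset <- 0L
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    if (length(idx) < fold_count)
      warning("dataset '", lab, "' has fewer subjects (", length(idx),
              ") than folds (", fold_count,
              "); using best-effort proportional assignment")
    idx <- idx[sample.int(length(idx))]
    # offset staggers the round-robin start across labels so small labels
    # don't all land in fold 1
    folds[idx] <- ((seq_along(idx) - 1L + offset) %% fold_count) + 1L
    offset <- offset + length(idx)
  }
  folds
}

#' K-fold cross-validation of the normative autoencoder
#'
#' Trains `fold_count` models, each holding out one stratified fold, and
#' reports the per-fold median per-subject reconstruction error (MSE_s)
#' on the training and validation portions; the mean of the train medians
#' measures performance, and the gap between mean validation and mean
#' train medians measures (over)generalization. Standardization is
#' refitted inside every fold on that fold's training portion only.
#'
#' @param spec An [autoencoder_spec()]; fold f trains with seed
#'   `spec$seed + f`.
#' @param train_features Raw (unstandardized) subjects x p matrix of the
#'   healthy training pool.
#' @param dataset_labels Per-subject dataset labels for stratification;
#'   a single label if omitted.
#' @param fold_count Number of folds (default 10).
#' @param standardize Refit the standardizer inside each fold (default
#'   TRUE). Set FALSE when `train_features` are already standardized (or
#'   deliberately degenerate, e.g. constant).
#' @return List of class `cv_report`: `fold` (data.frame with per-fold
#'   median train/validation MSE_s), `mean_train_median`,
#'   `mean_val_median`, `gap` (validation minus train).
#' @export
cross_validate <- function(spec, train_features, dataset_labels = NULL,
                           fold_count = 10L, standardize = TRUE) {
  X <- as.matrix(train_features)
  n <- nrow(X)
  if (is.null(dataset_labels)) dataset_labels <- rep("all", n)
  if (length(dataset_labels) != n)
    stop("dataset_labels must align with subjects")
  folds <- stratified_folds(dataset_labels, fold_count, seed = spec$seed)
  med_train <- numeric(fold_count); med_val <- numeric(fold_count)
  for (f in seq_len(fold_count)) {
    tr <- folds != f
    if (standardize) {
      std <- fit_standardizer(X[tr, , drop = FALSE])
      ztr <- apply_standardizer(std, X[tr, , drop = FALSE])
      zval <- apply_standardizer(std, X[!tr, , drop = FALSE])
    } else {
      std <- NULL
      ztr <- X[tr, , drop = FALSE]
      zval <- X[!tr, , drop = FALSE]
    }
    fold_spec <- spec; fold_spec$seed <- spec$seed + f
    model <- train_autoencoder(fold_spec, ztr, standardizer = std)
    med_train[f] <- stats::median(reconstruct(model, ztr)$mse_s)
    med_val[f] <- stats::median(reconstruct(model, zval)$mse_s)
  }
  structure(list(fold = data.frame(fold = seq_len(fold_count),
                                   median_train = med_train,
                                   median_val = med_val),
                 mean_train_median = mean(med_train),
                 mean_val_median = mean(med_val),
                 gap = mean(med_val) - mean(med_train)),
            class = "cv_report")
}

#' Min-max normalization of the two model-selection metrics
#'
#' Candidate architectures are compared on two metrics of different
#' scales (mean of train-fold median MSE_s = performance; train-validation
#' gap = generalization). Each metric is mapped to [0, 1] by
#' (x - min) / (max - min) across candidates, and the candidate that
#' best balances both — the argmin of the sum of the two normalized
#' metrics — is selected. The balance rule is pluggable.
#'
#' @param candidates data.frame (or matrix) with columns `performance`
#'   and `gap`, one row per candidate model.
#' @param balance Function mapping the normalized two-column matrix to a
#'   per-candidate score to minimize; default `rowSums`.
#' @return List: `normalized` (data.frame with normalized columns),
#'   `selected` (row index of the chosen candidate).
#' @export
normalize_selection_metrics <- function(candidates, balance = rowSums) {
  x <- as.data.frame(candidates)
  if (!all(c("performance", "gap") %in% names(x)))
    stop("candidates need 'performance' and 'gap' columns")
  if (nrow(x) < 2) stop("need at least 2 candidates")
  norm1 <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) {
      warning("metric constant across candidates; normalized to 0")
      return(rep(0, length(v)))
    }
    (v - r[1]) / (r[2] - r[1])
  }
  nx <- data.frame(performance = norm1(x$performance), gap = norm1(x$gap))
  list(normalized = nx,
       selected = which.min(balance(as.matrix(nx))))
}
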