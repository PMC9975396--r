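#' Power-style framewise displacement from six motion parameters
#'
#' FD at volume t is the sum of absolute backward differences of the six
#' rigid-body parameters, with rotations (degrees) converted to arc length
#' on a 50 mm sphere. The first volume gets FD = 0.
#'
#' @param motion data.frame with columns trans_x/y/z (mm), rot_x/y/z
#'   (degrees).
#' @return Non-negative numeric vector, one value per volume.
#' @export
framewise_displacement <- function(motion) {
  trans <- as.matrix(motion[, c("trans_x", "trans_y", "trans_z")])
  rot_mm <- as.matrix(motion[, c("rot_x", "rot_y", "rot_z")]) * pi / 180 * 50
  rowSums(rbind(0, abs(diff(trans)))) +
    rowSums(rbind(0, abs(diff(rot_mm))))
}

#' Motion quality-control thresholds
#'
#' Defaults follow the common head-motion rejection rule for 3 mm voxels:
#' a subject is excluded when maximum framewise displacement exceeds 3 mm,
#' any translation exceeds 3 mm, or any rotation exceeds 3 degrees.
#' @param max_fd_mm,max_translation_mm,max_rotation_deg Strictly positive
#'   rejection bounds.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_fd_mm = 3, max_translation_mm = 3,
                          max_rotation_deg = 3) {
  stopifnot(max_fd_mm > 0, max_translation_mm > 0, max_rotation_deg > 0)
  structure(list(max_fd_mm = max_fd_mm,
                 max_translation_mm = max_translation_mm,
                 max_rotation_deg = max_rotation_deg),
            class = "qc_thresholds")
}

#' Head-motion subject rejection
#'
#' "Exceeded" is read strictly: a maximum FD of exactly 3 mm passes. If
#' the table has no `fd` column it is computed with
#' [framewise_displacement()].
#'
#' @param motion data.frame with trans_x/y/z, rot_x/y/z and optionally fd.
#' @param thresholds A [qc_thresholds()].
#' @return List with `pass` (logical) and `violated` (character vector
#'   among "fd", "translation", "rotation").
#' @export
motion_qc <- function(motion, thresholds = qc_thresholds()) {
  need <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  if (!all(need %in% names(motion)))
    stop("malformed motion table: need columns ",
         paste(need, collapse = ", "))
  if (nrow(motion) < 1) stop("malformed motion table: empty")
  lens <- vapply(motion[need], length, 0L)
  if (length(unique(lens)) != 1)
    stop("malformed motion table: unequal series lengths")
  fd <- if ("fd" %in% names(motion)) motion$fd
        else framewise_displacement(motion)
  if (any(fd < 0)) stop("malformed motion table: negative fd")
  violated <- character(0)
  if (max(fd) > thresholds$max_fd_mm) violated <- c(violated, "fd")
  if (max(abs(as.matrix(motion[, c("trans_x", "trans_y", "trans_z")]))) >
      thresholds$max_translation_mm)
    violated <- c(violated, "translation")
  if (max(abs(as.matrix(motion[, c("rot_x", "rot_y", "rot_z")]))) >
      thresholds$max_rotation_deg)
    violated <- c(violated, "rotation")
  list(pass = length(violated) == 0, violated = violated)
}

#' Pearson functional-connectivity matrix of one subject
#'
#' Correlates every pair of network time series; the result is symmetric
#' with unit diagonal by construction, and both are enforced exactly.
#'
#' @param ts T x n numeric matrix (T >= 3), columns ordered as the atlas.
#' @param atlas An `fbn_atlas`.
#' @return An object of class `connectivity_matrix`: list with `values`
#'   (n x n matrix, atlas dimnames) and `atlas`.
#' @export
correlation_matrix <- function(ts, atlas = fbn_atlas()) {
  ts <- as.matrix(ts)
  n <- atlas$n_networks
  if (ncol(ts) != n)
    stop("expected ", n, " columns, got ", ncol(ts))
  if (nrow(ts) < 3) stop("need at least 3 time points")
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- atlas$labels[which(sds == 0)]
    stop("degenerate signal: zero-variance column(s) ",
         paste(bad, collapse = ", "))
  }
  m <- stats::cor(ts)
  m <- (m + t(m)) / 2
  m[m > 1] <- 1; m[m < -1] <- -1
  diag(m) <- 1
  dimnames(m) <- list(atlas$labels, atlas$labels)
  structure(list(values = m, atlas = atlas), class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("<connectivity_matrix> ", nrow(x$values), "x", ncol(x$values), "\n",
      sep = "")
  print(round(x$values[1:min(5, nrow(x$values)), 1:min(5, ncol(x$values))],
              3))
  invisible(x)
}

#' Feature matrix of a whole cohort
#'
#' Runs [correlation_matrix()] + [vectorize()] on every subject of a
#' [generate_cohort()] result.
#'
#' @param cohort A `cohort`.
#' @return List: `features` (subjects x 91 matrix, rownames = subject ids,
#'   colnames = pair labels), `manifest` (the cohort manifest), `atlas`.
#' @export
cohort_features <- function(cohort) {
  atlas <- cohort$config$atlas
  feats <- t(vapply(cohort$timeseries, function(ts)
    vectorize(correlation_matrix(ts, atlas), atlas),
    numeric(atlas$n_pairs)))
  rownames(feats) <- names(cohort$timeseries)
  list(features = feats, manifest = cohort$manifest, atlas = atlas)
}

#' Write a cohort feature matrix with its pair-index sidecar
#'
#' @param features subjects x 91 matrix (as from [cohort_features()]).
#' @param path Output path for the tab-delimited matrix; a
#'   `<path>.pairs.json` sidecar records the pair-index map.
#' @param atlas An `fbn_atlas`.
#' @export
write_features <- function(features, path, atlas = fbn_atlas()) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  jsonlite::write_json(pair_index(atlas),
                       paste0(path, ".pairs.json"), digits = NA)
  invisible(path)
}
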