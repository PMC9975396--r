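#' Functional brain network atlas
#'
#' The analysis is indexed by a fixed, ordered set of functional brain
#' network (FBN) labels. The default is the 14 canonical resting-state
#' networks (anterior salience, auditory, basal ganglia, dorsal default
#' mode, higher visual, language, left executive control, posterior
#' salience, precuneus, primary visual, right executive control,
#' sensorimotor, ventral default mode, visuospatial). The ordering is fixed
#' for the lifetime of an analysis: every connectivity matrix, feature
#' vector and pair index refers to it.
#'
#' @param labels Character vector of unique network codes. Defaults to the
#'   14-network set.
#' @return An object of class `fbn_atlas`: a list with `labels` and
#'   `n_pairs` (`choose(n, 2)`, 91 for 14 networks).
#' @examples
#' atlas <- fbn_atlas()
#' atlas$n_pairs  # 91
#' @export
fbn_atlas <- function(labels = c("ASN", "AN", "BGN", "DDMN", "HVN", "LN",
                                 "LECN", "PSN", "PN", "PVN", "RECN", "SN",
                                 "VDMN", "VN")) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("atlas labels must be unique")
  if (length(labels) < 2) stop("atlas needs at least 2 networks")
  structure(list(labels = labels,
                 n_networks = length(labels),
                 n_pairs = choose(length(labels), 2L)),
            class = "fbn_atlas")
}

#' @export
print.fbn_atlas <- function(x, ...) {
  cat("<fbn_atlas> ", x$n_networks, " networks, ", x$n_pairs, " pairs\n",
      sep = "")
  cat(paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Pair-index map for the strict lower triangle
#'
#' Feature k of a vectorized connectivity matrix corresponds to one
#' unordered network pair. The order is row-major over the strict lower
#' triangle: (2,1), (3,1), (3,2), (4,1), ... so that
#' `vectorize()`/`devectorize()` are exact inverses.
#'
#' @param atlas An `fbn_atlas`.
#' @return A data.frame with columns `k` (1-based feature index), `row`,
#'   `col` (matrix indices, row > col), `label_i`, `label_j` (labels at
#'   `row` and `col`), and `pair` ("label_i-label_j").
#' @export
pair_index <- function(atlas = fbn_atlas()) {
  stopifnot(inherits(atlas, "fbn_atlas"))
  n <- atlas$n_networks
  rows <- integer(0); cols <- integer(0)
  for (i in seq_len(n)[-1]) {
    rows <- c(rows, rep.int(i, i - 1L))
    cols <- c(cols, seq_len(i - 1L))
  }
  data.frame(k = seq_along(rows),
             row = rows, col = cols,
             label_i = atlas$labels[rows],
             label_j = atlas$labels[cols],
             pair = paste0(atlas$labels[rows], "-", atlas$labels[cols]),
             stringsAsFactors = FALSE)
}

#' Look up the feature index of a labelled network pair
#'
#' @param label_i,label_j Network labels (order-free).
#' @param atlas An `fbn_atlas`.
#' @return The 1-based feature index k.
#' @export
pair_to_k <- function(label_i, label_j, atlas = fbn_atlas()) {
  i <- match(label_i, atlas$labels)
  j <- match(label_j, atlas$labels)
  if (anyNA(c(i, j))) stop("unknown network label: ",
                           paste(c(label_i, label_j)[is.na(c(i, j))],
                                 collapse = ", "))
  if (any(i == j)) stop("self-pairs have no feature index")
  r <- pmax(i, j); c <- pmin(i, j)
  # row-major strict lower triangle: offset of row r is choose(r-1, 2)
  ((r - 1L) * (r - 2L)) %/% 2L + c
}

#' Vectorize a connectivity matrix to its 91 lower-triangle features
#'
#' Extracts the strict lower triangle in row-major order (the order
#' documented by [pair_index()]). For the 14-network atlas the result has
#' exactly 91 entries.
#'
#' @param conn A `connectivity_matrix` (see [correlation_matrix()]) or a
#'   plain symmetric numeric matrix matching the atlas.
#' @param atlas An `fbn_atlas`.
#' @return Numeric vector of length `atlas$n_pairs`, named by pair label.
#' @export
vectorize <- function(conn, atlas = fbn_atlas()) {
  m <- if (inherits(conn, "connectivity_matrix")) conn$values else conn
  n <- atlas$n_networks
  if (!is.matrix(m) || nrow(m) != n || ncol(m) != n)
    stop("expected a ", n, "x", n, " matrix, got ",
         paste(dim(m), collapse = "x"))
  pi <- pair_index(atlas)
  v <- m[cbind(pi$row, pi$col)]
  names(v) <- pi$pair
  v
}

#' Reshape a 91-feature vector into the lower-triangular matrix layout
#'
#' Inverse of [vectorize()]: entries are placed in the strict lower
#' triangle (row-major); the diagonal and upper triangle are zero.
#'
#' @param vec Numeric vector of length `atlas$n_pairs`.
#' @param atlas An `fbn_atlas`.
#' @param symmetric If TRUE, mirror into the upper triangle as well.
#' @return A square matrix with dimnames from the atlas labels.
#' @export
devectorize <- function(vec, atlas = fbn_atlas(), symmetric = FALSE) {
  n <- atlas$n_networks
  if (length(vec) != atlas$n_pairs)
    stop("expected a vector of length ", atlas$n_pairs,
         ", got ", length(vec))
  pi <- pair_index(atlas)
  m <- matrix(0, n, n, dimnames = list(atlas$labels, atlas$labels))
  m[cbind(pi$row, pi$col)] <- vec
  if (symmetric) m[cbind(pi$col, pi$row)] <- vec
  m
}
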