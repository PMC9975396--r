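#' @importFrom Matrix nearPD
NULL

# Project a symmetric matrix onto the nearest valid correlation matrix
# (Higham alternating projections via Matrix::nearPD, then rescale so the
# diagonal is exactly 1). Guarantees min eigenvalue > eig_floor.
as_valid_correlation <- function(m, eig_floor = 1e-8) {
  m <- (m + t(m)) / 2
  diag(m) <- 1
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= eig_floor) {
    m <- as.matrix(Matrix::nearPD(m, corr = TRUE, eig.tol = 1e-7,
                                  posd.tol = 1e-6, maxit = 200)$mat)
    # nearPD(corr = TRUE) keeps the unit diagonal; enforce exactly
    d <- sqrt(diag(m))
    m <- m / tcrossprod(d)
  }
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

#' Build a block-structured population correlation template
#'
#' Constructs the healthy-population correlation matrix the synthetic
#' cohorts are drawn around. Networks inside a block share a common
#' within-block correlation; pairs across blocks get the between-block
#' value, plus small seeded noise so the template is not exactly
#' degenerate. The raw matrix is projected to the nearest valid
#' correlation matrix (symmetric, unit diagonal, positive definite).
#'
#' @param atlas An `fbn_atlas`.
#' @param blocks List of integer or character vectors partitioning the
#'   atlas labels, or NULL for a single block of all networks.
#' @param within Correlation assigned inside a block (default 0.5).
#' @param between Correlation assigned across blocks (default 0.1).
#' @param noise_sd SD of seeded Gaussian roughening added to off-diagonal
#'   entries (default 0.05; 0 for exact block values).
#' @param seed Integer seed for the roughening.
#' @return A valid correlation matrix with atlas dimnames.
#' @export
make_base_correlation <- function(atlas = fbn_atlas(), blocks = NULL,
                                  within = 0.5, between = 0.1,
                                  noise_sd = 0.05, seed = 1L) {
  n <- atlas$n_networks
  if (is.null(blocks)) blocks <- list(seq_len(n))
  blocks <- lapply(blocks, function(b) {
    if (is.character(b)) b <- match(b, atlas$labels)
    if (anyNA(b)) stop("unknown label in block_structure")
    as.integer(b)
  })
  idx <- sort(unlist(blocks))
  if (!identical(idx, seq_len(n)))
    stop("blocks must partition the ", n, " atlas labels")

  block_of <- integer(n)
  for (b in seq_along(blocks)) block_of[blocks[[b]]] <- b
  m <- matrix(between, n, n)
  for (b in blocks) m[b, b] <- within
  diag(m) <- 1
  if (noise_sd > 0) {
    old <- local_seed(seed)
    on.exit(restore_seed(old))
    z <- matrix(stats::rnorm(n * n, sd = noise_sd), n, n)
    z <- (z + t(z)) / 2
    diag(z) <- 0
    m <- m + z
  }
  m[m > 0.99] <- 0.99
  m[m < -0.99] <- -0.99
  diag(m) <- 1
  m <- as_valid_correlation(m)
  dimnames(m) <- list(atlas$labels, atlas$labels)
  m
}

#' Inject edge perturbations into a correlation template
#'
#' Adds group-level offsets (deltas) to chosen network-pair entries,
#' symmetrically, then re-projects to a valid correlation matrix if the
#' shift broke positive definiteness. This is how the synthetic patient
#' groups' abnormal connectivity is defined.
#'
#' @param base A valid correlation matrix (atlas dimnames).
#' @param perturbations A list of `list(pair = c("BGN", "LN"), delta = 0.4)`
#'   entries (labels or indices).
#' @param atlas An `fbn_atlas`.
#' @return A valid correlation matrix; unperturbed entries move only by the
#'   projection tolerance.
#' @export
perturb_correlation <- function(base, perturbations, atlas = fbn_atlas()) {
  m <- base
  if (length(perturbations) == 0) return(m)
  for (p in perturbations) {
    pr <- p$pair
    if (is.character(pr)) {
      i <- match(pr[1], atlas$labels); j <- match(pr[2], atlas$labels)
      if (anyNA(c(i, j))) stop("unknown label in perturbation pair: ",
                               paste(pr, collapse = "-"))
    } else { i <- pr[1]; j <- pr[2] }
    if (i == j) stop("cannot perturb a diagonal entry")
    v <- m[i, j] + p$delta
    if (v <= -1 || v >= 1)
      stop("invalid perturbation: entry ", atlas$labels[i], "-",
           atlas$labels[j], " would become ", signif(v, 4),
           ", outside (-1, 1)")
    m[i, j] <- v; m[j, i] <- v
  }
  as_valid_correlation(m)
}

# Seed helpers: set the RNG reproducibly, restore the caller's state after.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed %% .Machine$integer.max))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
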