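# Independent oracles and small fixtures shared across test files.

# Brute-force pair-index map: enumerate the strict lower triangle the slow,
# obvious way (independent of pair_index()'s arithmetic).
brute_force_pair_map <- function(n) {
  out <- NULL
  for (i in 2:n) for (j in 1:(i - 1))
    out <- rbind(out, c(row = i, col = j))
  out
}

# Independent Mann-Whitney oracle: U by direct pair counting, p by
# exhaustive enumeration of group assignments.
oracle_mann_whitney <- function(x, y) {
  u_stat <- function(a, b)
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_obs <- u_stat(x, y)
  combs <- utils::combn(n1 + n2, n1)
  u_all <- apply(combs, 2, function(ix)
    u_stat(pooled[ix], pooled[-ix]))
  tol <- 1e-9
  p <- min(1, 2 * min(mean(u_all <= u_obs + tol),
                      mean(u_all >= u_obs - tol)))
  list(U = u_obs, p_value = p)
}

# A three-network atlas for reduced-size checks.
tiny_atlas <- function() fbn_atlas(c("A", "B", "C"))

# Small, fast study conditions for structural pipeline tests (NOT the
# default study conditions; those are exercised in test-acceptance.R).
tiny_cohort_config <- function(seed = 11L) {
  cohort_config(
    n_per_group = c("H-Train" = 24, "H-Test" = 8, "SCZ" = 8, "BD" = 8),
    train_group = "H-Train",
    n_timepoints = 60,
    perturbations = list(
      "SCZ" = list(list(pair = c("ASN", "BGN"), delta = 0.4),
                   list(pair = c("BGN", "HVN"), delta = 0.4)),
      "BD" = list(list(pair = c("BGN", "LN"), delta = 0.4))),
    seed = seed)
}

tiny_spec <- function(seed = 5L, epochs = 60L)
  autoencoder_spec(epochs = epochs, seed = seed)

# random valid symmetric correlation-like matrix for round-trip checks
random_symmetric <- function(n, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}
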