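#' Fit the per-feature standardizer on the healthy training set
#'
#' z = (x - mu) / sigma, with mu and sigma the per-feature mean and
#' population standard deviation (divide by n) of the training subjects
#' only. Test subjects are standardized with these training-set
#' parameters, never their own, so no information leaks from test to
#' train.
#'
#' @param train_features subjects x p numeric matrix (training set only).
#' @return List of class `standardizer`: `mu`, `sigma` (length-p vectors)
#'   and `n_train`.
#' @export
fit_standardizer <- function(train_features) {
  x <- as.matrix(train_features)
  if (nrow(x) < 2) stop("need at least 2 training subjects")
  n <- nrow(x)
  mu <- colMeans(x)
  sigma <- sqrt(colMeans(x^2) - mu^2)  # population SD
  if (any(sigma <= 0)) {
    bad <- colnames(x)[which(sigma <= 0)]
    if (is.null(bad)) bad <- which(sigma <= 0)
    stop("degenerate feature(s) with zero SD: ",
         paste(bad, collapse = ", "))
  }
  structure(list(mu = mu, sigma = sigma, n_train = n),
            class = "standardizer")
}

#' Apply a fitted standardizer
#'
#' @param params A `standardizer` from [fit_standardizer()].
#' @param features subjects x p matrix (any set: train or test).
#' @return Matrix of z-scores, same shape.
#' @export
apply_standardizer <- function(params, features) {
  x <- as.matrix(features)
  if (ncol(x) != length(params$mu))
    stop("feature count mismatch: standardizer has ", length(params$mu),
         ", data has ", ncol(x))
  sweep(sweep(x, 2, params$mu, "-"), 2, params$sigma, "/")
}

#' Invert a standardizer (z back to the original feature scale)
#'
#' @param params A `standardizer`.
#' @param z Matrix of z-scores.
#' @return Matrix on the original scale.
#' @export
invert_standardizer <- function(params, z) {
  sweep(sweep(as.matrix(z), 2, params$sigma, "*"), 2, params$mu, "+")
}
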