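#' Autoencoder architecture and training hyper-parameters
#'
#' The normative model is a fully connected autoencoder with three hidden
#' layers, 91-46-13-46-91: the 91 standardized connectivity features are
#' compressed through a 13-unit bottleneck and reconstructed. Hidden
#' units use leaky rectified linear activation; the output layer is
#' linear (targets are standardized reals). Weights follow He (fan-in,
#' normal) initialization; training minimizes mean squared error with L2
#' weight decay and dropout after each hidden activation, for a fixed
#' number of epochs of minibatch Adam.
#'
#' @param layer_sizes Integer vector, input through output; the default is
#'   the 91-46-13-46-91 architecture.
#' @param leaky_slope Negative-side slope of the leaky ReLU (default
#'   0.01).
#' @param l2_penalty L2 regularization coefficient on all weight matrices
#'   (default 1e-5).
#' @param dropout_rate Dropout probability after each hidden activation
#'   (default 0.5; 0 disables dropout).
#' @param epochs Training epochs (default 1000).
#' @param learning_rate,beta1,beta2,epsilon Adam parameters (defaults
#'   5e-4, 0.9, 0.999, 1e-7).
#' @param batch_size Minibatch size (default 8; small batches give many
#'   more Adam steps per epoch, which this small-sample, heavily
#'   dropout-regularized model needs to converge well).
#' @param seed Integer seed controlling weight init, dropout masks and
#'   minibatch shuffling.
#' @return A list of class `autoencoder_spec`.
#' @export
autoencoder_spec <- function(layer_sizes = c(91L, 46L, 13L, 46L, 91L),
                             leaky_slope = 0.01,
                             l2_penalty = 1e-5,
                             dropout_rate = 0.5,
                             epochs = 1000L,
                             learning_rate = 5e-4,
                             beta1 = 0.9, beta2 = 0.999, epsilon = 1e-7,
                             batch_size = 8L,
                             seed = 1L) {
  stopifnot(length(layer_sizes) >= 3,
            layer_sizes[1] == layer_sizes[length(layer_sizes)],
            min(layer_sizes) < layer_sizes[1],
            dropout_rate >= 0, dropout_rate < 1,
            leaky_slope >= 0, l2_penalty >= 0,
            epochs >= 1, batch_size >= 1, learning_rate > 0,
            beta1 >= 0, beta1 < 1, beta2 >= 0, beta2 < 1, epsilon > 0)
  structure(list(layer_sizes = as.integer(layer_sizes),
                 leaky_slope = leaky_slope, l2_penalty = l2_penalty,
                 dropout_rate = dropout_rate, epochs = as.integer(epochs),
                 learning_rate = learning_rate, beta1 = beta1,
                 beta2 = beta2, epsilon = epsilon,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "autoencoder_spec")
}

he_init <- function(sizes) {
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1],
                                  sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  list(W = W, b = b)
}

lrelu <- function(z, slope) ifelse(z > 0, z, slope * z)
lrelu_grad <- function(z, slope) ifelse(z > 0, 1, slope)

# forward pass without dropout (inference)
ae_forward <- function(W, b, x, slope) {
  L <- length(W)
  a <- x
  for (l in seq_len(L - 1L)) {
    a <- lrelu(a %*% W[[l]] + rep(b[[l]], each = nrow(a)), slope)
  }
  a %*% W[[L]] + rep(b[[L]], each = nrow(a))
}

#' Train the normative autoencoder
#'
#' Expects standardized features (see [fit_standardizer()]): train only on
#' healthy controls, so reconstruction error measures deviation from the
#' healthy norm. Runs exactly `spec$epochs` epochs of minibatch Adam with
#' inverted dropout; the per-epoch mean minibatch loss (MSE + L2 term) is
#' recorded. Deterministic for a fixed seed on a fixed platform.
#'
#' @param spec An [autoencoder_spec()].
#' @param train_features Standardized subjects x p matrix, p =
#'   `spec$layer_sizes[1]`.
#' @param standardizer Optional `standardizer` to carry with the model.
#' @return A list of class `trained_model`: `W`, `b`, `spec`,
#'   `standardizer`, `history` (per-epoch loss).
#' @export
train_autoencoder <- function(spec, train_features, standardizer = NULL) {
  stopifnot(inherits(spec, "autoencoder_spec"))
  X <- as.matrix(train_features)
  p <- spec$layer_sizes[1]
  if (ncol(X) != p) stop("expected ", p, " features, got ", ncol(X))
  n <- nrow(X)
  if (n < 2) stop("need at least 2 training subjects")

  old <- local_seed(spec$seed)
  on.exit(restore_seed(old))

  sizes <- spec$layer_sizes
  L <- length(sizes) - 1L
  par <- he_init(sizes)
  W <- par$W; b <- par$b
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  slope <- spec$leaky_slope; l2 <- spec$l2_penalty
  drop <- spec$dropout_rate
  lr <- spec$learning_rate; b1 <- spec$beta1; b2 <- spec$beta2
  eps <- spec$epsilon
  t_step <- 0L
  history <- numeric(spec$epochs)

  for (epoch in seq_len(spec$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = spec$batch_size)
    epoch_loss <- 0; epoch_n <- 0L
    for (s in starts) {
      idx <- ord[s:min(s + spec$batch_size - 1L, n)]
      x <- X[idx, , drop = FALSE]
      B <- nrow(x)
      # forward with cached pre-activations and dropout masks
      Z <- vector("list", L); A <- vector("list", L + 1L)
      M <- vector("list", L - 1L)
      A[[1]] <- x
      for (l in seq_len(L - 1L)) {
        Z[[l]] <- A[[l]] %*% W[[l]] + rep(b[[l]], each = B)
        h <- lrelu(Z[[l]], slope)
        if (drop > 0) {
          M[[l]] <- matrix((stats::runif(B * sizes[l + 1]) >= drop) /
                             (1 - drop), B, sizes[l + 1])
          h <- h * M[[l]]
        }
        A[[l + 1L]] <- h
      }
      yhat <- A[[L]] %*% W[[L]] + rep(b[[L]], each = B)
      resid <- yhat - x
      mse <- mean(resid^2)
      loss <- mse + l2 * sum(vapply(W, function(w) sum(w^2), 0))
      if (!is.finite(loss))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      epoch_loss <- epoch_loss + loss * B; epoch_n <- epoch_n + B

      # backward
      gW <- vector("list", L); gb <- vector("list", L)
      d <- 2 * resid / (B * p)
      gW[[L]] <- crossprod(A[[L]], d) + 2 * l2 * W[[L]]
      gb[[L]] <- colSums(d)
      for (l in rev(seq_len(L - 1L))) {
        d <- d %*% t(W[[l + 1L]])
        if (drop > 0) d <- d * M[[l]]
        d <- d * lrelu_grad(Z[[l]], slope)
        gW[[l]] <- crossprod(A[[l]], d) + 2 * l2 * W[[l]]
        gb[[l]] <- colSums(d)
      }

      # Adam
      t_step <- t_step + 1L
      c1 <- 1 - b1^t_step; c2 <- 1 - b2^t_step
      for (l in seq_len(L)) {
        mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW[[l]]
        vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW[[l]]^2
        W[[l]] <- W[[l]] - lr * (mW[[l]] / c1) /
          (sqrt(vW[[l]] / c2) + eps)
        mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb[[l]]
        vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb[[l]]^2
        b[[l]] <- b[[l]] - lr * (mb[[l]] / c1) /
          (sqrt(vb[[l]] / c2) + eps)
      }
    }
    history[epoch] <- epoch_loss / epoch_n
  }

  structure(list(W = W, b = b, spec = spec, standardizer = standardizer,
                 history = history),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat("<trained_model> ", paste(x$spec$layer_sizes, collapse = "-"),
      ", ", x$spec$epochs, " epochs, final loss ",
      signif(utils::tail(x$history, 1), 4), "\n", sep = "")
  invisible(x)
}

#' Reconstruct subjects through the trained normative model
#'
#' Inference applies no dropout. For each subject, returns the
#' reconstruction, the absolute difference |reconstruction - input| per
#' feature (the per-pair deviation used downstream), and the per-subject
#' mean squared error over the p features
#' (MSE_s = (1/p) * sum((yhat - y)^2)).
#'
#' @param model A `trained_model`.
#' @param features Standardized subjects x p matrix.
#' @return List of class `reconstruction`: `reconstruction`, `abs_diff`
#'   (both subjects x p), `mse_s` (named numeric vector).
#' @export
reconstruct <- function(model, features) {
  X <- as.matrix(features)
  p <- model$spec$layer_sizes[1]
  if (ncol(X) != p) stop("expected ", p, " features, got ", ncol(X))
  yhat <- ae_forward(model$W, model$b, X, model$spec$leaky_slope)
  resid <- yhat - X
  mse_s <- rowMeans(resid^2)
  names(mse_s) <- rownames(X)
  dimnames(yhat) <- dimnames(X)
  structure(list(reconstruction = yhat, abs_diff = abs(resid),
                 mse_s = mse_s),
            class = "reconstruction")
}
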