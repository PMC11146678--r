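# Exact t-SNE (no tree approximation) for the 2-D visualization of
# population activity: a few hundred (trial x epoch) points at most, so the
# O(n^2) gradient is cheap.  Perplexity calibration follows the standard
# per-point binary search on the Gaussian bandwidth.

tsne_p_matrix <- function(X, perplexity) {
  n <- nrow(X)
  D2 <- as.matrix(dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    lo <- -Inf
    hi <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sump <- sum(p)
      if (sump == 0) p <- rep(1e-12, length(di)) else p <- p / sump
      H <- -sum(p * log(pmax(p, 1e-12)))
      if (abs(H - logU) < 1e-5) break
      if (H > logU) {           # too flat: increase beta
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' Embed feature vectors in 2-D with t-SNE (visualization only)
#'
#' Exact t-distributed stochastic neighbour embedding of the (trial x epoch)
#' mean-rate vectors; similar activity patterns map to nearby points.
#' Features are standardized per unit by default.  Deterministic given the
#' seed.
#'
#' @param features Samples x units matrix (e.g.
#'   `epoch_rate_features()$features`).
#' @param perplexity Effective neighbourhood size (default 30; must be <
#'   (n - 1) / 3).
#' @param seed Integer seed.
#' @param standardize Standardize columns first (default `TRUE`).
#' @param n_iter Gradient-descent iterations (default 500).
#' @return An `n x 2` matrix of embedding coordinates.
#' @export
embed_2d <- function(features, perplexity = 30, seed = 1,
                     standardize = TRUE, n_iter = 500) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (perplexity >= (n - 1) / 3)
    stopf("perplexity too large for %d samples", n)
  if (standardize) {
    X <- scale(X)
    X[is.nan(X)] <- 0
  }
  P <- tsne_p_matrix(X, perplexity)
  set.seed(mix_seed(seed, 1001))
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  G <- matrix(0, n, 2)            # momentum accumulator
  lr <- 100
  for (iter in seq_len(n_iter)) {
    ex <- if (iter <= 100) 4 else 1      # early exaggeration
    mom <- if (iter <= 250) 0.5 else 0.8
    num <- 1 / (1 + as.matrix(dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (ex * P - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    G <- mom * G - lr * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
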