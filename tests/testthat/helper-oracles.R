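# Independent oracles used across the suite.  These deliberately do not
# share code with the package internals they check.

# Posterior state probabilities by explicit enumeration of all K^T paths.
# obs uses 0-based symbols; B columns are symbol + 1.
brute_force_posteriors <- function(pi, A, B, obs) {
  K <- length(pi)
  T_ <- length(obs)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  pr <- pi[paths[, 1]] * B[cbind(paths[, 1], obs[1] + 1)]
  if (T_ > 1) {
    for (t in 2:T_) {
      pr <- pr * A[cbind(paths[, t - 1], paths[, t])] *
        B[cbind(paths[, t], obs[t] + 1)]
    }
  }
  gamma <- matrix(0, T_, K)
  for (t in seq_len(T_)) {
    gamma[t, ] <- vapply(seq_len(K), function(k) sum(pr[paths[, t] == k]),
                         numeric(1))
  }
  list(gamma = gamma / rowSums(gamma), loglik = log(sum(pr)))
}

# Plain-R scaled forward-backward, written independently of the C++ code,
# used to cross-check window-averaged posterior decoding.
r_forward_backward <- function(pi, A, B, obs) {
  K <- length(pi)
  T_ <- length(obs)
  alpha <- matrix(0, T_, K)
  cvec <- numeric(T_)
  alpha[1, ] <- pi * B[, obs[1] + 1]
  cvec[1] <- sum(alpha[1, ])
  alpha[1, ] <- alpha[1, ] / cvec[1]
  if (T_ > 1) {
    for (t in 2:T_) {
      alpha[t, ] <- (alpha[t - 1, ] %*% A) * B[, obs[t] + 1]
      cvec[t] <- sum(alpha[t, ])
      alpha[t, ] <- alpha[t, ] / cvec[t]
    }
  }
  beta <- matrix(0, T_, K)
  beta[T_, ] <- 1
  if (T_ > 1) {
    for (t in (T_ - 1):1) {
      beta[t, ] <- A %*% (B[, obs[t + 1] + 1] * beta[t + 1, ]) / cvec[t + 1]
    }
  }
  g <- alpha * beta
  list(gamma = g / rowSums(g), loglik = sum(log(cvec)))
}

# Exact per-bin symbol distribution implied by the generator's rates and
# the random single-unit selection rule: P(symbol = u) = p_u * E[1/(1 + X)]
# where X counts the other active units (Poisson-binomial, computed by DP).
symbol_distribution_oracle <- function(rates_hz, bin_ms = 2) {
  p <- 1 - exp(-rates_hz * bin_ms / 1000)
  U <- length(p)
  out <- numeric(U + 1)
  out[1] <- prod(1 - p)
  for (u in seq_len(U)) {
    q <- p[-u]
    # DP for the distribution of X = number of other active units
    dist <- 1
    for (pv in q) dist <- c(dist * (1 - pv), 0) + c(0, dist * pv)
    out[u + 1] <- p[u] * sum(dist / seq_along(dist))
  }
  out
}

# Davies-Bouldin by direct transcription of the defining formula.
dbi_oracle <- function(features, labels) {
  features <- as.matrix(features)
  labs <- unique(labels)
  K <- length(labs)
  cent <- lapply(labs, function(l) colMeans(features[labels == l, , drop = FALSE]))
  S <- vapply(seq_len(K), function(i) {
    x <- features[labels == labs[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(x, 2, cent[[i]])^2)))
  }, numeric(1))
  total <- 0
  for (i in seq_len(K)) {
    best <- -Inf
    for (j in seq_len(K)) {
      if (i == j) next
      M <- sqrt(sum((cent[[i]] - cent[[j]])^2))
      best <- max(best, (S[i] + S[j]) / M)
    }
    total <- total + best
  }
  total / K
}

# Mean silhouette width (Euclidean), for checking that separated clusters
# stay separated in an embedding.
silhouette_oracle <- function(X, labels) {
  D <- as.matrix(dist(X))
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Expected fraction of bins with two or more active units, from the
# generator's rate model (Poisson counts per epoch).
expected_multi_active_fraction <- function(spec, trials, bin_ms = 2) {
  tot <- 0
  multi <- 0
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    b <- c(tr$home_press_ms, tr$target_on_ms, tr$movement_onset_ms,
           tr$touch_ms, tr$target_off_ms)
    dur <- diff(b)
    for (e in 1:4) {
      rates <- pmin(spec$baseline_rate * spec$epoch_gain[, e] *
                      spec$target_tuning[, tr$target_id], spec$max_rate_hz)
      ps <- exp(-rates * bin_ms / 1000)
      p0 <- prod(ps)
      p1 <- sum((1 - ps) / ps) * p0
      nb <- dur[e] / bin_ms
      tot <- tot + nb
      multi <- multi + nb * (1 - p0 - p1)
    }
  }
  multi / tot
}
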