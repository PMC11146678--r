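test_that("feedforward initialization has the Bakis structure", {
  h1 <- init_feedforward(1, 3, seed = 1)
  expect_equal(h1$A, matrix(1))
  expect_equal(h1$pi, 1)

  h <- init_feedforward(3, 6, seed = 2)
  expect_equal(h$pi, c(1, 0, 0))
  low <- lower.tri(h$A)
  upper2 <- row(h$A) < col(h$A) - 1
  expect_true(all(h$A[low] == 0))
  expect_true(all(h$A[upper2] == 0))
  expect_true(all(diag(h$A)[1:2] > 0.9))
  expect_equal(rowSums(h$A), rep(1, 3))
  expect_equal(rowSums(h$B), rep(1, 3))
  expect_identical(h, init_feedforward(3, 6, seed = 2))
})

test_that("posteriors match exhaustive path enumeration on a worked toy", {
  set.seed(4)
  A <- matrix(c(0.9, 0.1, 0, 1), 2, 2, byrow = TRUE)
  B <- matrix(c(0.7, 0.2, 0.1, 0.1, 0.3, 0.6), 2, 3, byrow = TRUE)
  pi <- c(1, 0)
  h <- hmm_params(pi, A, B, mask = matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2,
                                          byrow = TRUE))
  obs <- c(0L, 0L, 1L, 2L, 2L, 1L)
  tr <- posterior_decode(h, obs)
  oracle <- brute_force_posteriors(pi, A, B, obs)
  expect_lt(max(abs(tr$gamma - oracle$gamma)), 1e-12)
  expect_lt(abs(tr$loglik - oracle$loglik), 1e-12)
  expect_equal(rowSums(tr$gamma), rep(1, 6))
})

test_that("posterior decoding handles degenerate cases", {
  h1 <- init_feedforward(1, 3, seed = 1)
  tr <- posterior_decode(h1, c(0L, 1L, 2L))
  expect_equal(as.vector(tr$gamma), rep(1, 3))
  expect_error(posterior_decode(h1, integer(0)), "empty")
  expect_error(posterior_decode(h1, c(0L, 5L)), "symbols")

  # state 2 owns a private symbol: its posterior locks to 1 after the switch
  A <- matrix(c(0.5, 0.5, 0, 1), 2, 2, byrow = TRUE)
  B <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)
  h <- hmm_params(c(1, 0), A, B,
                  mask = matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2, byrow = TRUE))
  tr <- posterior_decode(h, c(0L, 0L, 1L, 1L))
  expect_equal(tr$gamma[, 2], c(0, 0, 1, 1))
})

test_that("Baum-Welch obeys the EM guarantees and the structural mask", {
  set.seed(10)
  init <- init_feedforward(3, 5, seed = 3)
  seqs <- lapply(1:8, function(i) sample(0:4, 80, replace = TRUE))
  fit <- baum_welch(init, seqs, max_iter = 60)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  expect_true(all(fit$params$A[!init$mask] == 0))
  expect_equal(rowSums(fit$params$A), rep(1, 3), tolerance = 1e-12)
  expect_equal(rowSums(fit$params$B), rep(1, 3), tolerance = 1e-12)
  # determinism
  fit2 <- baum_welch(init, seqs, max_iter = 60)
  expect_identical(fit$params$B, fit2$params$B)
})

test_that("one-state Baum-Welch reduces to the empirical symbol frequency", {
  seqv <- c(rep(1L, 30), rep(0L, 70))
  fit <- baum_welch(init_feedforward(1, 2, seed = 5), list(seqv))
  expect_equal(fit$params$B[1, ], c(0.7, 0.3), tolerance = 1e-5)
})

test_that("Baum-Welch recovers planted feedforward parameters", {
  # plant a 3-state chain with well-separated emission rows and sample
  # sequences from it; the fit must recover B up to small estimation error
  set.seed(77)
  K <- 3; M <- 6
  A <- matrix(0, K, K)
  A[1, 1] <- 0.95; A[1, 2] <- 0.05
  A[2, 2] <- 0.95; A[2, 3] <- 0.05
  A[3, 3] <- 1
  B <- rbind(c(0.70, 0.12, 0.12, 0.02, 0.02, 0.02),
             c(0.10, 0.05, 0.05, 0.70, 0.05, 0.05),
             c(0.05, 0.40, 0.05, 0.05, 0.40, 0.05))
  gen_seq <- function(T_) {
    s <- 1L
    out <- integer(T_)
    for (t in seq_len(T_)) {
      out[t] <- sample.int(M, 1, prob = B[s, ]) - 1L
      s <- sample.int(K, 1, prob = A[s, ])
    }
    out
  }
  seqs <- lapply(1:200, function(i) gen_seq(150))
  init <- init_feedforward(K, M, seed = 1, empirical_from = seqs)
  fit <- baum_welch(init, seqs, max_iter = 200, n_restarts = 2)
  expect_lt(max(abs(fit$params$B - B)), 0.02)
})

test_that("supervised estimation implements the duration and frequency rules", {
  # two epochs; epoch 1 spans 250 bins per trial, epoch 2 spans 150 bins
  labs <- rep(c("FREE", "DELAY"), c(250, 150))
  mkseq <- function(seed) {
    set.seed(seed)
    c(sample(c(0L, 2L), 250, replace = TRUE, prob = c(0.9, 0.1)),
      sample(c(0L, 1L), 150, replace = TRUE))
  }
  seqs <- lapply(1:5, mkseq)
  fit <- supervised_fit(seqs, rep(list(labs), 5), epochs = c("FREE", "DELAY"))
  expect_equal(fit$A[1, 2], 1 / 250)
  expect_equal(fit$A[1, 1], 1 - 1 / 250)
  expect_equal(fit$A[2, ], c(0, 1))     # last epoch is absorbing
  # emission = symbol frequency within the epoch (up to the smoothing floor)
  freq2 <- sum(vapply(seqs, function(s) sum(s[1:250] == 2), numeric(1))) /
    (5 * 250)
  expect_equal(fit$B[1, 3], freq2, tolerance = 1e-4)
  expect_error(supervised_fit(seqs, rep(list(rep("FREE", 400)), 5),
                              epochs = c("FREE", "DELAY")),
               "zero labelled bins")
})

test_that("supervised transition rule: mean epoch duration of 250 bins", {
  # epoch durations differing across trials average before inversion
  labs1 <- rep(c("A", "B"), c(200, 100))
  labs2 <- rep(c("A", "B"), c(300, 100))
  seqs <- list(rep(0L, 300), rep(0L, 400))
  fit <- supervised_fit(seqs, list(labs1, labs2), epochs = c("A", "B"))
  expect_equal(fit$A[1, 2], 0.004)   # 1 / mean(200, 300)
  expect_equal(fit$A[1, 1], 0.996)
})

test_that("consistency analysis counts threshold crossings per state", {
  # group of sequences generated by a sharply 2-state process: K = 2 is
  # consistent in every sequence
  set.seed(42)
  gen <- function() c(sample(c(0L, 1L), 50, TRUE, prob = c(0.9, 0.1)),
                      sample(c(2L, 3L), 50, TRUE))
  train <- lapply(1:20, function(i) gen())
  test <- lapply(1:10, function(i) gen())
  rep <- consistency_analysis(list(train), list(test), n_symbols = 4,
                              K_range = 2:3, max_iter = 50, n_restarts = 2,
                              seed = 1)
  expect_equal(rep$table$fraction[rep$table$K == 2], 1)
  expect_true(all(rep$table$fraction >= 0 & rep$table$fraction <= 1))
})

test_that("transition timing converts bins to ms and corrects variance", {
  # posterior crossing 0.7 first at bin 450 of a window starting at -1000 ms
  g <- matrix(0, 500, 2)
  g[, 1] <- 1
  g[450:500, 2] <- 0.8
  g[450:500, 1] <- 0.2
  tt <- transition_timing(list(g), threshold = 0.7, window_start_ms = -1000,
                          bin_ms = 2)
  expect_equal(tt$mean_rise_ms[2], -100)

  # var(rise) = 100, var(event) = 36 -> corrected SD = 8
  rises <- c(0, 10, 20)                       # var = 100
  evs <- c(0, 6, 12)                          # var = 36
  gs <- lapply(rises, function(r) {
    g <- matrix(0, 50, 1)
    g[(r / 2 + 1):50, 1] <- 1
    g
  })
  tt <- transition_timing(gs, threshold = 0.7, window_start_ms = -2,
                          bin_ms = 2, event_times_ms = evs)
  expect_equal(tt$sd_rise_ms[1], sqrt(var(rises - evs)))
  # with var_event = 0 the corrected SD equals the raw SD
  tt0 <- transition_timing(gs, threshold = 0.7, window_start_ms = -2,
                           bin_ms = 2)
  expect_equal(tt0$corrected_sd_ms[1], tt0$sd_rise_ms[1])
})

test_that("variance correction is floored at zero", {
  gs <- lapply(c(0, 2), function(r) {
    g <- matrix(0, 20, 1)
    g[(r / 2 + 1):20, 1] <- 1
    g
  })
  tt <- transition_timing(gs, threshold = 0.7, window_start_ms = 0,
                          bin_ms = 2, event_times_ms = c(0, 50))
  expect_equal(tt$corrected_sd_ms[1], 0)
})
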