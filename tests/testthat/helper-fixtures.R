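# Shared fixtures, memoized so expensive synthetic datasets are built once
# per test run.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

fixture_dataset <- function(n_units = 40, profile = "V6A-like",
                            n_trials = 10, seed = 7) {
  key <- paste("ds", n_units, profile, n_trials, seed, sep = "_")
  cached(key, make_synthetic_dataset(n_units, profile,
                                     n_trials_per_target = n_trials,
                                     seed = seed))
}

# A deterministic miniature spike set with hand-placed spikes: 3 units, 2
# trials, easy to reason about in IO and binning tests.
toy_dataset <- function() {
  trials <- data.frame(
    trial_id = 1:2, target_id = c(1L, 5L), home_press_ms = 0,
    target_on_ms = 1000, go_ms = c(2900, 3100),
    movement_onset_ms = c(3200, 3400), touch_ms = c(3560, 3770),
    target_off_ms = c(4560, 4790))
  spikes <- data.frame(
    unit_id = c(1L, 1L, 2L, 3L, 3L, 3L, 2L),
    trial_id = c(1L, 1L, 1L, 1L, 2L, 2L, 2L),
    time_ms = c(10.5, 999.9, 1000.0, 3200.0, 250.3, 3500.1, 4000.7))
  reachstates:::new_spike_dataset(spikes, trials, n_units = 3, area = "toy")
}

sort_by_key <- function(sp) {
  sp <- sp[order(sp$unit_id, sp$trial_id, sp$time_ms), ]
  rownames(sp) <- NULL
  sp
}

# A binned_counts object built directly from a matrix (single trial).
counts_from_matrix <- function(m, bin_ms = 2, trial_id = 1L, target_id = 1L) {
  structure(list(counts = list(m), trial_ids = trial_id,
                 target_ids = target_id, n_units = nrow(m),
                 event = "movement_onset",
                 window = c(0, ncol(m) * bin_ms), bin_ms = bin_ms,
                 n_bins = ncol(m)),
            class = "binned_counts")
}

# Nine 2-state and nine 3-state toy component models with M symbols,
# for boosted-structure tests that do not need training.
toy_target_models <- function(M = 5, seed = 3) {
  set.seed(seed)
  mk <- function(K) {
    A <- matrix(0, K, K)
    for (i in seq_len(K - 1)) {
      s <- runif(1, 0.95, 0.99)
      A[i, i] <- s
      A[i, i + 1] <- 1 - s
    }
    A[K, K] <- 1
    B <- matrix(runif(K * M, 0.05, 1), K, M)
    B <- B / rowSums(B)
    hmm_params(pi = c(1, rep(0, K - 1)), A = A, B = B,
               mask = reachstates:::feedforward_mask(K))
  }
  list(two = lapply(1:9, function(i) mk(2)),
       three = lapply(1:9, function(i) mk(3)))
}
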