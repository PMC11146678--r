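#' Construct an HMM parameter set
#'
#' @param pi Initial state distribution (length `K`).
#' @param A `K x K` transition matrix; entries outside `mask` must be zero.
#' @param B `K x M` emission matrix over symbols `0..M-1` (column `s + 1`
#'   holds the probability of symbol `s`).
#' @param mask Logical `K x K` structural mask of allowed transitions.
#' @param state_labels Optional `data.frame` mapping states to labels (e.g.
#'   epoch/target for the boosted model).
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(pi, A, B, mask = A > 0, state_labels = NULL) {
  K <- length(pi)
  stopifnot(nrow(A) == K, ncol(A) == K, nrow(B) == K,
            nrow(mask) == K, ncol(mask) == K)
  x <- structure(list(K = K, M = ncol(B), pi = as.numeric(pi), A = A, B = B,
                      mask = mask, state_labels = state_labels),
                 class = "hmm_params")
  validate_hmm_params(x)
  x
}

validate_hmm_params <- function(x, tol = 1e-9) {
  if (abs(sum(x$pi) - 1) > tol) stopf("pi must sum to 1")
  if (any(abs(rowSums(x$A) - 1) > tol)) stopf("rows of A must sum to 1")
  if (any(abs(rowSums(x$B) - 1) > tol)) stopf("rows of B must sum to 1")
  if (any(x$A[!x$mask] != 0)) stopf("A has mass on masked transitions")
  invisible(x)
}

#' @export
print.hmm_params <- function(x, ...) {
  cat(sprintf("<hmm_params> K = %d states, M = %d symbols, %d allowed transitions\n",
              x$K, x$M, sum(x$mask)))
  invisible(x)
}

feedforward_mask <- function(K) {
  mask <- diag(K) > 0
  if (K > 1) mask[cbind(seq_len(K - 1), seq_len(K - 1) + 1)] <- TRUE
  mask
}

#' Initialize a feedforward (Bakis) HMM with pseudo-random parameters
#'
#' The chain starts in state 1 (`pi = (1, 0, ...)`), transitions allow only
#' self-loops and steps to the next state, self-transition probabilities are
#' drawn near 0.98 (reaching states persist over many 2-ms bins), the last
#' state is absorbing up to its random perturbation, and emission rows are
#' random positive vectors normalized to 1.
#'
#' @param K Number of states (>= 1).
#' @param M Number of symbols (units + 1 >= 2).
#' @param seed Integer seed.
#' @param self_mean Centre of the random self-transition probability.
#' @param empirical_from Optional training sequences (any form accepted by
#'   [baum_welch()]).  When given, each emission row is a random
#'   multiplicative perturbation of the empirical symbol distribution
#'   instead of a uniform draw; with hundreds of bins per state this avoids
#'   the degenerate EM optimum in which early states explain everything and
#'   later states are starved.
#' @return An `hmm_params` object.
#' @export
init_feedforward <- function(K, M, seed = 1, self_mean = 0.98,
                             empirical_from = NULL) {
  K <- check_count(K, "K")
  M <- check_count(M, "M", min = 2)
  set.seed(mix_seed(seed, 505))
  A <- matrix(0, K, K)
  for (i in seq_len(K)) {
    if (i < K) {
      s <- min(max(self_mean + runif(1, -0.015, 0.015), 0.9), 0.999)
      A[i, i] <- s
      A[i, i + 1] <- 1 - s
    } else A[i, i] <- 1
  }
  if (is.null(empirical_from)) {
    B <- matrix(runif(K * M, 0.05, 1), K, M)
  } else {
    syms <- unlist(as_sequence_list(empirical_from))
    emp <- (tabulate(syms + 1L, nbins = M) + 1) / (length(syms) + M)
    B <- matrix(rep(emp, each = K), K, M) *
      matrix(runif(K * M, 0.5, 1.5), K, M)
  }
  B <- B / rowSums(B)
  hmm_params(pi = c(1, rep(0, K - 1)), A = A, B = B,
             mask = feedforward_mask(K))
}

# Flatten sequence containers into a plain list of integer vectors
# (symbols 0..M-1).
as_sequence_list <- function(x) {
  if (inherits(x, "emission_seqs"))
    return(unlist(lapply(x$seqs, function(m) lapply(seq_len(nrow(m)),
                                                    function(r) m[r, ])),
                  recursive = FALSE))
  if (is.matrix(x)) return(lapply(seq_len(nrow(x)), function(r) x[r, ]))
  if (is.list(x)) return(lapply(x, as.integer))
  list(as.integer(x))
}

#' Fit an HMM by Baum-Welch (EM) under a structural transition mask
#'
#' Multi-sequence expectation-maximization: expected transition and emission
#' counts are accumulated over all sequences each iteration.  The initial
#' distribution is held fixed, masked transitions stay exactly zero, and
#' every emission row receives an additive floor (then renormalization) so
#' that unseen or later-removed units never zero out a sequence likelihood.
#' Training stops after `max_iter` iterations or when the log-likelihood
#' gain falls below `tol`.
#'
#' @param init An `hmm_params` starting point, e.g. [init_feedforward()].
#' @param sequences An `emission_seqs` object, a matrix (rows = sequences),
#'   or a list of integer vectors with symbols in `0..M-1`.
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Absolute log-likelihood improvement threshold (default 1e-6).
#' @param emission_floor Additive emission floor (default 1e-6).
#' @param n_restarts Independent pseudo-random restarts; the fit with the
#'   highest final log-likelihood is kept (EM converges to local optima;
#'   restarts are drawn by re-initializing around `init` with fresh seeds).
#'   Default 1 (use `init` as given).
#' @param restart_seed Seed for the restart initializations.
#' @return A list of class `hmm_fit`: `params` (the fitted `hmm_params`),
#'   `loglik_trace`, `iterations`, `converged`.
#' @export
baum_welch <- function(init, sequences, max_iter = 500, tol = 1e-6,
                       emission_floor = 1e-6, n_restarts = 1,
                       restart_seed = 1) {
  stopifnot(inherits(init, "hmm_params"))
  seqs <- as_sequence_list(sequences)
  if (!length(seqs)) stopf("no training sequences")
  best <- NULL
  for (r in seq_len(max(1, n_restarts))) {
    ini <- if (r == 1) init else
      init_feedforward(init$K, init$M, seed = mix_seed(restart_seed, 515, r),
                       empirical_from = seqs)
    res <- rs_baum_welch(ini$pi, ini$A, ini$B, init$mask, seqs,
                         as.integer(max_iter), tol, emission_floor)
    if (is.null(best) ||
        tail(res$loglik_trace, 1) > tail(best$loglik_trace, 1))
      best <- res
  }
  params <- hmm_params(init$pi, best$A, best$B, init$mask, init$state_labels)
  structure(list(params = params, loglik_trace = best$loglik_trace,
                 iterations = best$iterations, converged = best$converged),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("<hmm_fit> K = %d, %d EM iterations (%s), final loglik %.2f\n",
              x$params$K, x$iterations,
              if (x$converged) "converged" else "max_iter reached",
              tail(x$loglik_trace, 1)))
  invisible(x)
}

#' Supervised HMM estimation from epoch-labelled sequences
#'
#' Direct parameter estimation without EM: the forward transition probability
#' out of epoch state `i` is `1 / (mean number of bins spent in epoch i)`,
#' the self-transition its complement (the last epoch is absorbing), and the
#' emission probability of symbol `s` in state `i` is the frequency of `s`
#' among bins labelled `i`.  The same emission floor as [baum_welch()] is
#' applied, then rows are renormalized.
#'
#' @param sequences An `emission_seqs` object (or list of integer vectors).
#' @param epoch_labels A list parallel to the trials of `sequences` (or to
#'   the plain sequence list), each an integer/character vector labelling
#'   every bin with its epoch; epochs must appear in feedforward order.
#' @param epochs Epoch order; defaults to the order of first appearance.
#' @param emission_floor Additive emission floor (default 1e-6).
#' @return An `hmm_params` with one state per epoch and `state_labels`.
#' @export
supervised_fit <- function(sequences, epoch_labels, epochs = NULL,
                           emission_floor = 1e-6) {
  if (inherits(sequences, "emission_seqs")) {
    M <- sequences$n_symbols
    n_rep <- sequences$n_repeats
    seq_list <- sequences$seqs           # per-trial matrices
    if (length(epoch_labels) != length(seq_list))
      stopf("need one label vector per trial")
  } else {
    seq_list <- lapply(as_sequence_list(sequences), function(v) matrix(v, 1))
    M <- max(unlist(lapply(seq_list, max))) + 1L
    n_rep <- 1L
    if (length(epoch_labels) != length(seq_list))
      stopf("need one label vector per sequence")
  }
  lab_all <- unlist(lapply(epoch_labels, as.character))
  if (is.null(epochs)) epochs <- unique(lab_all)
  K <- length(epochs)
  bins_per <- matrix(0, length(seq_list), K)  # bins in epoch per trial
  sym_counts <- matrix(0, K, M)
  for (i in seq_along(seq_list)) {
    lab <- as.character(epoch_labels[[i]])
    m <- seq_list[[i]]
    if (length(lab) != ncol(m))
      stopf("label vector %d has length %d but sequence has %d bins",
            i, length(lab), ncol(m))
    for (k in seq_len(K)) {
      sel <- lab == epochs[k]
      bins_per[i, k] <- sum(sel)
      if (any(sel))
        sym_counts[k, ] <- sym_counts[k, ] +
          tabulate(as.vector(m[, sel, drop = FALSE]) + 1L, nbins = M)
    }
  }
  if (any(colSums(bins_per) == 0))
    stopf("epoch(s) with zero labelled bins: %s",
          paste(epochs[colSums(bins_per) == 0], collapse = ", "))
  mean_bins <- colMeans(bins_per)
  A <- matrix(0, K, K)
  for (k in seq_len(K)) {
    if (k < K) {
      fwd <- 1 / mean_bins[k]
      A[k, k + 1] <- fwd
      A[k, k] <- 1 - fwd
    } else A[k, k] <- 1
  }
  B <- sym_counts / rowSums(sym_counts)
  B <- B + emission_floor
  B <- B / rowSums(B)
  hmm_params(pi = c(1, rep(0, K - 1)), A = A, B = B,
             mask = feedforward_mask(K),
             state_labels = data.frame(state = seq_len(K), epoch = epochs))
}

#' Posterior state probabilities of a sequence (forward-backward)
#'
#' @param params An `hmm_params`.
#' @param sequence Integer vector of symbols in `0..M-1`.
#' @return A list of class `posterior_trace`: `gamma` (`bins x K`, rows sum
#'   to 1) and `loglik`.
#' @export
posterior_decode <- function(params, sequence) {
  stopifnot(inherits(params, "hmm_params"))
  sequence <- as.integer(sequence)
  if (!length(sequence)) stopf("empty sequence")
  if (any(sequence < 0 | sequence >= params$M))
    stopf("symbols must lie in 0..M-1")
  res <- rs_forward_backward(params$pi, params$A, params$B, params$mask,
                             sequence)
  structure(list(gamma = res$gamma, loglik = res$loglik),
            class = "posterior_trace")
}

# A sequence is "consistent" with a K-state model when every state's
# posterior reaches `threshold` in at least one bin.
sequence_consistent <- function(gamma, threshold) {
  all(apply(gamma, 2, max) >= threshold)
}

#' Consistency analysis for choosing the number of neural states
#'
#' For each candidate state count `K`, fits one feedforward HMM per training
#' group (typically one group per reach target) and computes the fraction of
#' held-out sequences in which the posterior of every state reaches
#' `threshold` at least once.  The selected state count is the largest `K`
#' whose consistent fraction is at least `select_frac`.
#'
#' @param train_groups List of groups, each a list/matrix of training
#'   sequences (or a single `emission_seqs` per group).
#' @param test_groups Held-out sequences, same structure as `train_groups`.
#' @param n_symbols Symbol-alphabet size (units + 1).
#' @param K_range Candidate state counts (default `2:7`).
#' @param threshold State-probability threshold (default 0.7).
#' @param select_frac Minimum consistent fraction for selection (default 0.9).
#' @param max_iter,tol,emission_floor,n_restarts Passed to [baum_welch()].
#' @param seed Integer seed (one substream per group and K).
#' @return A list of class `consistency_report`: `table`
#'   (`data.frame(K, n_consistent, n_sequences, fraction)`), `chosen_k`,
#'   `threshold`.
#' @export
consistency_analysis <- function(train_groups, test_groups, n_symbols,
                                 K_range = 2:7, threshold = 0.7,
                                 select_frac = 0.9, max_iter = 500,
                                 tol = 1e-6, emission_floor = 1e-6,
                                 n_restarts = 1, seed = 1) {
  stopifnot(length(train_groups) == length(test_groups))
  rows <- lapply(K_range, function(K) {
    n_cons <- 0L
    n_tot <- 0L
    for (g in seq_along(train_groups)) {
      tr_seqs <- as_sequence_list(train_groups[[g]])
      init <- init_feedforward(K, n_symbols, seed = mix_seed(seed, K, g),
                               empirical_from = tr_seqs)
      fit <- baum_welch(init, tr_seqs, max_iter = max_iter, tol = tol,
                        emission_floor = emission_floor,
                        n_restarts = n_restarts,
                        restart_seed = mix_seed(seed, K, g, 7))
      for (s in as_sequence_list(test_groups[[g]])) {
        tr <- posterior_decode(fit$params, s)
        n_cons <- n_cons + sequence_consistent(tr$gamma, threshold)
        n_tot <- n_tot + 1L
      }
    }
    data.frame(K = K, n_consistent = n_cons, n_sequences = n_tot,
               fraction = n_cons / n_tot)
  })
  tab <- do.call(rbind, rows)
  ok <- tab$K[tab$fraction >= select_frac]
  structure(list(table = tab,
                 chosen_k = if (length(ok)) max(ok) else NA_integer_,
                 threshold = threshold, select_frac = select_frac),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat("<consistency_report>\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("chosen K: %s (largest K with fraction >= %.2f)\n",
              x$chosen_k, x$select_frac))
  invisible(x)
}

#' State-transition timing from posterior traces
#'
#' The "rise" of a state is the first bin in which its posterior reaches
#' `threshold`; rise times are reported in ms relative to the trace's
#' alignment window (`rise = window_start + bin * bin_ms`).  When a
#' behavioural reference event varies across trials, the transition SD is
#' corrected by subtracting the event-timing variance:
#' `corrected SD = sqrt(max(0, var(rise) - var(event)))`.
#'
#' @param traces List of `posterior_trace` objects (or gamma matrices) from
#'   consistent sequences.
#' @param threshold Posterior threshold (default 0.7).
#' @param window_start_ms Start of the alignment window in ms.
#' @param bin_ms Bin width in ms.
#' @param event_times_ms Optional per-trace reference event times (same ms
#'   axis); defaults to 0 (alignment event itself, zero variance).
#' @return A `data.frame` with one row per state: mean and SD of the rise
#'   relative to the event, the variance-corrected SD, and how many traces
#'   rose.  States that never rise in a trace are excluded from that trace's
#'   statistics but counted in `n_no_rise`.
#' @export
transition_timing <- function(traces, threshold = 0.7, window_start_ms,
                              bin_ms = 2, event_times_ms = NULL) {
  gmats <- lapply(traces, function(tr)
    if (inherits(tr, "posterior_trace")) tr$gamma else tr)
  K <- ncol(gmats[[1]])
  n <- length(gmats)
  if (is.null(event_times_ms)) event_times_ms <- rep(0, n)
  stopifnot(length(event_times_ms) == n)
  out <- lapply(seq_len(K), function(k) {
    rises <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      hit <- which(gmats[[i]][, k] >= threshold)
      if (length(hit)) rises[i] <- window_start_ms + hit[1] * bin_ms
    }
    rel <- rises - event_times_ms
    ok <- !is.na(rel)
    v_rise <- if (sum(ok) > 1) var(rel[ok]) else NA_real_
    v_ev <- if (sum(ok) > 1) var(event_times_ms[ok]) else 0
    data.frame(state = k, n_risen = sum(ok), n_no_rise = sum(!ok),
               mean_rise_ms = mean(rel[ok]),
               sd_rise_ms = if (is.na(v_rise)) NA_real_ else sqrt(v_rise),
               corrected_sd_ms = if (is.na(v_rise)) NA_real_ else
                 sqrt(max(0, v_rise - v_ev)))
  })
  do.call(rbind, out)
}
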