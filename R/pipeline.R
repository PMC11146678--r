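#' Decode validation trials with a trained boosted model
#'
#' Builds the concatenated decoding sequences for the given trials,
#' sliding-window decodes them at each requested width, and attaches true
#' labels.
#'
#' @param model An `hmm_params` from [merge_boosted()].
#' @param data A `spike_dataset` (possibly perturbed).
#' @param trial_ids Trials to decode.
#' @param widths_ms Window widths to decode (ms).
#' @param n_repeats Sequences per trial.
#' @param step_ms Window step (ms).
#' @param bin_ms Bin width (ms).
#' @param seed Integer seed for sequence generation.
#' @return A `data.frame` of predictions with a `width_ms` column.
#' @export
decode_with_model <- function(model, data, trial_ids, widths_ms = 200,
                              n_repeats = 100, step_ms = 10, bin_ms = 2,
                              seed = 1) {
  seqs <- build_decode_sequences(data, trial_ids, n_repeats, bin_ms, seed)
  out <- lapply(widths_ms, function(w) {
    pred <- decode_windows(model, seqs, w, step_ms)
    pred <- assign_true_labels(pred, seqs, data$trials)
    pred$width_ms <- w
    pred
  })
  do.call(rbind, out)
}

#' Train and evaluate the boosted HMM decoder on one cross-validation fold
#'
#' Trains the nine two-state and nine three-state target models on the
#' fold's training trials, merges them into the 28-state boosted HMM, and
#' decodes the fold's validation trials.
#'
#' @param data A `spike_dataset`.
#' @param fold A `list(train, validation)` of trial ids (see
#'   [make_cv_folds()]).
#' @param widths_ms Window widths to decode (ms).
#' @param n_repeats Sequences per trial.
#' @param step_ms,bin_ms Window step and bin width (ms).
#' @param method `"baum_welch"` (unsupervised) or `"supervised"`.
#' @param max_iter,tol,emission_floor,n_restarts Training controls, see
#'   [baum_welch()].
#' @param seed Integer seed.
#' @return A list of class `decode_report`: `model`, `target_models`,
#'   `predictions` (with true labels) and the call settings.
#' @export
decode_experiment <- function(data, fold, widths_ms = 200, n_repeats = 100,
                              step_ms = 10, bin_ms = 2,
                              method = c("baum_welch", "supervised"),
                              max_iter = 500, tol = 1e-6,
                              emission_floor = 1e-6, n_restarts = 1,
                              seed = 1) {
  method <- match.arg(method)
  tm <- train_target_models(data, fold$train, n_repeats, bin_ms, method,
                            max_iter, tol, emission_floor,
                            n_restarts = n_restarts,
                            seed = mix_seed(seed, 41))
  model <- merge_boosted(tm)
  pred <- decode_with_model(model, data, fold$validation, widths_ms,
                            n_repeats, step_ms, bin_ms,
                            seed = mix_seed(seed, 42))
  structure(list(model = model, target_models = tm, predictions = pred,
                 widths_ms = widths_ms, n_repeats = n_repeats,
                 method = method, seed = seed),
            class = "decode_report")
}

#' @export
print.decode_report <- function(x, ...) {
  cat(sprintf("<decode_report> %d predictions, widths: %s ms (%s training)\n",
              nrow(x$predictions), paste(x$widths_ms, collapse = ", "),
              x$method))
  for (w in x$widths_ms) {
    p <- x$predictions[x$predictions$width_ms == w, ]
    cat(sprintf("  width %3d ms: epoch accuracy %.3f, target accuracy %.3f\n",
                w, mean(p$pred_epoch == p$true_epoch),
                mean(p$pred_target == p$true_target)))
  }
  invisible(x)
}

#' Consistency analysis on a spike dataset
#'
#' Generates movement-onset-aligned emission sequences (1,000 ms before to
#' 1,000 ms after), splits them by reach target with a held-out trial per
#' target, and runs [consistency_analysis()] over the candidate state
#' counts.  One model per target is trained for each candidate `K`.
#'
#' @param data A `spike_dataset`.
#' @param fold A `list(train, validation)` of trial ids.
#' @param K_range Candidate state counts (default `2:7`).
#' @param n_repeats Sequences per trial.
#' @param bin_ms Bin width (ms).
#' @param threshold State-probability threshold (default 0.7).
#' @param select_frac Selection fraction (default 0.9).
#' @param max_iter,tol,n_restarts Training controls.
#' @param seed Integer seed.
#' @return A `consistency_report`.
#' @export
run_consistency <- function(data, fold, K_range = 2:7, n_repeats = 100,
                            bin_ms = 2, threshold = 0.7, select_frac = 0.9,
                            max_iter = 500, tol = 1e-6, n_restarts = 1,
                            seed = 1) {
  stopifnot(inherits(data, "spike_dataset"))
  win <- c(-1000, 1000)
  split_seqs <- function(ids, seed_off) {
    lapply(1:9, function(t) {
      tid <- intersect(ids, data$trials$trial_id[data$trials$target_id == t])
      bc <- align_and_bin(data, "movement_onset", win, bin_ms, trial_ids = tid)
      symbolize(bc, n_repeats, seed = mix_seed(seed, seed_off, t))
    })
  }
  train_groups <- split_seqs(fold$train, 51)
  test_groups <- split_seqs(fold$validation, 52)
  consistency_analysis(train_groups, test_groups,
                       n_symbols = data$n_units + 1L, K_range = K_range,
                       threshold = threshold, select_frac = select_frac,
                       max_iter = max_iter, tol = tol,
                       n_restarts = n_restarts, seed = mix_seed(seed, 53))
}
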