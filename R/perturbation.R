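#' Remove units from a dataset (neuron loss)
#'
#' Deletes the spikes of the given units.  With `reindex = FALSE` (the
#' convention for perturbation experiments without retraining) the remaining
#' units keep their original ids, so a trained model's symbol alphabet still
#' applies and the removed units' symbols simply never occur.  With
#' `reindex = TRUE` the kept units are renumbered 1..k (for retraining on a
#' subpopulation).
#'
#' @param data A `spike_dataset`.
#' @param units Unit ids to remove (or, if `reindex`, to keep -- see
#'   `keep`).
#' @param keep Interpret `units` as the set to keep instead of remove.
#' @param reindex Renumber kept units contiguously.
#' @return A `spike_dataset`.
#' @export
drop_units <- function(data, units, keep = FALSE, reindex = FALSE) {
  stopifnot(inherits(data, "spike_dataset"))
  kept <- if (keep) sort(units) else setdiff(seq_len(data$n_units), units)
  sp <- data$spikes[data$spikes$unit_id %in% kept, , drop = FALSE]
  n_units <- data$n_units
  pop <- data$population
  if (reindex) {
    sp$unit_id <- match(sp$unit_id, kept)
    n_units <- length(kept)
    if (!is.null(pop)) {
      pop$baseline_rate <- pop$baseline_rate[kept]
      pop$epoch_gain <- pop$epoch_gain[kept, , drop = FALSE]
      pop$target_tuning <- pop$target_tuning[kept, , drop = FALSE]
      pop$n_units <- n_units
    }
  }
  rownames(sp) <- NULL
  new_spike_dataset(sp, data$trials, n_units, area = data$area,
                    population = if (reindex) pop else data$population)
}

#' Shuffle the spikes of selected units (noise injection)
#'
#' For every (unit, trial) with at least 3 spikes, the first and last spike
#' times are kept and the interior spikes are replaced: `method = "uniform"`
#' redraws them uniformly between the first and last spike (count
#' preserved); `method = "isi"` permutes the inter-spike intervals instead.
#' Unit-trials with fewer than 3 spikes are left unchanged.
#'
#' @param data A `spike_dataset`.
#' @param units Units to perturb.
#' @param seed Integer seed.
#' @param method `"uniform"` (default) or `"isi"`.
#' @return A `spike_dataset` with identical spike counts per (unit, trial).
#' @export
shuffle_unit_spikes <- function(data, units, seed = 1,
                                method = c("uniform", "isi")) {
  method <- match.arg(method)
  stopifnot(inherits(data, "spike_dataset"))
  sp <- data$spikes
  sel <- sp$unit_id %in% units
  if (any(sel)) {
    idx <- which(sel)
    grp <- interaction(sp$unit_id[idx], sp$trial_id[idx], drop = TRUE)
    for (g in split(idx, grp)) {
      if (length(g) < 3) next
      tt <- sp$time_ms[g]
      set.seed(mix_seed(seed, 1102, sp$unit_id[g[1]], sp$trial_id[g[1]]))
      inner <- if (method == "uniform") {
        sort(runif(length(g) - 2, tt[1], tt[length(g)]))
      } else {
        tt[1] + cumsum(sample(diff(tt)))[-(length(g) - 1)]
      }
      sp$time_ms[g] <- c(tt[1], round(inner, 1), tt[length(g)])
    }
  }
  new_spike_dataset(sp, data$trials, data$n_units, area = data$area,
                    population = data$population)
}

# Epoch/target accuracy of a prediction table.
prediction_accuracy <- function(pred) {
  c(epoch = mean(pred$pred_epoch == pred$true_epoch),
    target = mean(pred$pred_target == pred$true_target))
}

# Train the three decoder families once on a fold (shared by the
# perturbation experiments).  `algorithms` is a subset of
# c("hmm", "svm", "lstm"); `opts` carries per-algorithm settings.
train_decoder_suite <- function(data, fold, algorithms, opts, seed) {
  suite <- list()
  if ("hmm" %in% algorithms) {
    o <- opts$hmm %||% list()
    tm <- train_target_models(data, fold$train,
                              n_repeats = o$n_repeats %||% 20,
                              bin_ms = o$bin_ms %||% 2,
                              method = o$method %||% "baum_welch",
                              max_iter = o$max_iter %||% 100,
                              tol = o$tol %||% 1e-6,
                              seed = mix_seed(seed, 61))
    suite$hmm <- list(model = merge_boosted(tm),
                      n_repeats = o$n_repeats %||% 20,
                      step_ms = o$step_ms %||% 10,
                      bin_ms = o$bin_ms %||% 2)
  }
  if ("svm" %in% algorithms) {
    o <- opts$svm %||% list()
    fw <- firing_rate_features(data, fold$train, width_ms = 200,
                               step_ms = o$step_ms %||% 10)
    grid <- o$grid %||% data.frame(kernel = "polynomial", degree = 2L,
                                   cost = 100)
    suite$svm <- list(fit = svm_fit(fw$features, fw$meta$class, grid = grid,
                                    cv = o$cv %||% 3,
                                    seed = mix_seed(seed, 62)),
                      step_ms = o$step_ms %||% 10)
  }
  if ("lstm" %in% algorithms) {
    o <- opts$lstm %||% list()
    val_ids <- fold$train[seq_len(min(9, length(fold$train)))]
    train_ids <- setdiff(fold$train, val_ids)
    lw <- lstm_windows(data, train_ids, width_ms = 200,
                       step_ms = o$step_ms %||% 50)
    lv <- lstm_windows(data, val_ids, width_ms = 200,
                       step_ms = o$step_ms %||% 50)
    suite$lstm <- list(fit = lstm_fit(lw$x, lw$meta$class, n_classes = 28,
                                      val_x = lv$x, val_y = lv$meta$class,
                                      n_hidden = o$n_hidden %||% 32,
                                      lr = o$lr %||% 1e-2,
                                      batch_size = o$batch_size %||% 256,
                                      dropout = o$dropout %||% 0.1,
                                      n_steps = o$n_steps %||% 120,
                                      seed = mix_seed(seed, 63)),
                       step_ms = o$step_ms %||% 50)
  }
  suite
}

state_labels_for <- function(class_ids) {
  lab <- boosted_state_labels()
  data.frame(pred_epoch = lab$epoch[class_ids],
             pred_target = lab$target[class_ids])
}

# Decode the validation trials of a (possibly perturbed) dataset with a
# pretrained suite; `zero_units` lists units whose SVM features / LSTM
# input rows are forced to 0 (the removed-unit convention).
evaluate_decoder_suite <- function(suite, data, val_ids, zero_units = NULL,
                                   seed = 1) {
  out <- list()
  if (!is.null(suite$hmm)) {
    s <- suite$hmm
    pred <- decode_with_model(s$model, data, val_ids, widths_ms = 200,
                              n_repeats = s$n_repeats, step_ms = s$step_ms,
                              bin_ms = s$bin_ms, seed = mix_seed(seed, 71))
    out$hmm <- prediction_accuracy(pred)
  }
  if (!is.null(suite$svm)) {
    s <- suite$svm
    fw <- firing_rate_features(data, val_ids, width_ms = 200,
                               step_ms = s$step_ms)
    if (length(zero_units)) fw$features[, zero_units] <- 0
    cls <- predict(s$fit, fw$features)
    pred <- cbind(state_labels_for(cls),
                  fw$meta[, c("true_epoch", "true_target")])
    out$svm <- prediction_accuracy(pred)
  }
  if (!is.null(suite$lstm)) {
    s <- suite$lstm
    lw <- lstm_windows(data, val_ids, width_ms = 200, step_ms = s$step_ms)
    if (length(zero_units)) lw$x[zero_units, , ] <- 0
    cls <- predict(s$fit, lw$x)
    pred <- cbind(state_labels_for(cls),
                  lw$meta[, c("true_epoch", "true_target")])
    out$lstm <- prediction_accuracy(pred)
  }
  out
}

suite_rows <- function(accs, k, boot) {
  do.call(rbind, lapply(names(accs), function(alg)
    data.frame(algorithm = alg, label_type = c("epoch", "target"), k = k,
               boot = boot, accuracy = unname(accs[[alg]]))))
}

#' Decoder robustness to neuron loss (no retraining)
#'
#' Trains the requested decoders once on the fold's training trials, then
#' removes increasing numbers of randomly chosen units from the validation
#' data and decodes without retraining.  For the HMM (and LSTM inputs) new
#' emission sequences/windows are generated without the removed units; for
#' the SVM the removed units' firing-rate features are set to 0.  Within a
#' bootstrap the removal sets are nested (a random unit order is drawn once
#' and level `k` removes its first `k` units), so each bootstrap traces a
#' degradation curve for one loss trajectory.
#'
#' @param data A `spike_dataset`.
#' @param fold `list(train, validation)` of trial ids.
#' @param ks Numbers of units to remove (default `c(2, 4, 8, 16, 32, 64)`);
#'   levels `>= n_units` are skipped with a message.  Level 0 (unperturbed)
#'   is always included.
#' @param n_boot Bootstrap repetitions (default 25).
#' @param algorithms Subset of `c("hmm", "svm", "lstm")`.
#' @param opts Per-algorithm option lists (see package vignette).
#' @param seed Integer seed.
#' @return `data.frame(algorithm, label_type, k, boot, accuracy)`.
#' @export
neuron_loss <- function(data, fold, ks = c(2, 4, 8, 16, 32, 64),
                        n_boot = 25, algorithms = "hmm", opts = list(),
                        seed = 1) {
  skip <- ks[ks >= data$n_units]
  if (length(skip))
    message("skipping removal level(s) >= population size: ",
            paste(skip, collapse = ", "))
  ks <- ks[ks < data$n_units]
  suite <- train_decoder_suite(data, fold, algorithms, opts, seed)
  base <- evaluate_decoder_suite(suite, data, fold$validation,
                                 seed = mix_seed(seed, 81))
  rows <- lapply(seq_len(n_boot), function(b) {
    set.seed(mix_seed(seed, 82, b))
    perm <- sample.int(data$n_units)
    boot_rows <- lapply(ks, function(k) {
      removed <- perm[seq_len(k)]
      pert <- drop_units(data, removed)
      accs <- evaluate_decoder_suite(suite, pert, fold$validation,
                                     zero_units = removed,
                                     seed = mix_seed(seed, 81))
      suite_rows(accs, k, b)
    })
    do.call(rbind, boot_rows)
  })
  rbind(suite_rows(base, 0L, 0L), do.call(rbind, rows))
}

#' Decoder robustness to spike-shuffling noise (no retraining)
#'
#' As [neuron_loss()], but instead of removing units their spike trains are
#' degraded with [shuffle_unit_spikes()] (first/last spikes kept, interior
#' redrawn), and new sequences/features are generated from the noisy data.
#'
#' @inheritParams neuron_loss
#' @param ks Numbers of noisy units per level.
#' @param n_boot Bootstrap repetitions (default 10).
#' @param method Passed to [shuffle_unit_spikes()].
#' @return `data.frame(algorithm, label_type, k, boot, accuracy)`.
#' @export
noise_injection <- function(data, fold, ks = c(2, 4, 8, 16, 32, 64),
                            n_boot = 10, algorithms = "hmm", opts = list(),
                            method = "uniform", seed = 1) {
  ks <- ks[ks <= data$n_units]
  suite <- train_decoder_suite(data, fold, algorithms, opts, seed)
  base <- evaluate_decoder_suite(suite, data, fold$validation,
                                 seed = mix_seed(seed, 91))
  rows <- lapply(seq_len(n_boot), function(b) {
    set.seed(mix_seed(seed, 92, b))
    perm <- sample.int(data$n_units)
    boot_rows <- lapply(ks, function(k) {
      noisy <- shuffle_unit_spikes(data, perm[seq_len(k)],
                                   seed = mix_seed(seed, 93, b),
                                   method = method)
      accs <- evaluate_decoder_suite(suite, noisy, fold$validation,
                                     seed = mix_seed(seed, 91))
      suite_rows(accs, k, b)
    })
    do.call(rbind, boot_rows)
  })
  rbind(suite_rows(base, 0L, 0L), do.call(rbind, rows))
}

#' Decoding accuracy as a function of population size (with retraining)
#'
#' Randomly subsamples the population in `step`-unit increments, retrains
#' the decoder on each subset, and reports accuracy per size, plus the
#' minimum size whose mean accuracy exceeds 0.5.
#'
#' @param data A `spike_dataset`.
#' @param fold `list(train, validation)` of trial ids.
#' @param sizes Population sizes (default `seq(step, n_units, by = step)`,
#'   always including the full population).
#' @param step Size increment (default 5).
#' @param n_repeats_boot Random subsets per size (default 10).
#' @param algorithms Subset of `c("hmm", "svm", "lstm")`.
#' @param opts Per-algorithm options.
#' @param seed Integer seed.
#' @return A list: `curve`
#'   (`data.frame(algorithm, label_type, size, boot, accuracy)`) and
#'   `min_units` (per algorithm/label type, smallest size with mean
#'   accuracy > 0.5, `NA` if never reached).
#' @export
subsample_curve <- function(data, fold, sizes = NULL, step = 5,
                            n_repeats_boot = 10, algorithms = "hmm",
                            opts = list(), seed = 1) {
  N <- data$n_units
  if (is.null(sizes)) sizes <- unique(c(seq(step, N, by = step), N))
  rows <- lapply(sizes, function(s) {
    per_boot <- lapply(seq_len(n_repeats_boot), function(b) {
      set.seed(mix_seed(seed, 1201, s, b))
      kept <- sort(sample.int(N, s))
      sub <- drop_units(data, kept, keep = TRUE, reindex = TRUE)
      suite <- train_decoder_suite(sub, fold, algorithms, opts,
                                   seed = mix_seed(seed, 1202, s, b))
      accs <- evaluate_decoder_suite(suite, sub, fold$validation,
                                     seed = mix_seed(seed, 1203, s, b))
      df <- suite_rows(accs, NA_integer_, b)
      df$size <- s
      df
    })
    do.call(rbind, per_boot)
  })
  curve <- do.call(rbind, rows)
  curve$k <- NULL
  agg <- stats::aggregate(accuracy ~ algorithm + label_type + size,
                          data = curve, FUN = mean)
  min_units <- do.call(rbind, lapply(
    split(agg, list(agg$algorithm, agg$label_type), drop = TRUE),
    function(d) data.frame(algorithm = d$algorithm[1],
                           label_type = d$label_type[1],
                           min_units = if (any(d$accuracy > 0.5))
                             min(d$size[d$accuracy > 0.5]) else NA_integer_)))
  rownames(min_units) <- NULL
  list(curve = curve, min_units = min_units)
}

#' Time course of target decoding accuracy
#'
#' Decodes 200-ms windows sliding (10-ms steps by default) over the
#' movement-centred segment and reports target accuracy per window
#' position.  The FREE period carries no target information by construction
#' and is excluded.
#'
#' @param model A boosted `hmm_params`.
#' @param data A `spike_dataset`.
#' @param trial_ids Validation trial ids.
#' @param width_ms,step_ms Window width and step (ms).
#' @param n_repeats Sequences per trial.
#' @param bin_ms Bin width (ms).
#' @param seed Integer seed.
#' @return `data.frame(time_ms, accuracy, n)` where `time_ms` is the window
#'   midpoint relative to movement onset.
#' @export
decode_timecourse <- function(model, data, trial_ids, width_ms = 200,
                              step_ms = 10, n_repeats = 20, bin_ms = 2,
                              seed = 1) {
  bc <- align_and_bin(data, "movement_onset", c(-1000, 1000), bin_ms,
                      trial_ids)
  seqs <- symbolize(bc, n_repeats, seed = mix_seed(seed, 1301))
  pred <- decode_windows(model, seqs, width_ms, step_ms)
  pred <- assign_true_labels(pred, seqs, data$trials)
  pred$time_ms <- -1000 + pred$midpoint_u_ms
  ok <- pred$pred_target == pred$true_target
  agg <- stats::aggregate(list(accuracy = ok),
                          by = list(time_ms = pred$time_ms), FUN = mean)
  agg$n <- stats::aggregate(list(n = ok),
                            by = list(time_ms = pred$time_ms),
                            FUN = length)$n
  agg
}
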