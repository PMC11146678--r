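#' State labels of the 28-state boosted decoder
#'
#' State 1 is the shared FREE state (no target); states `2..28` are nine
#' target-specific blocks of DELAY, MOVE, HOLD.
#'
#' @return `data.frame(state, epoch, target)` with `target = 0` for FREE.
#' @export
boosted_state_labels <- function() {
  data.frame(state = 1:28,
             epoch = c("FREE", rep(c("DELAY", "MOVE", "HOLD"), 9)),
             target = c(0L, rep(1:9, each = 3)))
}

# Per-bin epoch labels of an aligned window, by bin midpoint, for the
# supervised training variants.
window_epoch_labels <- function(trial_row, event, window, bin_ms) {
  n_bins <- as.integer(round((window[2] - window[1]) / bin_ms))
  ev <- trial_row[[paste0(event, "_ms")]]
  mids <- ev + window[1] + (seq_len(n_bins) - 0.5) * bin_ms
  eb <- epoch_bounds(trial_row)
  lab <- character(n_bins)
  for (e in seq_len(4))
    lab[mids >= eb$start_ms[e] & mids < eb$end_ms[e]] <- eb$epoch[e]
  lab
}

#' Train the per-target component models of the boosted decoder
#'
#' Fits, for each of the nine targets, a two-state HMM on sequences spanning
#' 500 ms before to 500 ms after target onset (FREE/DELAY) and a three-state
#' HMM on sequences spanning 1,000 ms before to 1,000 ms after movement onset
#' (DELAY/MOVE/HOLD).  `method = "baum_welch"` trains unsupervised from
#' pseudo-random feedforward initializations; `method = "supervised"`
#' estimates parameters directly from the epoch labels of each bin.
#'
#' @param data A `spike_dataset`.
#' @param train_ids Trial ids to train on (each target needs >= 1).
#' @param n_repeats Emission sequences per trial (default 100).
#' @param bin_ms Bin width (default 2 ms).
#' @param method `"baum_welch"` or `"supervised"`.
#' @param max_iter,tol,emission_floor,n_restarts Passed to [baum_welch()].
#' @param seed Integer seed.
#' @return A list of class `target_models`: `two` and `three` (lists of nine
#'   `hmm_params`), plus the windows used.
#' @export
train_target_models <- function(data, train_ids, n_repeats = 100, bin_ms = 2,
                                method = c("baum_welch", "supervised"),
                                max_iter = 500, tol = 1e-6,
                                emission_floor = 1e-6, n_restarts = 1,
                                seed = 1) {
  method <- match.arg(method)
  stopifnot(inherits(data, "spike_dataset"))
  M <- data$n_units + 1L
  trials <- data$trials[data$trials$trial_id %in% train_ids, ]
  two <- vector("list", 9)
  three <- vector("list", 9)
  win2 <- c(-500, 500)
  win3 <- c(-1000, 1000)
  for (t in 1:9) {
    ids <- trials$trial_id[trials$target_id == t]
    if (!length(ids)) stopf("no training trials for target %d", t)
    bc2 <- align_and_bin(data, "target_on", win2, bin_ms, trial_ids = ids)
    sq2 <- symbolize(bc2, n_repeats, seed = mix_seed(seed, 21, t))
    bc3 <- align_and_bin(data, "movement_onset", win3, bin_ms,
                         trial_ids = ids)
    sq3 <- symbolize(bc3, n_repeats, seed = mix_seed(seed, 22, t))
    if (method == "baum_welch") {
      two[[t]] <- baum_welch(
        init_feedforward(2, M, mix_seed(seed, 23, t), empirical_from = sq2),
        sq2, max_iter, tol, emission_floor, n_restarts = n_restarts,
        restart_seed = mix_seed(seed, 25, t))$params
      three[[t]] <- baum_welch(
        init_feedforward(3, M, mix_seed(seed, 24, t), empirical_from = sq3),
        sq3, max_iter, tol, emission_floor, n_restarts = n_restarts,
        restart_seed = mix_seed(seed, 26, t))$params
    } else {
      tr_rows <- lapply(ids, function(id)
        trials[trials$trial_id == id, , drop = FALSE])
      lab2 <- lapply(tr_rows, window_epoch_labels, event = "target_on",
                     window = win2, bin_ms = bin_ms)
      lab3 <- lapply(tr_rows, window_epoch_labels, event = "movement_onset",
                     window = win3, bin_ms = bin_ms)
      two[[t]] <- supervised_fit(sq2, lab2, epochs = c("FREE", "DELAY"),
                                 emission_floor = emission_floor)
      three[[t]] <- supervised_fit(sq3, lab3,
                                   epochs = c("DELAY", "MOVE", "HOLD"),
                                   emission_floor = emission_floor)
    }
  }
  structure(list(two = two, three = three, method = method,
                 window_two = win2, window_three = win3, bin_ms = bin_ms),
            class = "target_models")
}

#' Merge per-target models into the 28-state boosted HMM
#'
#' The shared FREE state's emission row is the mean of the nine two-state
#' models' first-state emission rows and its self-transition the mean of
#' their first-state self-transitions; the remaining FREE mass is split
#' equally over the nine target-specific DELAY states.  The nine three-state
#' models form a block-diagonal structure (DELAY/MOVE/HOLD per target) with
#' no transitions between targets; each HOLD state is absorbing.  Rows are
#' renormalized and the chain starts in FREE.
#'
#' @param models A `target_models` object, or `list(two = ..., three = ...)`
#'   of nine 2-state and nine 3-state `hmm_params`.
#' @return An `hmm_params` with `K = 28` and boosted `state_labels`.
#' @export
merge_boosted <- function(models) {
  two <- lapply(models$two, function(m) if (inherits(m, "hmm_fit")) m$params else m)
  three <- lapply(models$three, function(m) if (inherits(m, "hmm_fit")) m$params else m)
  stopifnot(length(two) == 9, length(three) == 9)
  Ms <- vapply(c(two, three), function(m) m$M, numeric(1))
  if (length(unique(Ms)) != 1)
    stopf("symbol-count mismatch across component models")
  M <- Ms[1]
  K <- 28L
  A <- matrix(0, K, K)
  B <- matrix(0, K, M)
  mask <- matrix(FALSE, K, K)

  free_self <- mean(vapply(two, function(m) m$A[1, 1], numeric(1)))
  delay_states <- 2L + 3L * (0:8)
  A[1, 1] <- free_self
  A[1, delay_states] <- (1 - free_self) / 9
  mask[1, 1] <- TRUE
  mask[1, delay_states] <- TRUE
  B[1, ] <- colMeans(do.call(rbind, lapply(two, function(m) m$B[1, ])))

  for (t in 1:9) {
    idx <- (2L + 3L * (t - 1L)):(4L + 3L * (t - 1L))
    A[idx, idx] <- three[[t]]$A
    mask[idx, idx] <- three[[t]]$mask
    B[idx, ] <- three[[t]]$B
  }
  A <- A / rowSums(A)
  B <- B / rowSums(B)
  hmm_params(pi = c(1, rep(0, K - 1)), A = A, B = B, mask = mask,
             state_labels = boosted_state_labels())
}

#' Build concatenated decoding sequences for a set of trials
#'
#' Emission sequences over the last 500 ms of the FREE epoch (aligned to
#' target onset) concatenated with sequences spanning 1,000 ms before to
#' 1,000 ms after movement onset, as used for decoding.
#'
#' @param data A `spike_dataset`.
#' @param trial_ids Trials to include.
#' @param n_repeats Sequences per trial.
#' @param bin_ms Bin width (ms).
#' @param seed Integer seed.
#' @return An `emission_seqs` with a recorded `seam_bin`.
#' @export
build_decode_sequences <- function(data, trial_ids, n_repeats = 100,
                                   bin_ms = 2, seed = 1) {
  bc_free <- align_and_bin(data, "target_on", c(-500, 0), bin_ms, trial_ids)
  sq_free <- symbolize(bc_free, n_repeats, seed = mix_seed(seed, 31))
  bc_move <- align_and_bin(data, "movement_onset", c(-1000, 1000), bin_ms,
                           trial_ids)
  sq_move <- symbolize(bc_move, n_repeats, seed = mix_seed(seed, 32))
  concat_segments(sq_free, sq_move)
}

# 0-based window starts for a sliding decode; windows never straddle the
# concatenation seam (a real temporal discontinuity).
decode_window_starts <- function(n_bins, width_bins, step_bins,
                                 seam_bin = NULL) {
  starts <- seq(0L, n_bins - width_bins, by = step_bins)
  if (!is.null(seam_bin) && seam_bin > 0 && seam_bin < n_bins)
    starts <- starts[!(starts < seam_bin & starts + width_bins > seam_bin)]
  as.integer(starts)
}

# Map a position (ms) on the concatenated decode axis to trial time (ms).
concat_to_trial_time <- function(u_ms, trial_row, seqs) {
  if (is.null(seqs$seam_bin) || !length(seqs$seam_bin) || seqs$seam_bin == 0) {
    ev <- trial_row[[paste0(seqs$event, "_ms")]]
    return(ev + seqs$window[1] + u_ms)
  }
  seam_ms <- seqs$seam_bin * seqs$bin_ms
  ev1 <- trial_row[[paste0(seqs$event[1], "_ms")]]
  ev2 <- trial_row[[paste0(seqs$event[2], "_ms")]]
  ifelse(u_ms < seam_ms,
         ev1 + seqs$window$first[1] + u_ms,
         ev2 + seqs$window$second[1] + (u_ms - seam_ms))
}

#' Decode sliding windows with a boosted HMM
#'
#' Slides windows of `width_ms` (step `step_ms`) over each emission sequence;
#' each fragment is decoded independently by forward-backward with the chain
#' restarted in FREE, the posteriors are averaged over the fragment's bins,
#' and the state with the highest average is the prediction (ties broken by
#' the earliest state in chain order).  Windows straddling the concatenation
#' seam are dropped.
#'
#' @param model An `hmm_params`, typically from [merge_boosted()].
#' @param seqs An `emission_seqs` (e.g. [build_decode_sequences()]).
#' @param width_ms Window width in ms; must be divisible by the bin width.
#' @param step_ms Window step in ms (default 10).
#' @return A `data.frame` with one row per (trial, repeat, window):
#'   `trial_id`, `rep`, `start_bin` (0-based), `midpoint_u_ms` (window
#'   midpoint on the concatenated axis), `pred_state`, and, when the model
#'   carries state labels, `pred_epoch` / `pred_target`.
#' @export
decode_windows <- function(model, seqs, width_ms, step_ms = 10) {
  stopifnot(inherits(model, "hmm_params"), inherits(seqs, "emission_seqs"))
  width_bins <- width_ms / seqs$bin_ms
  step_bins <- step_ms / seqs$bin_ms
  if (width_bins != round(width_bins) || step_bins != round(step_bins))
    stopf("width and step must be divisible by the bin width")
  width_bins <- as.integer(width_bins)
  out <- vector("list", length(seqs$seqs))
  for (i in seq_along(seqs$seqs)) {
    m <- seqs$seqs[[i]]
    starts <- decode_window_starts(ncol(m), width_bins,
                                   as.integer(step_bins), seqs$seam_bin)
    if (!length(starts)) next
    per_rep <- vector("list", nrow(m))
    for (r in seq_len(nrow(m))) {
      post <- rs_window_posteriors(model$pi, model$A, model$B, model$mask,
                                   m[r, ], starts, width_bins)
      per_rep[[r]] <- data.frame(
        trial_id = seqs$trial_ids[i], rep = r, start_bin = starts,
        midpoint_u_ms = (starts + width_bins / 2) * seqs$bin_ms,
        pred_state = max.col(post, ties.method = "first"))
    }
    out[[i]] <- do.call(rbind, per_rep)
  }
  res <- do.call(rbind, out)
  if (!is.null(model$state_labels) && !is.null(res)) {
    res$pred_epoch <- model$state_labels$epoch[res$pred_state]
    if ("target" %in% names(model$state_labels))
      res$pred_target <- model$state_labels$target[res$pred_state]
  }
  res
}

#' Assign true (epoch, target) labels to decoded windows
#'
#' A window's true epoch is the epoch containing its midpoint in that trial's
#' own event timeline (boundaries are half-open, so a midpoint exactly on a
#' boundary belongs to the later epoch: movement onset belongs to MOVE).  The
#' true target is the trial's target, or 0 (none) for FREE windows.
#'
#' @param windows A `data.frame` from [decode_windows()].
#' @param seqs The `emission_seqs` the windows were decoded from.
#' @param trials The trial table.
#' @return `windows` with `true_epoch` and `true_target` columns appended.
#' @export
assign_true_labels <- function(windows, seqs, trials) {
  validate_trial_table(trials)
  key <- paste(windows$trial_id, windows$midpoint_u_ms)
  uniq <- which(!duplicated(key))
  u_epoch <- character(length(uniq))
  u_target <- integer(length(uniq))
  tr_by_id <- split(trials, trials$trial_id)
  for (j in seq_along(uniq)) {
    i <- uniq[j]
    tr <- tr_by_id[[as.character(windows$trial_id[i])]]
    tt <- concat_to_trial_time(windows$midpoint_u_ms[i], tr, seqs)
    eb <- epoch_bounds(tr)
    hit <- which(tt >= eb$start_ms & tt < eb$end_ms)
    if (!length(hit))
      stopf("window midpoint (%.1f ms) outside trial %d", tt, tr$trial_id)
    u_epoch[j] <- eb$epoch[hit]
    u_target[j] <- if (eb$epoch[hit] == "FREE") 0L else tr$target_id
  }
  idx <- match(key, key[uniq])
  windows$true_epoch <- u_epoch[idx]
  windows$true_target <- u_target[idx]
  windows
}
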