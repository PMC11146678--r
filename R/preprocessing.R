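#' Align spike trains to an event and bin them
#'
#' Counts spikes in half-open bins `[event + start + (b-1) * bin_ms,
#' event + start + b * bin_ms)` (bins numbered from 1) for every trial.
#'
#' @param data A `spike_dataset`.
#' @param event Alignment event: one of `"home_press"`, `"target_on"`,
#'   `"go"`, `"movement_onset"`, `"touch"`, `"target_off"`.
#' @param window Numeric `c(start, end)` in ms relative to the event; the
#'   width must be divisible by `bin_ms`.
#' @param bin_ms Bin width in ms (default 2).
#' @param trial_ids Optional subset of trials (default all).
#' @return An object of class `binned_counts`: per-trial `units x bins` count
#'   matrices plus alignment metadata.
#' @export
align_and_bin <- function(data, event, window, bin_ms = 2, trial_ids = NULL) {
  stopifnot(inherits(data, "spike_dataset"))
  col <- paste0(event, "_ms")
  if (!col %in% names(data$trials))
    stopf("unknown alignment event `%s`", event)
  width <- window[2] - window[1]
  n_bins <- width / bin_ms
  if (abs(n_bins - round(n_bins)) > 1e-9)
    stopf("window width (%g ms) must be divisible by bin_ms (%g ms)",
          width, bin_ms)
  n_bins <- as.integer(round(n_bins))
  trials <- data$trials
  if (!is.null(trial_ids)) trials <- trials[trials$trial_id %in% trial_ids, ]
  U <- data$n_units
  sp_by_trial <- split(data$spikes[, c("unit_id", "time_ms")],
                       factor(data$spikes$trial_id, levels = trials$trial_id))
  counts <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    sp <- sp_by_trial[[i]]
    m <- matrix(0L, U, n_bins)
    if (!is.null(sp) && nrow(sp)) {
      u <- (sp$time_ms - trials[[col]][i] - window[1]) / bin_ms
      b <- floor(u + 1e-9) + 1L
      keep <- b >= 1L & b <= n_bins & u < n_bins - 1e-9
      if (any(keep)) {
        idx <- (b[keep] - 1L) * U + sp$unit_id[keep]
        tab <- tabulate(idx, nbins = U * n_bins)
        m <- matrix(as.integer(tab), U, n_bins)
      }
    }
    counts[[i]] <- m
  }
  structure(list(counts = counts, trial_ids = trials$trial_id,
                 target_ids = trials$target_id, n_units = U, event = event,
                 window = window, bin_ms = bin_ms, n_bins = n_bins),
            class = "binned_counts")
}

#' Convert binned counts to single-symbol emission sequences
#'
#' Each 2-ms bin is replaced by one symbol: 0 when all units are silent, the
#' firing unit's number when exactly one unit is active, and a uniformly
#' random choice among the active units otherwise.  A unit firing twice in a
#' bin emits its symbol once (symbols carry identity, not count).  The random
#' tie-break makes the sequence stochastic, so `n_repeats` independent
#' sequences per trial (default 100) jointly retain the population
#' information.
#'
#' @param counts A [align_and_bin()] result.
#' @param n_repeats Sequences per trial (default 100).
#' @param seed Integer seed; deterministic per trial substream.
#' @return An object of class `emission_seqs`: per-trial `n_repeats x bins`
#'   integer matrices of symbols in `0..n_units`.
#' @export
symbolize <- function(counts, n_repeats = 100, seed = 1) {
  stopifnot(inherits(counts, "binned_counts"))
  n_repeats <- check_count(n_repeats, "n_repeats")
  seqs <- vector("list", length(counts$counts))
  for (i in seq_along(counts$counts)) {
    m <- counts$counts[[i]]
    B <- ncol(m)
    act <- m > 0L
    nact <- colSums(act)
    base <- integer(B)
    single <- which(nact == 1L)
    if (length(single))
      base[single] <- apply(act[, single, drop = FALSE], 2, which)
    S <- matrix(rep(base, each = n_repeats), nrow = n_repeats)
    multi <- which(nact > 1L)
    if (length(multi)) {
      set.seed(mix_seed(seed, 404, counts$trial_ids[i]))
      for (b in multi) {
        u <- which(act[, b])
        S[, b] <- u[sample.int(length(u), n_repeats, replace = TRUE)]
      }
    }
    seqs[[i]] <- S
  }
  structure(list(seqs = seqs, trial_ids = counts$trial_ids,
                 target_ids = counts$target_ids, n_units = counts$n_units,
                 n_symbols = counts$n_units + 1L, bin_ms = counts$bin_ms,
                 event = counts$event, window = counts$window,
                 n_repeats = n_repeats, seam_bin = NULL),
            class = "emission_seqs")
}

#' Concatenate two emission-sequence sets trial by trial
#'
#' Repeat `r` of the output is repeat `r` of the first segment followed by
#' repeat `r` of the second, e.g. a pre-cue segment followed by a
#' movement-centred segment.  The seam position is recorded so that
#' downstream sliding windows can avoid straddling the temporal
#' discontinuity.
#'
#' @param a,b `emission_seqs` over the same trials, repeats and bin width.
#' @return An `emission_seqs` whose sequences have `ncol(a) + ncol(b)` bins
#'   and whose `seam_bin` is the length of the first segment.
#' @export
concat_segments <- function(a, b) {
  stopifnot(inherits(a, "emission_seqs"), inherits(b, "emission_seqs"))
  if (!identical(a$trial_ids, b$trial_ids))
    stopf("segments cover different trials")
  if (a$n_repeats != b$n_repeats)
    stopf("repeat-count mismatch (%d vs %d)", a$n_repeats, b$n_repeats)
  if (a$bin_ms != b$bin_ms) stopf("bin width mismatch")
  if (a$n_units != b$n_units) stopf("unit-count mismatch")
  seqs <- Map(cbind, a$seqs, b$seqs)
  structure(list(seqs = seqs, trial_ids = a$trial_ids,
                 target_ids = a$target_ids, n_units = a$n_units,
                 n_symbols = a$n_symbols, bin_ms = a$bin_ms,
                 event = c(a$event, b$event),
                 window = list(first = a$window, second = b$window),
                 n_repeats = a$n_repeats,
                 seam_bin = if (length(a$seqs)) ncol(a$seqs[[1]]) else 0L),
            class = "emission_seqs")
}

#' Leave-one-trial-per-target-out cross-validation folds
#'
#' With `n` trials per target, fold `k` holds out the `k`-th trial of every
#' target (ordered by trial id) and trains on the rest, giving `n` folds
#' whose validation sets partition the trials.
#'
#' @param trials A trial table.
#' @return A list of `n` folds, each `list(train = <trial ids>,
#'   validation = <trial ids>)`.
#' @export
make_cv_folds <- function(trials) {
  validate_trial_table(trials)
  by_target <- split(trials$trial_id, trials$target_id)
  sizes <- lengths(by_target)
  if (length(unique(sizes)) != 1)
    stopf("unequal trial counts per target: %s",
          paste(sizes, collapse = ", "))
  n <- sizes[[1]]
  by_target <- lapply(by_target, sort)
  lapply(seq_len(n), function(k) {
    val <- vapply(by_target, `[`, numeric(1), k)
    list(train = sort(setdiff(trials$trial_id, val)),
         validation = sort(unname(val)))
  })
}
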