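#' Map (epoch, target) labels to the 28-class state ids
#'
#' Class 1 is (FREE, none); classes `2..28` are the nine target blocks of
#' DELAY, MOVE, HOLD, matching [boosted_state_labels()].
#'
#' @param epoch Character vector of epochs.
#' @param target Integer vector of targets (0 = none).
#' @return Integer class ids in 1..28.
#' @export
label_to_state <- function(epoch, target) {
  out <- integer(length(epoch))
  free <- epoch == "FREE"
  out[free] <- 1L
  pos <- match(epoch[!free], c("DELAY", "MOVE", "HOLD"))
  out[!free] <- 1L + 3L * (target[!free] - 1L) + pos
  out
}

#' Mean firing-rate features over sliding windows
#'
#' For each trial, computes the per-unit mean firing rate (sp/s) in
#' partially overlapping windows over the same concatenated decoding axis
#' used by the boosted HMM (last 500 ms of FREE + 2,000 ms centred on
#' movement onset); windows straddling the seam are dropped.  These are the
#' SVM input vectors; [lstm_windows()] produces the binned counterpart.
#'
#' @param data A `spike_dataset`.
#' @param trial_ids Trials to include.
#' @param width_ms Window width (default 200 ms).
#' @param step_ms Window step (default 10 ms); must divide `width_ms`.
#' @return A list of class `feature_windows`: `features` (windows x units
#'   matrix of rates), `meta` (`trial_id`, `midpoint_u_ms`, `true_epoch`,
#'   `true_target`, `class`).
#' @export
firing_rate_features <- function(data, trial_ids, width_ms = 200,
                                 step_ms = 10) {
  if (width_ms %% step_ms != 0)
    stopf("width_ms must be divisible by step_ms")
  bc1 <- align_and_bin(data, "target_on", c(-500, 0), step_ms, trial_ids)
  bc2 <- align_and_bin(data, "movement_onset", c(-1000, 1000), step_ms,
                       trial_ids)
  seam_bin <- bc1$n_bins
  n_bins <- seam_bin + bc2$n_bins
  wb <- width_ms / step_ms
  starts <- decode_window_starts(n_bins, wb, 1L, seam_bin)
  U <- data$n_units
  feats <- vector("list", length(bc1$counts))
  meta <- vector("list", length(bc1$counts))
  for (i in seq_along(bc1$counts)) {
    m <- cbind(bc1$counts[[i]], bc2$counts[[i]])
    cs <- cbind(0, t(apply(m, 1, cumsum)))    # U x (n_bins + 1)
    rates <- t(cs[, starts + wb + 1, drop = FALSE] -
                 cs[, starts + 1, drop = FALSE]) / (width_ms / 1000)
    feats[[i]] <- rates
    meta[[i]] <- data.frame(trial_id = bc1$trial_ids[i],
                            midpoint_u_ms = (starts + wb / 2) * step_ms)
  }
  meta <- do.call(rbind, meta)
  seq_meta <- list(seam_bin = seam_bin, bin_ms = step_ms,
                   event = c("target_on", "movement_onset"),
                   window = list(first = c(-500, 0), second = c(-1000, 1000)))
  meta <- assign_true_labels(meta, seq_meta, data$trials)
  meta$class <- label_to_state(meta$true_epoch, meta$true_target)
  structure(list(features = do.call(rbind, feats), meta = meta,
                 width_ms = width_ms, step_ms = step_ms),
            class = "feature_windows")
}

#' Binned spike-count windows for the LSTM baseline
#'
#' Same sliding windows as [firing_rate_features()], but each sample is the
#' full `units x bins` matrix of `bin_ms`-binned counts within the window
#' (the LSTM consumes the temporal structure directly).
#'
#' @inheritParams firing_rate_features
#' @param bin_ms Within-window bin width (default 2 ms).
#' @return A list of class `lstm_windows`: `x` (array
#'   `units x bins x windows`), `meta` as in [firing_rate_features()].
#' @export
lstm_windows <- function(data, trial_ids, width_ms = 200, step_ms = 10,
                         bin_ms = 2) {
  if (width_ms %% step_ms != 0 || step_ms %% bin_ms != 0)
    stopf("width_ms must be divisible by step_ms and step_ms by bin_ms")
  bc1 <- align_and_bin(data, "target_on", c(-500, 0), bin_ms, trial_ids)
  bc2 <- align_and_bin(data, "movement_onset", c(-1000, 1000), bin_ms,
                       trial_ids)
  seam_bin <- bc1$n_bins
  n_bins <- seam_bin + bc2$n_bins
  wb <- as.integer(width_ms / bin_ms)
  sb <- as.integer(step_ms / bin_ms)
  starts <- decode_window_starts(n_bins, wb, sb, seam_bin)
  U <- data$n_units
  n_tot <- length(starts) * length(bc1$counts)
  x <- array(0, dim = c(U, wb, n_tot))
  meta <- vector("list", length(bc1$counts))
  k <- 0L
  for (i in seq_along(bc1$counts)) {
    m <- cbind(bc1$counts[[i]], bc2$counts[[i]])
    for (s in starts) {
      k <- k + 1L
      x[, , k] <- m[, (s + 1):(s + wb)]
    }
    meta[[i]] <- data.frame(trial_id = bc1$trial_ids[i],
                            midpoint_u_ms = (starts + wb / 2) * bin_ms)
  }
  meta <- do.call(rbind, meta)
  seq_meta <- list(seam_bin = seam_bin, bin_ms = bin_ms,
                   event = c("target_on", "movement_onset"),
                   window = list(first = c(-500, 0), second = c(-1000, 1000)))
  meta <- assign_true_labels(meta, seq_meta, data$trials)
  meta$class <- label_to_state(meta$true_epoch, meta$true_target)
  structure(list(x = x, meta = meta, width_ms = width_ms,
                 step_ms = step_ms, bin_ms = bin_ms),
            class = "lstm_windows")
}

#' Default SVM hyperparameter grid
#'
#' Misclassification penalty `C` in `{0.001, 0.01, 0.1, 1, 10, 100, 1000}`
#' crossed with a radial-basis kernel (automatic width) and polynomial
#' kernels of degree 2-8.
#'
#' @return `data.frame(kernel, degree, cost)` with 56 rows.
#' @export
default_svm_grid <- function() {
  costs <- c(0.001, 0.01, 0.1, 1, 10, 100, 1000)
  rbind(
    expand.grid(kernel = "radial", degree = NA_integer_, cost = costs,
                stringsAsFactors = FALSE),
    expand.grid(kernel = "polynomial", degree = 2:8, cost = costs,
                stringsAsFactors = FALSE)
  )
}

#' Fit a multiclass SVM over firing-rate features with a grid search
#'
#' Hyperparameters are chosen by cross-validated accuracy over `grid`; the
#' winning configuration is refit on all data.  Multiclass reduction is
#' one-vs-one (the libsvm scheme), recorded in the returned metadata.
#'
#' @param features Numeric matrix (samples x units), e.g.
#'   `firing_rate_features()$features`.
#' @param labels Vector of class labels (>= 2 distinct classes).
#' @param grid `data.frame(kernel, degree, cost)`; defaults to
#'   [default_svm_grid()].
#' @param cv Cross-validation folds for the grid search (default 5).
#' @param seed Integer seed (controls the CV partition).
#' @return A list of class `reach_svm`: the fitted `e1071::svm` model,
#'   `best` hyperparameters, the full `grid_results`, and metadata.
#' @export
svm_fit <- function(features, labels, grid = default_svm_grid(), cv = 5,
                    seed = 1) {
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) < 2)
    stopf("svm_fit needs at least 2 distinct classes")
  features <- as.matrix(features)
  acc <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    set.seed(mix_seed(seed, 606, r))
    args <- list(x = features, y = labels, type = "C-classification",
                 kernel = grid$kernel[r], cost = grid$cost[r],
                 scale = FALSE, cross = cv)
    if (grid$kernel[r] == "polynomial") args$degree <- grid$degree[r]
    fit <- do.call(e1071::svm, args)
    acc[r] <- fit$tot.accuracy / 100
  }
  best <- which.max(acc)
  set.seed(mix_seed(seed, 607))
  args <- list(x = features, y = labels, type = "C-classification",
               kernel = grid$kernel[best], cost = grid$cost[best],
               scale = FALSE)
  if (grid$kernel[best] == "polynomial") args$degree <- grid$degree[best]
  model <- do.call(e1071::svm, args)
  structure(list(model = model,
                 best = grid[best, , drop = FALSE],
                 grid_results = cbind(grid, cv_accuracy = acc),
                 multiclass = "one-vs-one", levels = levels(labels)),
            class = "reach_svm")
}

#' @export
predict.reach_svm <- function(object, newdata, ...) {
  p <- as.character(predict(object$model, as.matrix(newdata)))
  if (!anyNA(suppressWarnings(as.numeric(object$levels)))) as.integer(p) else p
}
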