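#' Write a spike dataset to plain-text files
#'
#' Writes `spikes.csv` (`unit_id`, `trial_id`, `time_ms`), `trials.csv` (the
#' trial event table) and, when the dataset carries its generating population
#' spec, `population.json`.  Times are stored at 0.1 ms resolution so the
#' reader round-trips bit-exactly.
#'
#' @param data A `spike_dataset`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_spike_dataset <- function(data, dir) {
  stopifnot(inherits(data, "spike_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sp <- data$spikes
  sp$time_ms <- sprintf("%.1f", sp$time_ms)
  write.csv(sp, file.path(dir, "spikes.csv"), row.names = FALSE, quote = FALSE)
  write.csv(data$trials, file.path(dir, "trials.csv"), row.names = FALSE,
            quote = FALSE)
  meta <- list(n_units = data$n_units, area = data$area)
  if (!is.null(data$population)) {
    p <- data$population
    meta$population <- list(
      n_units = p$n_units, area_profile = p$area_profile,
      baseline_rate = p$baseline_rate, epoch_gain = p$epoch_gain,
      target_tuning = p$target_tuning, max_rate_hz = p$max_rate_hz,
      seed = p$seed)
  }
  jsonlite::write_json(meta, file.path(dir, "population.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a spike dataset written by [write_spike_dataset()]
#'
#' Validates referential integrity (every spike must reference a trial in the
#' trial table; violations are an error) and repairs unsorted spike times with
#' a warning.  Times are rounded to 0.1 ms.
#'
#' @param dir Directory containing `spikes.csv` and `trials.csv`.
#' @return A `spike_dataset`.
#' @export
read_spike_dataset <- function(dir) {
  sp_path <- file.path(dir, "spikes.csv")
  tr_path <- file.path(dir, "trials.csv")
  if (!file.exists(sp_path) || !file.exists(tr_path))
    stopf("expected spikes.csv and trials.csv under %s", dir)
  spikes <- read.csv(sp_path)
  trials <- read.csv(tr_path)
  validate_trial_table(trials)
  need <- c("unit_id", "trial_id", "time_ms")
  if (!all(need %in% names(spikes)))
    stopf("spikes.csv must have columns unit_id, trial_id, time_ms")
  bad <- setdiff(unique(spikes$trial_id), trials$trial_id)
  if (length(bad))
    stopf("integrity error: spikes reference unknown trial(s): %s",
          paste(head(bad, 5), collapse = ", "))
  spikes$time_ms <- round(spikes$time_ms, 1)
  if (nrow(spikes)) {
    grp <- paste(spikes$unit_id, spikes$trial_id)
    if (any(vapply(split(spikes$time_ms, grp), is.unsorted, logical(1))))
      warning("spike times were not sorted within (unit, trial); repaired")
    spikes <- spikes[order(spikes$unit_id, spikes$trial_id, spikes$time_ms), ,
                     drop = FALSE]
    rownames(spikes) <- NULL
  }

  meta_path <- file.path(dir, "population.json")
  n_units <- max(spikes$unit_id, 0)
  area <- NA_character_
  population <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    n_units <- meta$n_units %||% n_units
    area <- meta$area %||% area
    if (!is.null(meta$population)) {
      p <- meta$population
      population <- structure(
        list(n_units = p$n_units, area_profile = p$area_profile,
             baseline_rate = p$baseline_rate,
             epoch_gain = matrix(as.numeric(p$epoch_gain), ncol = 4,
                                 dimnames = list(NULL, EPOCHS)),
             target_tuning = matrix(as.numeric(p$target_tuning), ncol = 9),
             max_rate_hz = p$max_rate_hz, seed = p$seed),
        class = "population_spec")
    }
  }
  new_spike_dataset(spikes, trials, n_units, area = area,
                    population = population)
}

config_defaults <- function() {
  list(
    bin_ms = 2,
    n_repeats = 100,
    window_widths_ms = c(50, 100, 150, 200, 250, 300),
    window_step_ms = 10,
    consistency_threshold = 0.7,
    max_iter = 500,
    tol = 1e-6,
    emission_floor = 1e-6,
    n_folds = 10,
    seed = 1
  )
}

#' Load a run configuration
#'
#' Reads a YAML file of analysis settings and fills unset keys with the
#' pipeline defaults: 2-ms bins, 100 emission sequences per trial, window
#' widths 50-300 ms with a 10-ms step, consistency threshold 0.7, and
#' Baum-Welch stopping at 500 iterations or a log-likelihood gain below 1e-6.
#' Unknown keys and out-of-range values are errors.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A named list of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- config_defaults()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  with(cfg, {
    if (bin_ms <= 0) stopf("config error: bin_ms must be > 0")
    if (consistency_threshold <= 0 || consistency_threshold >= 1)
      stopf("config error: consistency_threshold must be in (0, 1)")
    if (n_repeats < 1) stopf("config error: n_repeats must be >= 1")
    if (window_step_ms <= 0) stopf("config error: window_step_ms must be > 0")
    if (any(window_widths_ms %% bin_ms != 0))
      stopf("config error: window widths must be divisible by bin_ms")
    if (max_iter < 1 || tol <= 0)
      stopf("config error: max_iter >= 1 and tol > 0 required")
  })
  structure(cfg, class = "run_config")
}

#' Hash a configuration
#'
#' Polynomial rolling hash of the canonical text representation; runs that
#' log equal hashes (and seeds) are reproductions of one another.
#'
#' @param cfg A list, e.g. from [load_config()].
#' @return An 8-character hexadecimal string.
#' @export
config_hash <- function(cfg) {
  txt <- paste(names(cfg), vapply(cfg, function(x)
    paste(format(x, digits = 15), collapse = ","), ""), sep = "=",
    collapse = ";")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
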