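#' Task timing parameters
#'
#' Timing of the instructed-delay reaching protocol.  A trial starts with the
#' hand on the home button (FREE), the target lights up after a fixed
#' `free_ms`, the animal withholds movement for a variable delay, releases the
#' button after a reaction time, reaches (movement), then holds the target.
#' Defaults follow the recorded protocol: 1,000 ms free period, 1,800-2,300 ms
#' delay, 800-1,200 ms hold, and movement duration centred near 360 ms.  The
#' reaction-time range is a modelling choice (the task only bounds it above by
#' 1 s); 200-400 ms keeps movement-onset variability realistic.
#'
#' @param free_ms Fixed duration (ms) between home-button press and target
#'   onset.
#' @param delay_range_ms Uniform range (ms) of the instructed delay
#'   (target onset to go signal).
#' @param reaction_range_ms Uniform range (ms) of the reaction time
#'   (go signal to movement onset).
#' @param movement_range_ms Uniform range (ms) of the reach duration
#'   (movement onset to target touch).
#' @param hold_range_ms Uniform range (ms) of the hold period
#'   (touch to target offset).
#' @return An object of class `task_timing`.
#' @export
task_timing <- function(free_ms = 1000,
                        delay_range_ms = c(1800, 2300),
                        reaction_range_ms = c(200, 400),
                        movement_range_ms = c(280, 440),
                        hold_range_ms = c(800, 1200)) {
  rng <- list(delay_range_ms = delay_range_ms,
              reaction_range_ms = reaction_range_ms,
              movement_range_ms = movement_range_ms,
              hold_range_ms = hold_range_ms)
  for (nm in names(rng)) {
    r <- rng[[nm]]
    if (!is.numeric(r) || length(r) != 2 || any(r <= 0) || r[1] > r[2])
      stopf("`%s` must be a positive range with low <= high", nm)
  }
  if (!is.numeric(free_ms) || length(free_ms) != 1 || free_ms <= 0)
    stopf("`free_ms` must be a single positive number")
  structure(c(list(free_ms = free_ms), rng), class = "task_timing")
}

#' Generate a trial schedule for the 9-target reaching task
#'
#' Draws event times for `9 * n_trials_per_target` trials.  Event times are in
#' ms relative to the home-button press of each trial (home press at 0) and
#' are stored at 0.1 ms resolution.
#'
#' @param n_trials_per_target Number of correct trials per target (default 10).
#' @param timing A [task_timing()] object.
#' @param seed Integer seed; the schedule is deterministic given the seed.
#' @return A `data.frame` (trial table) with columns `trial_id`, `target_id`
#'   (1-9), `home_press_ms`, `target_on_ms`, `go_ms`, `movement_onset_ms`,
#'   `touch_ms`, `target_off_ms`.
#' @export
make_task_schedule <- function(n_trials_per_target = 10,
                               timing = task_timing(),
                               seed = 1) {
  n_trials_per_target <- check_count(n_trials_per_target, "n_trials_per_target")
  stopifnot(inherits(timing, "task_timing"))
  n <- 9L * n_trials_per_target
  set.seed(mix_seed(seed, 101))
  draw <- function(r) round(runif(n, r[1], r[2]), 1)
  delay <- draw(timing$delay_range_ms)
  react <- draw(timing$reaction_range_ms)
  move <- draw(timing$movement_range_ms)
  hold <- draw(timing$hold_range_ms)
  target_on <- rep(timing$free_ms, n)
  go <- target_on + delay
  mo <- go + react
  touch <- mo + move
  off <- touch + hold
  data.frame(
    trial_id = seq_len(n),
    target_id = rep(1:9, times = n_trials_per_target),
    home_press_ms = 0,
    target_on_ms = round(target_on, 1),
    go_ms = round(go, 1),
    movement_onset_ms = round(mo, 1),
    touch_ms = round(touch, 1),
    target_off_ms = round(off, 1)
  )
}

validate_trial_table <- function(trials) {
  need <- c("trial_id", "target_id", "home_press_ms", "target_on_ms", "go_ms",
            "movement_onset_ms", "touch_ms", "target_off_ms")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stopf("trial table missing columns: %s", paste(miss, collapse = ", "))
  ev <- as.matrix(trials[, need[-(1:2)]])
  if (any(apply(ev, 1, function(r) any(diff(r) <= 0))))
    stopf("trial event times must be strictly increasing within each trial")
  if (anyDuplicated(trials$trial_id)) stopf("duplicate trial ids")
  if (!all(trials$target_id %in% 1:9)) stopf("target ids must be in 1..9")
  invisible(trials)
}

# Per-trial epoch boundaries, half-open [start, end) in trial time (ms).
# The reaction period (go -> movement onset) is counted as DELAY.
epoch_bounds <- function(trial_row) {
  b <- c(trial_row$home_press_ms, trial_row$target_on_ms,
         trial_row$movement_onset_ms, trial_row$touch_ms,
         trial_row$target_off_ms)
  data.frame(epoch = EPOCHS, start_ms = b[1:4], end_ms = b[2:5])
}

# 3 x 3 target grid used by the tuning model and the workspace geometry:
# target id = 3 * (depth - 1) + direction, directions left/centre/right
# (columns 1..3), depths near/intermediate/far (rows 1..3).
target_grid <- function() {
  data.frame(target_id = 1:9,
             direction = rep(c(-1, 0, 1), times = 3),
             depth = rep(1:3, each = 3))
}

profile_names <- c("V6A-like", "PEc-like", "PE-like", "custom")

#' Generate a synthetic neural population
#'
#' Draws per-unit baseline rates, epoch gain multipliers and 9-target tuning
#' multipliers that emulate the qualitative contrasts between the three
#' parietal populations: `"V6A-like"` has strong, spatially smooth target
#' tuning; `"PEc-like"` has the strongest epoch separation with intermediate
#' tuning; `"PE-like"` has weak tuning and near-identical FREE and HOLD gains
#' (the FREE/HOLD similarity that degrades its decoding).  `"custom"` yields a
#' homogeneous population (all gains 1, flat tuning) unless overridden.
#'
#' Tuning is multiplicative and spatially smooth: each unit has a 2-D Gaussian
#' sensitivity bump over the 3 x 3 (direction x depth) target grid with a
#' random centre, exponentiated so nearby targets have correlated rates.
#'
#' @param n_units Number of units (>= 1).
#' @param area_profile One of `"V6A-like"`, `"PEc-like"`, `"PE-like"`,
#'   `"custom"`.
#' @param seed Integer seed.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of baseline
#'   rates (sp/s).
#' @param max_rate_hz Cap (sp/s) applied to instantaneous rates during
#'   simulation, guarding against symbol saturation in 2-ms bins.
#' @param custom For `area_profile = "custom"`: optional list with entries
#'   `baseline_rate` (length `n_units`), `epoch_gain` (`n_units` x 4 matrix,
#'   columns FREE/DELAY/MOVE/HOLD) and `target_tuning` (`n_units` x 9 matrix).
#' @return An object of class `population_spec`.
#' @export
make_population <- function(n_units, area_profile = "V6A-like", seed = 1,
                            baseline_meanlog = log(5), baseline_sdlog = 0.5,
                            max_rate_hz = 100, custom = NULL) {
  n_units <- check_count(n_units, "n_units")
  if (!is.character(area_profile) || length(area_profile) != 1 ||
      !area_profile %in% profile_names)
    stopf("unknown area profile; must be one of: %s",
          paste(profile_names, collapse = ", "))
  set.seed(mix_seed(seed, 202))
  baseline <- rlnorm(n_units, baseline_meanlog, baseline_sdlog)

  g <- matrix(1, n_units, 4, dimnames = list(NULL, EPOCHS))
  grid <- target_grid()
  tuning <- matrix(1, n_units, 9)

  if (area_profile != "custom") {
    # Epoch gains are drawn per unit and per epoch (log-normal around
    # epoch-specific means), so each epoch has a distinct population-wide
    # activation *pattern* -- some units up-, some down-modulated -- rather
    # than a common scaling.  The log-spread controls how separable the
    # epoch patterns are; the tuning amplitude controls spatial information.
    g[, "FREE"] <- rlnorm(n_units, 0, 0.3)
    if (area_profile == "V6A-like") {
      g[, "DELAY"] <- rlnorm(n_units, log(1.6), 0.4)
      g[, "MOVE"] <- rlnorm(n_units, log(2.8), 0.4)
      g[, "HOLD"] <- rlnorm(n_units, log(1.5), 0.6)
      amp <- runif(n_units, 1.5, 2.5)
    } else if (area_profile == "PEc-like") {
      g[, "DELAY"] <- rlnorm(n_units, log(1.8), 0.5)
      g[, "MOVE"] <- rlnorm(n_units, log(3.2), 0.5)
      g[, "HOLD"] <- rlnorm(n_units, log(1.7), 0.7)
      amp <- runif(n_units, 0.5, 1.0)
    } else { # PE-like: FREE and HOLD nearly identical per unit, weak tuning
      g[, "DELAY"] <- rlnorm(n_units, log(1.3), 0.3)
      g[, "MOVE"] <- rlnorm(n_units, log(1.9), 0.25)
      g[, "HOLD"] <- g[, "FREE"] * runif(n_units, 0.95, 1.05)
      amp <- runif(n_units, 0.1, 0.3)
    }
    cx <- runif(n_units, -1, 1)
    cy <- runif(n_units, 1, 3)
    sigma <- 1
    for (u in seq_len(n_units)) {
      bump <- exp(-((grid$direction - cx[u])^2 + (grid$depth - cy[u])^2) /
                    (2 * sigma^2))
      tun <- exp(amp[u] * (bump - mean(bump)))
      tuning[u, ] <- tun / mean(tun)   # mean 1: tuning shifts, not inflates
    }
  } else if (!is.null(custom)) {
    if (!is.null(custom$baseline_rate)) {
      stopifnot(length(custom$baseline_rate) == n_units,
                all(custom$baseline_rate >= 0))
      baseline <- custom$baseline_rate
    }
    if (!is.null(custom$epoch_gain)) {
      stopifnot(nrow(custom$epoch_gain) == n_units,
                ncol(custom$epoch_gain) == 4, all(custom$epoch_gain > 0))
      g[, ] <- as.matrix(custom$epoch_gain)
    }
    if (!is.null(custom$target_tuning)) {
      stopifnot(nrow(custom$target_tuning) == n_units,
                ncol(custom$target_tuning) == 9, all(custom$target_tuning > 0))
      tuning <- as.matrix(custom$target_tuning)
    }
  }

  structure(list(n_units = n_units, area_profile = area_profile,
                 baseline_rate = baseline, epoch_gain = g,
                 target_tuning = tuning, max_rate_hz = max_rate_hz,
                 seed = seed),
            class = "population_spec")
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("<population_spec> %d units, profile %s\n", x$n_units,
              x$area_profile))
  cat(sprintf("  baseline rate: median %.1f sp/s; rate cap %.0f sp/s\n",
              stats::median(x$baseline_rate), x$max_rate_hz))
  invisible(x)
}

#' Simulate Poisson spike trains for a task schedule
#'
#' Within each epoch of each trial, unit `u` fires as a homogeneous Poisson
#' process at `baseline * epoch_gain[epoch] * target_tuning[target]` sp/s
#' (capped at `max_rate_hz`).  Spike times are in ms relative to the trial's
#' home-button press, rounded to 0.1 ms and sorted.  All randomness flows from
#' `seed` via one substream per (unit, trial), so datasets are reproducible
#' and unaffected by the order of generation.
#'
#' @param spec A [make_population()] object.
#' @param trials A trial table from [make_task_schedule()].
#' @param seed Integer seed.
#' @return An object of class `spike_dataset`: a list with `spikes`
#'   (`data.frame` of `unit_id`, `trial_id`, `time_ms`), `n_units`, `trials`,
#'   `area`, and the generating `population` spec.
#' @export
simulate_spikes <- function(spec, trials, seed = 1) {
  stopifnot(inherits(spec, "population_spec"))
  validate_trial_table(trials)
  t_list <- vector("list", nrow(trials) * spec$n_units)
  n_per <- integer(nrow(trials) * spec$n_units)
  uu <- integer(length(n_per))
  ii <- integer(length(n_per))
  k <- 0L
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    eb <- epoch_bounds(tr)
    tune <- spec$target_tuning[, tr$target_id]
    for (u in seq_len(spec$n_units)) {
      set.seed(mix_seed(seed, 303, u, tr$trial_id))
      times <- numeric(0)
      for (e in seq_len(4)) {
        rate <- min(spec$baseline_rate[u] * spec$epoch_gain[u, e] * tune[u],
                    spec$max_rate_hz)
        dur <- eb$end_ms[e] - eb$start_ms[e]
        n <- rpois(1, rate * dur / 1000)
        if (n > 0)
          times <- c(times, runif(n, eb$start_ms[e], eb$end_ms[e]))
      }
      k <- k + 1L
      t_list[[k]] <- sort(round(times, 1))
      n_per[k] <- length(times)
      uu[k] <- u
      ii[k] <- tr$trial_id
    }
  }
  spikes <- data.frame(unit_id = rep(uu[seq_len(k)], n_per[seq_len(k)]),
                       trial_id = rep(ii[seq_len(k)], n_per[seq_len(k)]),
                       time_ms = unlist(t_list[seq_len(k)]))
  new_spike_dataset(spikes, trials, spec$n_units, area = spec$area_profile,
                    population = spec)
}

new_spike_dataset <- function(spikes, trials, n_units, area = NA_character_,
                              population = NULL) {
  validate_trial_table(trials)
  structure(list(spikes = spikes, trials = trials, n_units = n_units,
                 area = area, population = population),
            class = "spike_dataset")
}

#' @export
print.spike_dataset <- function(x, ...) {
  cat(sprintf("<spike_dataset> %d units, %d trials, %d spikes (area: %s)\n",
              x$n_units, nrow(x$trials), nrow(x$spikes), x$area))
  invisible(x)
}

#' Convenience: generate a full synthetic dataset
#'
#' Chains [make_task_schedule()], [make_population()] and [simulate_spikes()]
#' with substreams of one seed.
#'
#' @inheritParams make_population
#' @param n_trials_per_target Trials per target (default 10).
#' @param timing A [task_timing()] object.
#' @param ... Passed to [make_population()].
#' @return A `spike_dataset`.
#' @export
make_synthetic_dataset <- function(n_units, area_profile = "V6A-like",
                                   n_trials_per_target = 10,
                                   timing = task_timing(), seed = 1, ...) {
  trials <- make_task_schedule(n_trials_per_target, timing,
                               seed = mix_seed(seed, 1))
  spec <- make_population(n_units, area_profile, seed = mix_seed(seed, 2), ...)
  simulate_spikes(spec, trials, seed = mix_seed(seed, 3))
}
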