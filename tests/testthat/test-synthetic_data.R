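test_that("task schedule respects the protocol timing and is reproducible", {
  tt <- task_timing()
  tr <- make_task_schedule(10, tt, seed = 42)
  expect_equal(nrow(tr), 90)
  expect_equal(as.vector(table(tr$target_id)), rep(10, 9))
  expect_true(all(tr$target_on_ms - tr$home_press_ms == tt$free_ms))
  delay <- tr$go_ms - tr$target_on_ms
  expect_true(all(delay >= 1800 & delay <= 2300))
  hold <- tr$target_off_ms - tr$touch_ms
  expect_true(all(hold >= 800 & hold <= 1200))
  move <- tr$touch_ms - tr$movement_onset_ms
  expect_true(all(move >= tt$movement_range_ms[1] &
                    move <= tt$movement_range_ms[2]))
  ev <- as.matrix(tr[, c("home_press_ms", "target_on_ms", "go_ms",
                         "movement_onset_ms", "touch_ms", "target_off_ms")])
  expect_true(all(apply(ev, 1, function(r) all(diff(r) > 0))))
  expect_identical(tr, make_task_schedule(10, tt, seed = 42))
  expect_false(identical(tr, make_task_schedule(10, tt, seed = 43)))
})

test_that("degenerate timing ranges give identical event offsets", {
  tt <- task_timing(delay_range_ms = c(2000, 2000),
                    reaction_range_ms = c(300, 300),
                    movement_range_ms = c(360, 360),
                    hold_range_ms = c(1000, 1000))
  tr <- make_task_schedule(3, tt, seed = 1)
  for (col in c("go_ms", "movement_onset_ms", "touch_ms", "target_off_ms"))
    expect_equal(length(unique(tr[[col]])), 1)
})

test_that("schedule and timing arguments are validated", {
  expect_error(make_task_schedule(0), "n_trials_per_target")
  expect_error(task_timing(delay_range_ms = c(2300, 1800)), "low <= high")
  expect_error(task_timing(hold_range_ms = c(-5, 10)), "positive")
})

test_that("area profiles produce the intended tuning and gain contrasts", {
  expect_error(make_population(10, "M1-like"), "unknown area profile")
  expect_error(make_population(0), "n_units")

  pe <- make_population(42, "PE-like", seed = 5)
  g <- pe$epoch_gain
  near <- abs(g[, "FREE"] - g[, "HOLD"]) < abs(g[, "MOVE"] - g[, "HOLD"])
  expect_gte(mean(near), 0.9)
  expect_true(all(pe$target_tuning > 0))
  expect_equal(ncol(pe$target_tuning), 9)

  v6a <- make_population(42, "V6A-like", seed = 5)
  cv <- function(m) mean(apply(m, 1, function(x) sd(x) / mean(x)))
  expect_gt(cv(v6a$target_tuning), cv(pe$target_tuning))

  # all profiles give MOVE a clearly distinct (elevated) gain distribution
  for (prof in c("V6A-like", "PEc-like", "PE-like")) {
    p <- make_population(60, prof, seed = 2)
    m <- colMeans(p$epoch_gain)
    expect_gt(m[["MOVE"]], m[["DELAY"]] * 1.1)
    expect_gt(m[["MOVE"]], m[["HOLD"]] * 1.1)
    expect_gt(m[["DELAY"]], m[["FREE"]] * 1.05)
  }
})

test_that("custom profile with unit gains and flat tuning is homogeneous", {
  p <- make_population(5, "custom", seed = 1)
  expect_true(all(p$epoch_gain == 1))
  expect_true(all(p$target_tuning == 1))
})

test_that("tuning is spatially smooth: nearby targets correlate", {
  p <- make_population(80, "V6A-like", seed = 11)
  geom <- target_geometry()
  d <- geom$distances
  tun <- log(p$target_tuning)
  cors <- cor(tun)
  near_pairs <- d > 0 & d <= 6
  far_pairs <- d >= 16
  expect_gt(mean(cors[near_pairs]), mean(cors[far_pairs]))
})

test_that("simulated spikes are Poisson with the specified rates", {
  # 1 unit at 20 sp/s, flat gains/tuning; FREE epoch is exactly 1000 ms
  spec <- make_population(1, "custom", seed = 1,
                          custom = list(baseline_rate = 20))
  trials <- make_task_schedule(50, task_timing(), seed = 3)  # 450 trials
  data <- simulate_spikes(spec, trials, seed = 9)
  counts <- vapply(trials$trial_id, function(id) {
    sum(data$spikes$trial_id == id & data$spikes$time_ms < 1000)
  }, numeric(1))
  n <- length(counts)
  se <- sqrt(20 / n)
  expect_lt(abs(mean(counts) - 20), 3 * se)
  # Fano factor of Poisson counts is 1
  fano <- var(counts) / mean(counts)
  expect_lt(abs(fano - 1), 3 * sqrt(2 / (n - 1)))
})

test_that("zero-rate units never fire and spikes stay inside the trial", {
  spec <- make_population(3, "custom", seed = 1,
                          custom = list(baseline_rate = c(0, 10, 10)))
  trials <- make_task_schedule(2, task_timing(), seed = 2)
  data <- simulate_spikes(spec, trials, seed = 4)
  expect_false(any(data$spikes$unit_id == 1))
  for (id in trials$trial_id) {
    sp <- data$spikes[data$spikes$trial_id == id, ]
    expect_true(all(sp$time_ms >= 0 &
                      sp$time_ms <= trials$target_off_ms[trials$trial_id == id]))
    for (u in unique(sp$unit_id))
      expect_false(is.unsorted(sp$time_ms[sp$unit_id == u]))
  }
})

test_that("the full generator is reproducible from one seed", {
  d1 <- make_synthetic_dataset(6, "PEc-like", n_trials_per_target = 2, seed = 31)
  d2 <- make_synthetic_dataset(6, "PEc-like", n_trials_per_target = 2, seed = 31)
  expect_identical(d1$spikes, d2$spikes)
  expect_identical(d1$trials, d2$trials)
})
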