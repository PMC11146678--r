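expected_boosted_mask <- function() {
  mask <- matrix(FALSE, 28, 28)
  mask[1, 1] <- TRUE
  for (t in 1:9) {
    d <- 2 + 3 * (t - 1)
    mask[1, d] <- TRUE
    mask[d, d] <- TRUE; mask[d, d + 1] <- TRUE
    mask[d + 1, d + 1] <- TRUE; mask[d + 1, d + 2] <- TRUE
    mask[d + 2, d + 2] <- TRUE
  }
  mask
}

test_that("merging builds the 28-state block topology with a shared FREE", {
  tm <- toy_target_models(M = 5)
  model <- merge_boosted(tm)
  expect_equal(model$K, 28)
  expect_equal(rowSums(model$A), rep(1, 28), tolerance = 1e-12)
  expect_equal(rowSums(model$B), rep(1, 28), tolerance = 1e-12)
  expect_equal(model$pi, c(1, rep(0, 27)))

  # FREE row: mean self-transition, remaining mass split over DELAY states
  free_self <- mean(vapply(tm$two, function(m) m$A[1, 1], numeric(1)))
  expect_equal(model$A[1, 1], free_self)
  delay_states <- 2 + 3 * (0:8)
  expect_equal(unname(model$A[1, delay_states]),
               rep((1 - free_self) / 9, 9))
  expect_equal(model$B[1, ],
               colMeans(do.call(rbind, lapply(tm$two, function(m) m$B[1, ]))))

  # blocks copied from the per-target three-state models
  for (t in c(1, 5, 9)) {
    idx <- (2 + 3 * (t - 1)):(4 + 3 * (t - 1))
    expect_equal(unname(model$A[idx, idx]), unname(tm$three[[t]]$A))
    expect_equal(unname(model$B[idx, ]), unname(tm$three[[t]]$B))
  }

  # structural zeros cell by cell: no cross-target or backward transitions
  expect_identical(unname(model$mask), expected_boosted_mask())
  expect_true(all(model$A[!expected_boosted_mask()] == 0))
  expect_equal(model$A[3, 6], 0)            # DELAY_1 -> MOVE_2 forbidden
  expect_equal(model$A[4, 4], 1)            # HOLD_1 absorbing
  lab <- model$state_labels
  expect_equal(lab$epoch[1], "FREE")
  expect_equal(sum(lab$epoch == "DELAY"), 9)

  tm_bad <- tm
  tm_bad$two[[3]] <- hmm_params(c(1, 0),
                                matrix(c(0.9, 0.1, 0, 1), 2, 2, byrow = TRUE),
                                matrix(1 / 4, 2, 4),
                                mask = matrix(c(TRUE, TRUE, FALSE, TRUE),
                                              2, 2, byrow = TRUE))
  expect_error(merge_boosted(tm_bad), "symbol-count mismatch")
})

test_that("window decoding fragments, restarts at FREE and averages", {
  # boosted model over 4 symbols where HOLD_3's block owns symbol 3
  tm <- toy_target_models(M = 5, seed = 9)
  # symbol 3 is unique to HOLD_3's emission support
  B3 <- rbind(c(0.25, 0.25, 0.25, 0.001, 0.249),
              c(0.25, 0.25, 0.25, 0.001, 0.249),
              c(0.001, 0.001, 0.001, 0.995, 0.002))
  B3 <- B3 / rowSums(B3)
  tm$three[[3]]$B <- B3
  model <- merge_boosted(tm)

  seqs <- structure(list(seqs = list(matrix(3L, 2, 500)), trial_ids = 1L,
                         target_ids = 3L, n_units = 4L, n_symbols = 5L,
                         bin_ms = 2, event = "movement_onset",
                         window = c(-500, 500), n_repeats = 2L,
                         seam_bin = NULL),
                    class = "emission_seqs")
  pred <- decode_windows(model, seqs, width_ms = 200, step_ms = 10)
  # fragments are 100 bins wide, starts step by 5 bins
  expect_equal(sort(unique(pred$start_bin)),
               seq(0L, 400L, by = 5L))
  # fragments emitted solely by HOLD_3's private symbol decode to HOLD_3
  expect_true(all(pred$pred_state == 10))
  expect_true(all(pred$pred_epoch == "HOLD"))
  expect_true(all(pred$pred_target == 3))
})

test_that("ties in the averaged posterior go to the earliest chain state", {
  A <- diag(2)
  B <- matrix(0.5, 2, 2)
  h <- hmm_params(c(0.5, 0.5), A, B, mask = diag(2) > 0,
                  state_labels = data.frame(state = 1:2,
                                            epoch = c("FREE", "DELAY"),
                                            target = c(0L, 1L)))
  seqs <- structure(list(seqs = list(matrix(0L, 1, 20)), trial_ids = 1L,
                         target_ids = 1L, n_units = 1L, n_symbols = 2L,
                         bin_ms = 2, event = "movement_onset",
                         window = c(0, 40), n_repeats = 1L, seam_bin = NULL),
                    class = "emission_seqs")
  pred <- decode_windows(h, seqs, width_ms = 20, step_ms = 10)
  expect_true(all(pred$pred_state == 1))
})

test_that("windows never straddle the concatenation seam", {
  starts <- reachstates:::decode_window_starts(1250L, 100L, 5L, 250L)
  expect_false(any(starts < 250 & starts + 100 > 250))
  expect_true(0 %in% starts)        # FREE-segment windows survive
  expect_true(250 %in% starts)      # movement-segment windows start at seam
})

test_that("decoded windows agree with an independent forward-backward", {
  tm <- toy_target_models(M = 6, seed = 2)
  model <- merge_boosted(tm)
  set.seed(31)
  obs <- sample(0:5, 400, replace = TRUE)
  starts <- as.integer(seq(0, 300, by = 6))
  post <- reachstates:::rs_window_posteriors(model$pi, model$A, model$B,
                                             model$mask, obs, starts, 100L)
  for (w in seq_along(starts)) {
    frag <- obs[(starts[w] + 1):(starts[w] + 100)]
    oracle <- r_forward_backward(model$pi, model$A, model$B, frag)
    expect_lt(max(abs(post[w, ] - colMeans(oracle$gamma))), 1e-10)
  }
})

test_that("true labels follow the window midpoint and the later-epoch rule", {
  trials <- data.frame(trial_id = 1L, target_id = 4L, home_press_ms = 0,
                       target_on_ms = 1000, go_ms = 3000,
                       movement_onset_ms = 3300, touch_ms = 3660,
                       target_off_ms = 4660)
  seq_meta <- list(seam_bin = 250L, bin_ms = 2,
                   event = c("target_on", "movement_onset"),
                   window = list(first = c(-500, 0), second = c(-1000, 1000)))
  # midpoints on the concatenated axis:
  #  u = 250   -> trial time 750 (FREE)
  #  u = 1500  -> 1000 ms into the movement window = movement onset (MOVE)
  #  u = 1000  -> 3300 - 500 = 2800 (DELAY)
  #  u = 1860  -> touch exactly -> later epoch HOLD
  win <- data.frame(trial_id = 1L, midpoint_u_ms = c(250, 1500, 1000, 1860))
  lab <- assign_true_labels(win, seq_meta, trials)
  expect_equal(lab$true_epoch, c("FREE", "MOVE", "DELAY", "HOLD"))
  expect_equal(lab$true_target, c(0L, 4L, 4L, 4L))

  bad <- data.frame(trial_id = 1L, midpoint_u_ms = 2900)
  expect_error(assign_true_labels(bad, seq_meta, trials), "outside")
})
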