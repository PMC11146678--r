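test_that("accuracy and shuffle chance behave as expected", {
  pred <- rep(1:4, 50)
  out <- accuracy_and_chance(pred, pred, n_shuffles = 10, seed = 1)
  expect_equal(out$accuracy, 1)
  expect_error(accuracy_and_chance(pred, pred, n_shuffles = 0), "n_shuffles")
  expect_error(accuracy_and_chance(integer(0), integer(0)), "non-empty")

  # balanced 4-class labels: mean shuffled accuracy approaches 1/4
  set.seed(3)
  true <- sample(rep(1:4, 250))
  pred <- sample(rep(1:4, 250))
  out <- accuracy_and_chance(pred, true, n_shuffles = 400, seed = 2)
  expect_lt(abs(mean(out$chance_distribution) - 0.25), 0.01)
  expect_gte(out$chance_level, mean(out$chance_distribution))
})

test_that("confusion matrices conserve counts and normalize rows", {
  pred <- c(1, 1, 2, 3, 3, 3)
  true <- c(1, 2, 2, 3, 3, 1)
  cm <- confusion(pred, true)
  expect_equal(sum(cm$counts), 6)
  expect_equal(unname(rowSums(cm$prop)), rep(1, 3))
  cm_perfect <- confusion(true, true)
  expect_equal(unname(cm_perfect$prop), diag(3))
  cm_missing <- confusion(c(1, 1), c(1, 1), labels = 1:3)
  expect_equal(cm_missing$zero_support, 2:3)
})

test_that("error patterns split misclassifications by epoch order", {
  # all confusion mass strictly below the diagonal: preceding fraction 1
  true <- c("DELAY", "MOVE", "HOLD")
  pred <- c("FREE", "DELAY", "MOVE")
  ep <- error_pattern(pred, true)
  expect_equal(ep$preceding, 1)
  expect_equal(ep$subsequent, 0)

  # symmetric confusion: 0.5 / 0.5
  true <- c("FREE", "DELAY", "DELAY", "MOVE")
  pred <- c("DELAY", "FREE", "MOVE", "DELAY")
  ep <- error_pattern(pred, true)
  expect_equal(ep$preceding, 0.5)
  expect_equal(ep$preceding + ep$subsequent, 1)

  ep0 <- error_pattern(c("FREE", "MOVE"), c("FREE", "MOVE"))
  expect_equal(ep0$n_errors, 0L)
  expect_true(is.na(ep0$preceding))

  ep1 <- error_pattern(c("MOVE", "FREE", "MOVE"),
                       c("DELAY", "HOLD", "FREE"))
  expect_equal(ep1$delay_as_move, 1 / 3)
  expect_equal(ep1$hold_as_free, 1 / 3)
  expect_equal(ep1$free_as_move, 1 / 3)
})

test_that("target geometry places the 3 x 3 grid in the workspace plane", {
  g <- target_geometry()
  pos <- g$positions
  expect_equal(nrow(pos), 9)
  # near-central target sits straight ahead at 10 cm
  nc <- pos[pos$direction == 0 & pos$depth == 1, ]
  expect_equal(c(nc$x_cm, nc$y_cm), c(0, 10))
  # far-right x-coordinate is 25 sin(15 deg)
  fr <- pos[pos$direction == 1 & pos$depth == 3, ]
  expect_equal(fr$x_cm, 25 * sin(15 * pi / 180))
  # mirror symmetry: left and right targets are equidistant from centre
  for (d in 1:3) {
    l <- pos$target_id[pos$direction == -1 & pos$depth == d]
    r <- pos$target_id[pos$direction == 1 & pos$depth == d]
    c0 <- pos$target_id[pos$direction == 0 & pos$depth == d]
    expect_equal(g$distances[l, c0], g$distances[r, c0])
  }
  expect_equal(sum(upper.tri(g$distances)), 36)
})

test_that("distance-confusion correlation detects spatial error structure", {
  g <- target_geometry()
  d <- g$distances
  conf <- exp(-d / 5)
  diag(conf) <- 5
  out <- distance_confusion_correlation(conf, g)
  expect_lt(out$estimate, -0.8)
  expect_lt(out$p_value, 0.001)

  # permuting the targets destroys the correlation
  set.seed(4)
  perm <- sample(9)
  out_p <- distance_confusion_correlation(conf[perm, perm], g)
  expect_lt(abs(out_p$estimate), abs(out$estimate))

  # uniform confusion carries no distance signal
  u <- matrix(1, 9, 9)
  out_u <- distance_confusion_correlation(u, g)
  expect_equal(out_u$estimate, 0)

  z <- diag(9)
  out_z <- distance_confusion_correlation(z, g)
  expect_true(out_z$absent)
})

test_that("DBI matches the defining formula", {
  # two zero-scatter clusters
  f <- matrix(c(0, 0, 5, 5), 4, 1)
  expect_equal(as.numeric(dbi(f, c(1, 1, 2, 2))), 0)

  # 1-D worked example: S = 1 each, M = 10 -> DBI = 0.2
  f <- matrix(c(0, 2, 10, 12), 4, 1)
  expect_equal(as.numeric(dbi(f, c("a", "a", "b", "b"))), 0.2)

  expect_error(dbi(f, c(1, 1, 1, 1)), "at least 2 clusters")
  expect_error(dbi(f, c(1, 1, 2, 3)), "at least 2 samples")

  # coincident centroids give an infinite index with a warning
  f <- matrix(c(0, 2, 1, 1, 0, 2), 6, 1)
  expect_warning(v <- dbi(f, c(1, 1, 1, 2, 2, 2)), "coincident")
  expect_true(is.infinite(v))
})

test_that("DBI equals an independent oracle on exhaustive small instances", {
  set.seed(6)
  for (rep in 1:5) {
    pts <- matrix(round(rnorm(6), 2), 6, 1)
    # all 2-cluster assignments of 6 points with >= 2 points per cluster
    for (code in 1:(2^6 - 2)) {
      lab <- as.integer(intToBits(code))[1:6]
      if (sum(lab) < 2 || sum(lab) > 4) next
      expect_equal(as.numeric(dbi(pts, lab)), dbi_oracle(pts, lab))
    }
  }
})

test_that("merging separated clusters raises the DBI", {
  set.seed(9)
  f <- rbind(matrix(rnorm(40, 0, 0.5), 20, 2),
             matrix(rnorm(40, 5, 0.5), 20, 2),
             matrix(rnorm(40, 10, 0.5), 20, 2))
  lab <- rep(1:3, each = 20)
  base <- as.numeric(dbi(f, lab))
  # random relabelling of two true clusters into two mixed ones
  mixed <- lab
  swap <- sample(which(lab != 3))
  mixed[swap] <- rep(1:2, length.out = length(swap))
  expect_gt(as.numeric(dbi(f, mixed)), base)
})

test_that("bootstrap DBI resamples unit subsets", {
  set.seed(12)
  f <- rbind(matrix(rnorm(200, 0), 10, 20), matrix(rnorm(200, 2), 10, 20))
  lab <- rep(1:2, each = 10)
  one <- bootstrap_dbi(f, lab, mode = "fraction", fraction = 1.0, n_boot = 1,
                       seed = 1)
  expect_equal(as.numeric(one), as.numeric(dbi(f, lab)))
  fixed <- bootstrap_dbi(f, lab, mode = "fixed", n_fixed = 18, n_boot = 20,
                         seed = 2)
  expect_length(fixed, 20)
  expect_error(bootstrap_dbi(f[, 1:10], lab, mode = "fixed", n_fixed = 40),
               "cannot sample")

  # resampling variability shrinks with population size
  big <- cbind(f, f + rnorm(length(f), sd = 0.1),
               f + rnorm(length(f), sd = 0.1))
  sd_small <- sd(bootstrap_dbi(f, lab, n_boot = 60, seed = 3))
  sd_big <- sd(bootstrap_dbi(big, lab, n_boot = 60, seed = 3))
  expect_lt(sd_big, sd_small)
})

test_that("epoch rate features average spikes within each epoch", {
  data <- toy_dataset()
  f <- epoch_rate_features(data)
  expect_equal(dim(f$features), c(8, 3))
  expect_equal(nrow(f$labels), 8)
  # trial 1, FREE epoch (0-1000 ms): unit 1 fired twice -> 2 sp/s
  row <- which(f$labels$trial_id == 1 & f$labels$epoch == "FREE")
  expect_equal(f$features[row, 1], 2)
})

test_that("rank comparisons of condition samples", {
  expect_equal(compare_conditions(1:10, 1:10), 1)
  a <- rnorm(20, 0, 0.1)
  b <- rnorm(20, 10, 0.1)
  expect_lt(compare_conditions(a, b), 0.01)
  expect_error(compare_conditions(1:2, 1:5), "at least 3")
})

test_that("the 2-D embedding preserves separated epoch clusters", {
  set.seed(21)
  f <- rbind(matrix(rnorm(120, 0), 20, 6),
             matrix(rnorm(120, 6), 20, 6),
             matrix(rnorm(120, 12), 20, 6))
  lab <- rep(1:3, each = 20)
  emb <- embed_2d(f, perplexity = 8, seed = 5, n_iter = 300)
  expect_equal(dim(emb), c(60, 2))
  expect_identical(emb, embed_2d(f, perplexity = 8, seed = 5, n_iter = 300))
  expect_gt(silhouette_oracle(emb, lab), 0)
  expect_error(embed_2d(f[1:10, ], perplexity = 8), "perplexity")
})
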