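#' Classification accuracy with a label-shuffle chance distribution
#'
#' Accuracy is the fraction of correct classifications.  The chance
#' distribution is obtained by shuffling the vector of true labels
#' `n_shuffles` times (default 1,000) and recomputing accuracy; the chance
#' level reported is the 95th percentile of that distribution (the full
#' distribution is returned as well).
#'
#' @param pred,true Equal-length label vectors.
#' @param n_shuffles Number of shuffles (>= 1).
#' @param seed Integer seed.
#' @return A list: `accuracy`, `chance_level` (95th percentile),
#'   `chance_distribution`, `above_chance`.
#' @export
accuracy_and_chance <- function(pred, true, n_shuffles = 1000, seed = 1) {
  if (!length(pred) || length(pred) != length(true))
    stopf("pred and true must be non-empty and of equal length")
  n_shuffles <- check_count(n_shuffles, "n_shuffles")
  acc <- mean(pred == true)
  set.seed(mix_seed(seed, 808))
  ch <- vapply(seq_len(n_shuffles),
               function(i) mean(pred == sample(true)), numeric(1))
  lvl <- unname(quantile(ch, 0.95))
  list(accuracy = acc, chance_level = lvl, chance_distribution = ch,
       above_chance = acc > lvl)
}

#' Confusion matrix (counts and row-normalized)
#'
#' Rows are true classes, columns predicted classes.  Classes absent from
#' the data still get (zero) rows, which are flagged rather than dropped.
#'
#' @param pred,true Label vectors.
#' @param labels Label order; defaults to the sorted union.
#' @return A list of class `confusion_matrix`: `counts`, `prop`
#'   (row-normalized; zero-support rows are NA), `labels`, `zero_support`.
#' @export
confusion <- function(pred, true, labels = NULL) {
  if (is.null(labels)) labels <- sort(unique(c(pred, true)))
  counts <- table(true = factor(true, levels = labels),
                  pred = factor(pred, levels = labels))
  counts <- unclass(counts)
  rs <- rowSums(counts)
  prop <- counts / ifelse(rs == 0, NA, rs)
  structure(list(counts = counts, prop = prop, labels = labels,
                 zero_support = labels[rs == 0]),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, digits = 2, ...) {
  cat("<confusion_matrix> row-normalized (rows = true classes)\n")
  print(round(x$prop, digits))
  if (length(x$zero_support))
    cat("zero-support rows:", paste(x$zero_support, collapse = ", "), "\n")
  invisible(x)
}

#' Epoch misclassification pattern
#'
#' Among misclassified windows, the fraction assigned to an epoch preceding
#' vs. following the true one (epoch order FREE < DELAY < MOVE < HOLD), plus
#' the named confusions DELAY-as-MOVE, FREE-as-MOVE and HOLD-as-FREE as
#' fractions of all errors.
#'
#' @param pred_epoch,true_epoch Epoch label vectors.
#' @return A list: `n_errors`, `preceding`, `subsequent`,
#'   `delay_as_move`, `free_as_move`, `hold_as_free`.  Fractions are `NA`
#'   when there are no misclassifications.
#' @export
error_pattern <- function(pred_epoch, true_epoch) {
  pr <- match(pred_epoch, EPOCHS)
  tr <- match(true_epoch, EPOCHS)
  if (anyNA(pr) || anyNA(tr)) stopf("labels must be task epochs")
  mis <- pr != tr
  n <- sum(mis)
  if (n == 0)
    return(list(n_errors = 0L, preceding = NA_real_, subsequent = NA_real_,
                delay_as_move = NA_real_, free_as_move = NA_real_,
                hold_as_free = NA_real_))
  list(n_errors = n,
       preceding = mean(pr[mis] < tr[mis]),
       subsequent = mean(pr[mis] > tr[mis]),
       delay_as_move = sum(true_epoch == "DELAY" & pred_epoch == "MOVE") / n,
       free_as_move = sum(true_epoch == "FREE" & pred_epoch == "MOVE") / n,
       hold_as_free = sum(true_epoch == "HOLD" & pred_epoch == "FREE") / n)
}

#' Workspace geometry of the nine reach targets
#'
#' Targets lie at eye level in the horizontal plane along three directions
#' (version angles -15, 0, +15 degrees) and three radial distances from the
#' eyes (10, 15, 25 cm), position `(d * sin(v), d * cos(v))`.  Target ids
#' follow [target_grid()]: near left/centre/right, then intermediate, then
#' far.
#'
#' @return A list of class `target_geometry`: `positions`
#'   (`data.frame(target_id, direction, depth, x_cm, y_cm)`) and `distances`
#'   (9 x 9 Euclidean distance matrix).
#' @export
target_geometry <- function() {
  grid <- target_grid()
  version_deg <- grid$direction * 15
  dist_cm <- c(10, 15, 25)[grid$depth]
  x <- dist_cm * sin(version_deg * pi / 180)
  y <- dist_cm * cos(version_deg * pi / 180)
  pos <- cbind(grid, data.frame(x_cm = x, y_cm = y))
  structure(list(positions = pos,
                 distances = as.matrix(dist(cbind(x, y)))),
            class = "target_geometry")
}

#' Correlation between target confusion and physical target distance
#'
#' Tests whether two targets are confused more often the closer they are in
#' the workspace: the row-normalized confusion probabilities are symmetrized
#' (`(P[i,j] + P[j,i]) / 2`) and correlated with the pairwise Euclidean
#' distances over the 36 unordered target pairs.
#'
#' @param conf A `confusion_matrix` over the 9 targets (or a 9 x 9 counts
#'   matrix).
#' @param geom A [target_geometry()] (default).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A list: `estimate` (correlation coefficient), `p_value`, `n_pairs`.
#'   Both are `NA` (with `absent = TRUE`) when all off-diagonal confusion is
#'   zero.
#' @export
distance_confusion_correlation <- function(conf, geom = target_geometry(),
                                           method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- if (inherits(conf, "confusion_matrix")) conf$prop else {
    rs <- rowSums(conf)
    conf / ifelse(rs == 0, NA, rs)
  }
  if (!all(dim(m) == c(9, 9))) stopf("need a 9 x 9 target confusion matrix")
  sym <- (m + t(m)) / 2
  up <- upper.tri(sym)
  p <- sym[up]
  d <- geom$distances[up]
  ok <- !is.na(p)
  if (!any(p[ok] > 0))
    return(list(estimate = NA_real_, p_value = NA_real_, n_pairs = sum(ok),
                absent = TRUE))
  if (sd(p[ok]) == 0)  # uniform confusion: no distance signal by definition
    return(list(estimate = 0, p_value = 1, n_pairs = sum(ok),
                absent = FALSE))
  ct <- suppressWarnings(cor.test(p[ok], d[ok], method = method))
  list(estimate = unname(ct$estimate), p_value = ct$p.value,
       n_pairs = sum(ok), absent = FALSE)
}

# Cluster scatter/separation ratio underlying the Davies-Bouldin index:
# R_ij = (S_i + S_j) / M_ij with S the mean Euclidean distance of cluster
# members to their centroid and M the distance between centroids.
cluster_stats <- function(features, labels) {
  labs <- unique(labels)
  cent <- matrix(0, length(labs), ncol(features))
  for (k in seq_along(labs))
    cent[k, ] <- colMeans(features[labels == labs[k], , drop = FALSE])
  S <- vapply(seq_along(labs), function(k) {
    x <- features[labels == labs[k], , drop = FALSE]
    mean(sqrt(rowSums(sweep(x, 2, cent[k, ])^2)))
  }, numeric(1))
  list(labels = labs, centroids = cent, S = S)
}

#' Pairwise cluster overlap ratio (R metric)
#'
#' @param features Numeric matrix (samples x dimensions).
#' @param labels Cluster labels per sample.
#' @param a,b The two cluster labels to compare.
#' @return `R = (S_a + S_b) / M_ab`; `Inf` when the centroids coincide.
#' @export
r_metric <- function(features, labels, a, b) {
  cs <- cluster_stats(as.matrix(features), labels)
  ia <- match(a, cs$labels)
  ib <- match(b, cs$labels)
  if (is.na(ia) || is.na(ib)) stopf("cluster label not present")
  M <- sqrt(sum((cs$centroids[ia, ] - cs$centroids[ib, ])^2))
  if (M == 0) return(Inf)
  (cs$S[ia] + cs$S[ib]) / M
}

#' Davies-Bouldin index
#'
#' `DBI = mean_i max_{j != i} (S_i + S_j) / M_ij`: higher values mean more
#' overlap between clusters (a harder decoding problem).  Coincident
#' centroids yield an infinite index, reported as `Inf` with a warning.
#'
#' @param features Numeric matrix (samples x dimensions).
#' @param labels Cluster labels per sample; >= 2 clusters, each with >= 2
#'   samples.
#' @return The index (scalar); the pairwise `R` matrix is attached as
#'   attribute `"R"`.
#' @export
dbi <- function(features, labels) {
  features <- as.matrix(features)
  tab <- table(labels)
  if (length(tab) < 2) stopf("need at least 2 clusters")
  if (any(tab < 2)) stopf("every cluster needs at least 2 samples")
  cs <- cluster_stats(features, labels)
  K <- length(cs$labels)
  M <- as.matrix(dist(cs$centroids))
  R <- outer(cs$S, cs$S, "+") / M
  diag(R) <- NA
  if (any(!is.finite(R[!is.na(R)])))
    warning("coincident centroids: infinite R values")
  out <- mean(apply(R, 1, max, na.rm = TRUE))
  attr(out, "R") <- R
  out
}

#' Bootstrap distribution of the Davies-Bouldin index over unit subsets
#'
#' Resamples the neural population without replacement -- either 90% of the
#' units (`mode = "fraction"`) or a fixed number (`mode = "fixed"`, default
#' 40) -- and recomputes the index on each subset.  Infinite values are
#' excluded from summaries with a recorded count.
#'
#' @param features Samples x units matrix of firing rates.
#' @param labels Cluster labels per sample.
#' @param mode `"fraction"` or `"fixed"`.
#' @param fraction Fraction of units kept (default 0.9).
#' @param n_fixed Fixed unit count (default 40).
#' @param n_boot Bootstrap samples (default 1000).
#' @param seed Integer seed.
#' @return Numeric vector of DBI values (length `n_boot`); the number of
#'   infinite values excluded is attached as attribute `"n_infinite"`.
#' @export
bootstrap_dbi <- function(features, labels, mode = c("fraction", "fixed"),
                          fraction = 0.9, n_fixed = 40, n_boot = 1000,
                          seed = 1) {
  mode <- match.arg(mode)
  features <- as.matrix(features)
  U <- ncol(features)
  keep <- if (mode == "fraction") max(1L, round(fraction * U)) else n_fixed
  if (keep > U)
    stopf("cannot sample %d units from a population of %d", keep, U)
  set.seed(mix_seed(seed, 909))
  vals <- vapply(seq_len(n_boot), function(b) {
    cols <- sample.int(U, keep)
    suppressWarnings(as.numeric(dbi(features[, cols, drop = FALSE], labels)))
  }, numeric(1))
  n_inf <- sum(!is.finite(vals))
  out <- vals
  attr(out, "n_infinite") <- n_inf
  out
}

#' Mean firing rates per trial and epoch
#'
#' One sample per (trial, epoch): the vector of per-unit mean firing rates
#' (sp/s) within that epoch of that trial.  These are the feature vectors
#' for the clustering indices and the 2-D embedding.
#'
#' @param data A `spike_dataset`.
#' @param trial_ids Trials to include (default all).
#' @param standardize Standardize each unit (column) to zero mean / unit SD
#'   (constant columns become 0)?  Default `FALSE`.
#' @return A list: `features` (samples x units), `labels`
#'   (`data.frame(trial_id, target_id, epoch)`).
#' @export
epoch_rate_features <- function(data, trial_ids = NULL, standardize = FALSE) {
  stopifnot(inherits(data, "spike_dataset"))
  trials <- data$trials
  if (!is.null(trial_ids)) trials <- trials[trials$trial_id %in% trial_ids, ]
  U <- data$n_units
  sp <- split(data$spikes[, c("unit_id", "time_ms")],
              factor(data$spikes$trial_id, levels = trials$trial_id))
  feats <- matrix(0, nrow(trials) * 4, U)
  labs <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    eb <- epoch_bounds(tr)
    s <- sp[[i]]
    for (e in 1:4) {
      row <- (i - 1) * 4 + e
      if (!is.null(s) && nrow(s)) {
        sel <- s$time_ms >= eb$start_ms[e] & s$time_ms < eb$end_ms[e]
        cnt <- tabulate(s$unit_id[sel], nbins = U)
      } else cnt <- numeric(U)
      feats[row, ] <- cnt / (eb$end_ms[e] - eb$start_ms[e]) * 1000
    }
    labs[[i]] <- data.frame(trial_id = tr$trial_id, target_id = tr$target_id,
                            epoch = EPOCHS)
  }
  if (standardize) {
    feats <- scale(feats)
    feats[is.nan(feats)] <- 0
    attr(feats, "scaled:center") <- NULL
    attr(feats, "scaled:scale") <- NULL
  }
  list(features = feats, labels = do.call(rbind, labs))
}

#' Nonparametric comparison of two accuracy (or index) samples
#'
#' Wilcoxon rank test over bootstrap/fold samples; `paired = TRUE` uses the
#' signed-rank variant.
#'
#' @param a,b Numeric samples (each n >= 3).
#' @param paired Paired test? Default `FALSE`.
#' @return The p-value.
#' @export
compare_conditions <- function(a, b, paired = FALSE) {
  if (length(a) < 3 || length(b) < 3)
    stopf("need at least 3 samples per condition")
  if (paired && length(a) != length(b))
    stopf("paired comparison needs equal-length samples")
  if (identical(as.numeric(a), as.numeric(b))) return(1)
  suppressWarnings(wilcox.test(a, b, paired = paired, exact = FALSE))$p.value
}
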