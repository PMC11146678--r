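# Self-contained single-layer LSTM classifier: input layer -> LSTM hidden
# layer -> dropout -> fully connected -> softmax, trained by truncated BPTT
# over full windows with Adam.  Sized for desk-scale populations; all state
# is plain R matrices so results are exactly reproducible given a seed.

sigmoid <- function(x) 1 / (1 + exp(-x))

lstm_init <- function(n_input, n_hidden, n_classes, seed) {
  set.seed(mix_seed(seed, 701))
  r <- 1 / sqrt(n_hidden)
  H4 <- 4L * n_hidden
  b <- numeric(H4)
  b[(n_hidden + 1):(2 * n_hidden)] <- 1  # forget-gate bias
  list(Wx = matrix(runif(H4 * n_input, -r, r), H4, n_input),
       Wh = matrix(runif(H4 * n_hidden, -r, r), H4, n_hidden),
       b = b,
       Wy = matrix(runif(n_classes * n_hidden, -r, r), n_classes, n_hidden),
       by = numeric(n_classes),
       n_hidden = n_hidden, n_input = n_input, n_classes = n_classes)
}

# Forward pass over a batch.  x: array (U x T x B).  Returns the final
# hidden state and, when `cache = TRUE`, everything BPTT needs.
lstm_forward <- function(par, x, cache = FALSE) {
  H <- par$n_hidden
  Tt <- dim(x)[2]
  B <- dim(x)[3]
  h <- matrix(0, H, B)
  cc <- matrix(0, H, B)
  caches <- if (cache) vector("list", Tt) else NULL
  idx_i <- 1:H; idx_f <- H + 1:H; idx_g <- 2 * H + 1:H; idx_o <- 3 * H + 1:H
  for (t in seq_len(Tt)) {
    xt <- matrix(x[, t, ], dim(x)[1], B)
    z <- par$Wx %*% xt + par$Wh %*% h + par$b
    gi <- sigmoid(z[idx_i, , drop = FALSE])
    gf <- sigmoid(z[idx_f, , drop = FALSE])
    gg <- tanh(z[idx_g, , drop = FALSE])
    go <- sigmoid(z[idx_o, , drop = FALSE])
    c_prev <- cc
    h_prev <- h
    cc <- gf * c_prev + gi * gg
    tc <- tanh(cc)
    h <- go * tc
    if (cache)
      caches[[t]] <- list(xt = xt, gi = gi, gf = gf, gg = gg, go = go,
                          c_prev = c_prev, h_prev = h_prev, tc = tc)
  }
  list(h = h, caches = caches)
}

lstm_loss_grad <- function(par, x, y, dropout, rng_active) {
  H <- par$n_hidden
  B <- dim(x)[3]
  fw <- lstm_forward(par, x, cache = TRUE)
  hfin <- fw$h
  if (dropout > 0 && rng_active) {
    mask <- matrix(stats::rbinom(H * B, 1, 1 - dropout), H, B) / (1 - dropout)
  } else mask <- matrix(1, H, B)
  hd <- hfin * mask
  logits <- par$Wy %*% hd + par$by
  logits <- sweep(logits, 2, apply(logits, 2, max))
  p <- exp(logits)
  p <- sweep(p, 2, colSums(p), "/")
  loss <- -mean(log(pmax(p[cbind(y, seq_len(B))], 1e-12)))

  dlog <- p
  dlog[cbind(y, seq_len(B))] <- dlog[cbind(y, seq_len(B))] - 1
  dlog <- dlog / B
  g <- list(Wy = dlog %*% t(hd), by = rowSums(dlog),
            Wx = matrix(0, nrow(par$Wx), ncol(par$Wx)),
            Wh = matrix(0, nrow(par$Wh), ncol(par$Wh)),
            b = numeric(length(par$b)))
  dh <- (t(par$Wy) %*% dlog) * mask
  dc <- matrix(0, H, B)
  idx_i <- 1:H; idx_f <- H + 1:H; idx_g <- 2 * H + 1:H; idx_o <- 3 * H + 1:H
  for (t in rev(seq_along(fw$caches))) {
    cs <- fw$caches[[t]]
    dgo <- dh * cs$tc
    dc <- dc + dh * cs$go * (1 - cs$tc^2)
    dgi <- dc * cs$gg
    dgg <- dc * cs$gi
    dgf <- dc * cs$c_prev
    dz <- rbind(dgi * cs$gi * (1 - cs$gi),
                dgf * cs$gf * (1 - cs$gf),
                dgg * (1 - cs$gg^2),
                dgo * cs$go * (1 - cs$go))
    g$Wx <- g$Wx + dz %*% t(cs$xt)
    g$Wh <- g$Wh + dz %*% t(cs$h_prev)
    g$b <- g$b + rowSums(dz)
    dh <- t(par$Wh) %*% dz
    dc <- dc * cs$gf
  }
  list(loss = loss, grad = g)
}

lstm_val_loss <- function(par, x, y) {
  B <- dim(x)[3]
  h <- lstm_forward(par, x)$h
  logits <- par$Wy %*% h + par$by
  logits <- sweep(logits, 2, apply(logits, 2, max))
  p <- exp(logits)
  p <- sweep(p, 2, colSums(p), "/")
  -mean(log(pmax(p[cbind(y, seq_len(B))], 1e-12)))
}

#' Fit the LSTM baseline classifier
#'
#' Single hidden LSTM layer, dropout on its final hidden state, a fully
#' connected output layer (one unit per class) and a softmax; trained with
#' Adam on full-window spike-count inputs.  A held-out validation set is
#' monitored and the parameters with the lowest validation loss are
#' retained.  Defaults follow the reference architecture (200 hidden units,
#' learning rate 1e-2, minibatch 1,024, dropout 0.1); the minibatch is
#' reduced automatically when the training set is smaller.
#'
#' @param x Training inputs: array `units x bins x samples` (e.g.
#'   `lstm_windows()$x`) or a list of `units x bins` matrices.
#' @param y Integer class labels in `1..n_classes`.
#' @param n_classes Number of classes (output layer size).
#' @param val_x,val_y Validation inputs/labels (required; typically one
#'   held-out trial).
#' @param n_hidden Hidden units (default 200).
#' @param lr Initial Adam learning rate (default 1e-2).
#' @param batch_size Minibatch size (default 1024, auto-reduced).
#' @param dropout Dropout probability on the final hidden state
#'   (default 0.1).
#' @param n_steps Optimization steps (default 200).
#' @param val_every Validate every this many steps (default 10).
#' @param seed Integer seed.
#' @return A list of class `reach_lstm`: best parameters, loss histories
#'   and the hyperparameters used.
#' @export
lstm_fit <- function(x, y, n_classes, val_x, val_y, n_hidden = 200,
                     lr = 1e-2, batch_size = 1024, dropout = 0.1,
                     n_steps = 200, val_every = 10, seed = 1) {
  if (is.list(x) && !is.array(x)) x <- simplify2array(x)
  if (is.list(val_x) && !is.array(val_x)) val_x <- simplify2array(val_x)
  y <- as.integer(y)
  val_y <- as.integer(val_y)
  missing <- setdiff(seq_len(n_classes), y)
  if (length(missing))
    stopf("class(es) absent from the training fold: %s",
          paste(missing, collapse = ", "))
  n <- dim(x)[3]
  B <- min(batch_size, n)
  par <- lstm_init(dim(x)[1], n_hidden, n_classes, seed)
  mstate <- lapply(par[1:5], function(p) p * 0)
  vstate <- mstate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- par
  best_val <- Inf
  train_hist <- numeric(0)
  val_hist <- data.frame(step = integer(0), loss = numeric(0))
  set.seed(mix_seed(seed, 702))
  for (step in seq_len(n_steps)) {
    idx <- if (B < n) sample.int(n, B) else seq_len(n)
    lg <- lstm_loss_grad(par, x[, , idx, drop = FALSE], y[idx], dropout, TRUE)
    train_hist <- c(train_hist, lg$loss)
    for (nm in names(mstate)) {
      mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * lg$grad[[nm]]
      vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * lg$grad[[nm]]^2
      mhat <- mstate[[nm]] / (1 - b1^step)
      vhat <- vstate[[nm]] / (1 - b2^step)
      par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
    if (step %% val_every == 0 || step == n_steps) {
      vl <- lstm_val_loss(par, val_x, val_y)
      val_hist <- rbind(val_hist, data.frame(step = step, loss = vl))
      if (vl < best_val) {
        best_val <- vl
        best <- par
      }
    }
  }
  structure(list(par = best, best_val_loss = best_val,
                 train_loss = train_hist, val_loss = val_hist,
                 n_classes = n_classes,
                 hyper = list(n_hidden = n_hidden, lr = lr,
                              batch_size = B, dropout = dropout,
                              n_steps = n_steps, seed = seed)),
            class = "reach_lstm")
}

#' @export
predict.reach_lstm <- function(object, newdata, ...) {
  x <- newdata
  if (is.list(x) && !is.array(x)) x <- simplify2array(x)
  h <- lstm_forward(object$par, x)$h
  logits <- object$par$Wy %*% h + object$par$by
  max.col(t(logits), ties.method = "first")
}
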