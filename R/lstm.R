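# Minimal LSTM regressor for sequence-shaped feature curves, written as a
# batch-vectorised forward/backward pass (states are n-by-H matrices, so one
# epoch is a handful of matrix products per timestep) trained with Adam on
# the mean-squared error.  The reference layer stack this emulates is
# sequence input -> LSTM -> dense -> dropout -> dense(1); dropout is omitted
# and sizes are desk-scale by default (the curve is mean-pooled to
# `pool_len` steps, hidden size `hidden`).

sigmoid <- function(z) 1 / (1 + exp(-z))

# mean-pool each row of X to `len` chunks (pooling matrix keeps chunk order)
pool_rows <- function(X, len) {
  p <- ncol(X)
  idx <- pmin(ceiling(seq_len(p) / (p / len)), len)
  M <- matrix(0, p, len)
  M[cbind(seq_len(p), idx)] <- 1
  M <- sweep(M, 2, colSums(M), "/")
  X %*% M
}

lstm_init <- function(hidden, seed) {
  with_seed(seed, {
    s <- 0.5 / sqrt(hidden)
    list(
      wx = matrix(runif(4 * hidden, -s, s), 1, 4 * hidden),
      wh = matrix(runif(4 * hidden * hidden, -s, s), hidden, 4 * hidden),
      b = {
        b <- rep(0, 4 * hidden)
        b[seq_len(hidden) + hidden] <- 1  # forget-gate bias at 1
        b
      },
      wy = matrix(runif(hidden, -s, s), hidden, 1),
      by = 0
    )
  })
}

lstm_forward <- function(par, X, keep = FALSE) {
  n <- nrow(X); L <- ncol(X); H <- nrow(par$wy)
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  cache <- if (keep) vector("list", L)
  gi <- seq_len(H); gf <- gi + H; go <- gf + H; gg <- go + H
  for (t in seq_len(L)) {
    z <- X[, t] %*% par$wx + h %*% par$wh
    z <- sweep(z, 2, par$b, "+")
    i <- sigmoid(z[, gi, drop = FALSE]); f <- sigmoid(z[, gf, drop = FALSE])
    o <- sigmoid(z[, go, drop = FALSE]); g <- tanh(z[, gg, drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h_prev <- h
    h <- o * tc
    if (keep) cache[[t]] <- list(i = i, f = f, o = o, g = g, c = cc, tc = tc,
                                 c_prev = c_prev, h_prev = h_prev)
  }
  yhat <- as.numeric(h %*% par$wy + par$by)
  list(yhat = yhat, h = h, cache = cache)
}

lstm_backward <- function(par, X, y, fw) {
  n <- nrow(X); L <- ncol(X); H <- nrow(par$wy)
  gi <- seq_len(H); gf <- gi + H; go <- gf + H; gg <- go + H
  dy <- 2 * (fw$yhat - y) / n
  grads <- list(wx = 0 * par$wx, wh = 0 * par$wh, b = 0 * par$b,
                wy = t(fw$h) %*% dy, by = sum(dy))
  dh <- outer(dy, as.numeric(par$wy))
  dc <- matrix(0, n, H)
  for (t in rev(seq_len(L))) {
    cc <- fw$cache[[t]]
    do <- dh * cc$tc
    dc <- dc + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g; dg <- dc * cc$i; df <- dc * cc$c_prev
    dz <- cbind(di * cc$i * (1 - cc$i), df * cc$f * (1 - cc$f),
                do * cc$o * (1 - cc$o), dg * (1 - cc$g^2))
    grads$wx <- grads$wx + X[, t] %*% dz
    grads$wh <- grads$wh + t(cc$h_prev) %*% dz
    grads$b <- grads$b + colSums(dz)
    dh <- dz %*% t(par$wh)
    dc <- dc * cc$f
  }
  grads
}

lstm_fit <- function(X, y, hidden = 16, pool_len = 32, epochs = 40,
                     lr = 0.01, seed = 1) {
  pool_len <- min(pool_len, ncol(X))
  Xp <- pool_rows(X, pool_len)
  xm <- mean(Xp); xs <- max(sd(Xp), 1e-12)
  Xp <- (Xp - xm) / xs
  ym <- mean(y); ys <- max(sd(y), 1e-12)
  yn <- (y - ym) / ys
  par <- lstm_init(hidden, seed)
  m <- lapply(par, function(p) 0 * p)
  v <- lapply(par, function(p) 0 * p)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0
  for (e in seq_len(epochs)) {
    fw <- lstm_forward(par, Xp, keep = TRUE)
    gr <- lstm_backward(par, Xp, yn, fw)
    step <- step + 1
    for (nm in names(par)) {
      m[[nm]] <- b1 * m[[nm]] + (1 - b1) * gr[[nm]]
      v[[nm]] <- b2 * v[[nm]] + (1 - b2) * gr[[nm]]^2
      mhat <- m[[nm]] / (1 - b1^step)
      vhat <- v[[nm]] / (1 - b2^step)
      par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(par = par, pool_len = pool_len, xm = xm, xs = xs, ym = ym, ys = ys)
}

lstm_predict <- function(fit, Xnew) {
  Xp <- (pool_rows(Xnew, fit$pool_len) - fit$xm) / fit$xs
  lstm_forward(fit$par, Xp)$yhat * fit$ys + fit$ym
}
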