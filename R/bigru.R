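## Batched GRU forward/backward (same padding/masking conventions as the
## LSTM in bilstm.R; gradients verified numerically in the test suite).

init_gru_params <- function(input_dim, hidden_dim) {
  list(Wx = glorot(input_dim, 3 * hidden_dim),
       Wh = glorot(hidden_dim, 3 * hidden_dim),
       b = numeric(3 * hidden_dim))
}

gru_forward <- function(X, mask, params) {
  Tm <- length(X); B <- nrow(X[[1]]); H <- nrow(params$Wh)
  iz <- 1:H; ir <- (H + 1):(2 * H); inn <- (2 * H + 1):(3 * H)
  h <- matrix(0, B, H)
  cache <- vector("list", Tm); hs <- vector("list", Tm)
  for (t in seq_len(Tm)) {
    ax <- sweep(X[[t]] %*% params$Wx, 2, params$b, `+`)
    ah <- h %*% params$Wh
    z <- sigmoid(ax[, iz, drop = FALSE] + ah[, iz, drop = FALSE])
    r <- sigmoid(ax[, ir, drop = FALSE] + ah[, ir, drop = FALSE])
    n <- tanh(ax[, inn, drop = FALSE] + r * ah[, inn, drop = FALSE])
    m <- mask[, t]
    h_prev <- h
    h <- ((1 - z) * n + z * h_prev) * m
    cache[[t]] <- list(z = z, r = r, n = n, h_prev = h_prev, ahn = ah[, inn, drop = FALSE],
                       m = m, x = X[[t]])
    hs[[t]] <- h
  }
  list(h = hs, cache = cache)
}

gru_backward <- function(fwd, dH, params) {
  cache <- fwd$cache
  Tm <- length(cache); B <- nrow(cache[[1]]$h_prev); H <- ncol(cache[[1]]$h_prev)
  iz <- 1:H; ir <- (H + 1):(2 * H); inn <- (2 * H + 1):(3 * H)
  dWx <- params$Wx * 0; dWh <- params$Wh * 0; db <- numeric(3 * H)
  dX <- vector("list", Tm)
  dh_carry <- matrix(0, B, H)
  for (t in Tm:1) {
    cc <- cache[[t]]
    dh <- (dH[[t]] + dh_carry) * cc$m
    dz <- dh * (cc$h_prev - cc$n)
    dn <- dh * (1 - cc$z)
    dh_prev <- dh * cc$z
    ## n = tanh(x Wxn + bn + r * ahn) with ahn = h_prev Whn
    dan <- dn * (1 - cc$n^2)
    dr <- dan * cc$ahn
    dahn <- dan * cc$r
    daz <- dz * cc$z * (1 - cc$z)
    dar <- dr * cc$r * (1 - cc$r)
    da <- cbind(daz, dar, dan)
    dWx <- dWx + crossprod(cc$x, da)
    db <- db + colSums(da)
    dX[[t]] <- da %*% t(params$Wx)
    dah <- cbind(daz, dar, dahn)
    dWh <- dWh + crossprod(cc$h_prev, dah)
    dh_prev <- dh_prev + dah %*% t(params$Wh)
    dh_carry <- dh_prev
  }
  list(Wx = dWx, Wh = dWh, b = db, dX = dX)
}
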