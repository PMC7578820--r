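## Batched LSTM forward/backward passes in base R matrix algebra. Sequences
## are right-padded; the mask zeroes hidden/cell states at padded positions
## so the time-reversed (right-context) pass starts fresh when it crosses
## from padding into a real sequence. Gradients are exact BPTT, checked
## against numerical differentiation in the test suite.

glorot <- function(nr, nc) {
  r <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -r, r), nr, nc)
}

init_lstm_params <- function(input_dim, hidden_dim) {
  b <- numeric(4 * hidden_dim)
  b[(hidden_dim + 1):(2 * hidden_dim)] <- 1 # forget-gate bias
  list(Wx = glorot(input_dim, 4 * hidden_dim),
       Wh = glorot(hidden_dim, 4 * hidden_dim),
       b = b)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## X: list over t of B x D inputs; mask: B x T (1 = real position)
lstm_forward <- function(X, mask, params) {
  Tm <- length(X); B <- nrow(X[[1]]); H <- nrow(params$Wh)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  cache <- vector("list", Tm)
  hs <- vector("list", Tm)
  idx <- list(i = 1:H, f = (H + 1):(2 * H), g = (2 * H + 1):(3 * H), o = (3 * H + 1):(4 * H))
  for (t in seq_len(Tm)) {
    z <- X[[t]] %*% params$Wx + h %*% params$Wh
    z <- sweep(z, 2, params$b, `+`)
    gi <- sigmoid(z[, idx$i, drop = FALSE])
    gf <- sigmoid(z[, idx$f, drop = FALSE])
    gg <- tanh(z[, idx$g, drop = FALSE])
    go <- sigmoid(z[, idx$o, drop = FALSE])
    c_raw <- gf * cc + gi * gg
    tc <- tanh(c_raw)
    m <- mask[, t]
    h_prev <- h; c_prev <- cc
    h <- (go * tc) * m
    cc <- c_raw * m
    cache[[t]] <- list(gi = gi, gf = gf, gg = gg, go = go, tc = tc,
                       h_prev = h_prev, c_prev = c_prev, m = m, x = X[[t]])
    hs[[t]] <- h
  }
  list(h = hs, cache = cache, idx = idx)
}

## dH: list over t of B x H gradients wrt the (masked) hidden outputs
lstm_backward <- function(fwd, dH, params) {
  cache <- fwd$cache; idx <- fwd$idx
  Tm <- length(cache); B <- nrow(cache[[1]]$h_prev); H <- ncol(cache[[1]]$h_prev)
  dWx <- array(0, dim(params$Wx)); dWh <- array(0, dim(params$Wh)); db <- numeric(length(params$b))
  dX <- vector("list", Tm)
  dh_carry <- matrix(0, B, H); dc_carry <- matrix(0, B, H)
  for (t in Tm:1) {
    cc <- cache[[t]]
    dh <- (dH[[t]] + dh_carry) * cc$m
    do_ <- dh * cc$tc
    dc_raw <- dc_carry * cc$m + dh * cc$go * (1 - cc$tc^2)
    di <- dc_raw * cc$gg
    dg <- dc_raw * cc$gi
    df <- dc_raw * cc$c_prev
    dz <- matrix(0, B, 4 * H)
    dz[, idx$i] <- di * cc$gi * (1 - cc$gi)
    dz[, idx$f] <- df * cc$gf * (1 - cc$gf)
    dz[, idx$g] <- dg * (1 - cc$gg^2)
    dz[, idx$o] <- do_ * cc$go * (1 - cc$go)
    dWx <- dWx + crossprod(cc$x, dz)
    dWh <- dWh + crossprod(cc$h_prev, dz)
    db <- db + colSums(dz)
    dX[[t]] <- dz %*% t(params$Wx)
    dh_carry <- dz %*% t(params$Wh)
    dc_carry <- dc_raw * cc$gf
  }
  list(Wx = dWx, Wh = dWh, b = db, dX = dX)
}

## reverse each row's first len_b elements along time (pads stay in place)
reverse_time <- function(X, lens) {
  Tm <- length(X)
  out <- lapply(X, function(m) m)
  for (b in seq_along(lens)) {
    L <- lens[b]
    if (L > 1) for (t in seq_len(L)) out[[t]][b, ] <- X[[L - t + 1L]][b, ]
  }
  out
}

## ---- Adam optimizer over a flat named list of arrays ----------------------
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      clip = NULL) {
  if (!is.null(clip)) {
    nrm <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
    if (is.finite(nrm) && nrm > clip) grads <- lapply(grads, function(g) g * (clip / nrm))
  }
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
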