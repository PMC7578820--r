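## Linear-chain CRF layer: log-partition (forward algorithm), Viterbi
## decoding, and the batched forward-backward pass that supplies emission /
## transition gradients during training. Scores are additive:
##   score(y) = start[y_1] + sum_t e[t, y_t] + sum_{t>1} T[y_{t-1}, y_t] + stop[y_T]

#' Log-partition function of a linear-chain CRF
#'
#' Computes `log sum_y exp(score(y))` over all label sequences by the
#' forward algorithm in log space.
#'
#' @param emissions Numeric matrix, positions x labels.
#' @param transitions Square numeric matrix, labels x labels
#'   (`transitions[i, j]` scores label `i` followed by `j`).
#' @param start,stop Optional per-label boundary scores (default zero).
#' @return Scalar log-partition value.
#' @export
crf_log_partition <- function(emissions, transitions, start = NULL, stop = NULL) {
  ck <- check_crf_dims(emissions, transitions, start, stop)
  alpha <- emissions[1, ] + ck$start
  nt <- nrow(emissions)
  if (nt > 1) {
    for (t in 2:nt) {
      alpha <- emissions[t, ] + apply(alpha + transitions, 2, logsumexp)
    }
  }
  logsumexp(alpha + ck$stop)
}

#' Viterbi decoding of a linear-chain CRF
#'
#' Returns a maximum-score label sequence and its score. Ties are broken
#' toward the smallest label index at each dynamic-programming step, so a
#' fully tied score surface yields the all-first-label sequence.
#'
#' @inheritParams crf_log_partition
#' @return List with `path` (integer label indices) and `score`.
#' @export
viterbi_decode <- function(emissions, transitions, start = NULL, stop = NULL) {
  ck <- check_crf_dims(emissions, transitions, start, stop)
  nt <- nrow(emissions); k <- ncol(emissions)
  delta <- emissions[1, ] + ck$start
  back <- matrix(0L, nt, k)
  if (nt > 1) {
    for (t in 2:nt) {
      m <- delta + transitions # m[j, k]: best coming from j
      best <- apply(m, 2, which.max) # first index on ties
      delta <- emissions[t, ] + m[cbind(best, seq_len(k))]
      back[t, ] <- best
    }
  }
  last <- which.max(delta + ck$stop)
  path <- integer(nt)
  path[nt] <- last
  if (nt > 1) for (t in nt:2) path[t - 1L] <- back[t, path[t]]
  list(path = path, score = unname(delta[last] + ck$stop[last]))
}

check_crf_dims <- function(emissions, transitions, start, stop) {
  if (!is.matrix(emissions) || nrow(emissions) < 1) stopf("emissions must be a positions x labels matrix")
  k <- ncol(emissions)
  if (!is.matrix(transitions) || any(dim(transitions) != k))
    stopf("transitions must be %d x %d to match emissions", k, k)
  start <- start %||% numeric(k); stop <- stop %||% numeric(k)
  if (length(start) != k || length(stop) != k) stopf("start/stop must have one score per label")
  list(start = start, stop = stop)
}

## ---- batched forward-backward over padded sequences -----------------------
## emis: list over t of B x K matrices; lens: B sequence lengths; gold:
## B x T integer label matrix (0 where padded). Returns loss (sum of
## negative log-likelihoods) and gradients wrt emissions/transitions/
## start/stop. Alphas are propagated in log space through a scaled
## exp-matrix product (exact up to float rounding).
crf_batch_nll <- function(emis, lens, gold, trans, start, stop) {
  Tmax <- length(emis); B <- nrow(emis[[1]]); K <- ncol(trans)
  expTr <- exp(trans)
  lse_step <- function(alpha) {
    cmax <- apply(alpha, 1, max)
    log(pmax(exp(alpha - cmax) %*% expTr, .Machine$double.xmin)) + cmax
  }
  alphas <- vector("list", Tmax)
  alpha <- sweep(emis[[1]], 2, start, `+`)
  alphas[[1]] <- alpha
  if (Tmax > 1) for (t in 2:Tmax) {
    upd <- lse_step(alpha) + emis[[t]]
    act <- lens >= t
    alpha[act, ] <- upd[act, , drop = FALSE]
    alphas[[t]] <- alpha
  }
  ## logZ per row uses alpha at that row's final position
  fin <- alphas[[1]]
  for (b in seq_len(B)) fin[b, ] <- alphas[[lens[b]]][b, ]
  logZ <- apply(sweep(fin, 2, stop, `+`), 1, logsumexp)

  ## betas (filled only where t <= len)
  betas <- vector("list", Tmax)
  beta <- matrix(rep(stop, each = B), B, K)
  betas[[Tmax]] <- beta
  if (Tmax > 1) for (t in (Tmax - 1):1) {
    nxt <- betas[[t + 1]] + emis[[t + 1]]
    cmax <- apply(nxt, 1, max)
    upd <- log(pmax(exp(nxt - cmax) %*% t(expTr), .Machine$double.xmin)) + cmax
    beta <- upd
    beta[lens == t, ] <- matrix(rep(stop, each = sum(lens == t)), ncol = K)
    betas[[t]] <- beta
  }

  d_emis <- vector("list", Tmax)
  d_trans <- matrix(0, K, K)
  gold_score <- numeric(B)
  for (t in seq_len(Tmax)) {
    act <- lens >= t
    logm <- alphas[[t]] + betas[[t]] - logZ
    g <- exp(logm)
    g[!act, ] <- 0
    ## subtract gold one-hot
    gb <- which(act)
    g[cbind(gb, gold[gb, t])] <- g[cbind(gb, gold[gb, t])] - 1
    d_emis[[t]] <- g
    gold_score[gb] <- gold_score[gb] + emis[[t]][cbind(gb, gold[gb, t])]
    if (t > 1) {
      A <- alphas[[t - 1]] - logZ # B x K, active rows only meaningful
      Yv <- emis[[t]] + betas[[t]]
      mY <- apply(Yv, 1, max)
      U <- exp(A + mY); V <- exp(Yv - mY)
      U[!act, ] <- 0; V[!act, ] <- 0
      d_trans <- d_trans + crossprod(U, V) * expTr
      ## empirical gold transitions
      if (length(gb)) {
        prev <- gold[gb, t - 1L]; cur <- gold[gb, t]
        for (i in seq_along(gb)) {
          d_trans[prev[i], cur[i]] <- d_trans[prev[i], cur[i]] - 1
          gold_score[gb[i]] <- gold_score[gb[i]] + trans[prev[i], cur[i]]
        }
      }
    }
  }
  y1 <- gold[, 1]
  m1 <- exp(alphas[[1]] + betas[[1]] - logZ)
  d_start <- colSums(m1) - tabulate(y1, K)
  gold_score <- gold_score + start[y1]
  yl <- gold[cbind(seq_len(B), lens)]
  mfin <- exp(fin + matrix(rep(stop, each = B), B, K) - logZ)
  d_stop <- colSums(mfin) - tabulate(yl, K)
  gold_score <- gold_score + stop[yl]

  list(loss = sum(logZ - gold_score),
       d_emis = d_emis, d_trans = d_trans, d_start = d_start, d_stop = d_stop,
       logZ = logZ)
}
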