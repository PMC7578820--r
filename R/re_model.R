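## Dual-attention BiGRU relation classifier. Characters (with boundary
## markers inserted around the two mentions) are embedded and run through a
## BiGRU; word-level attention pools the states into an instance vector;
## sentence-level attention pools the instances that share an entity pair
## (degenerating to identity for singleton bags); a linear softmax layer
## scores the relation labels. Predictions are masked to the candidate's
## schema-admissible labels, so no emitted relation can violate the schema.

.RE_MARKERS <- c("<h>", "</h>", "<t>", "</t>")

#' Hyperparameters for the relation classifier
#'
#' The reference description fixes the architecture (character embeddings,
#' BiGRU, word- and sentence-level attention) but not its sizes; these
#' defaults are conventional for the scale of the synthetic corpora.
#'
#' @param embedding_dim Character embedding dimension.
#' @param hidden_dim GRU hidden units per direction.
#' @param batch_size Instances per minibatch (bags are kept whole).
#' @param learning_rate Adam learning rate.
#' @param epochs Training epochs.
#' @param clip Global gradient-norm clip.
#' @param val_fraction Held-out fraction used for best-epoch selection.
#' @param seed RNG seed.
#' @return A `dstkg_re_hp` list.
#' @export
re_hyperparams <- function(embedding_dim = 64L, hidden_dim = 48L, batch_size = 32L,
                           learning_rate = 2e-3, epochs = 8L, clip = 5,
                           val_fraction = 0.1, seed = 1L) {
  structure(list(embedding_dim = as.integer(embedding_dim), hidden_dim = as.integer(hidden_dim),
                 batch_size = as.integer(batch_size), learning_rate = learning_rate,
                 epochs = as.integer(epochs), clip = clip, val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "dstkg_re_hp")
}

## candidate -> token sequence with mention boundary markers
re_tokens <- function(candidate) {
  cs <- chars(candidate$sentence)
  h <- candidate$head; t <- candidate$tail
  marks <- data.frame(pos = c(h$start, h$end, t$start, t$end),
                      tok = .RE_MARKERS[c(1, 2, 3, 4)],
                      stringsAsFactors = FALSE)
  marks <- marks[order(-marks$pos, -seq_len(4)), ]
  toks <- as.list(cs)
  for (i in seq_len(4)) {
    p <- marks$pos[i]
    toks <- append(toks, marks$tok[i], after = p)
  }
  unlist(toks)
}

re_encode <- function(candidate, vocab) {
  toks <- re_tokens(candidate)
  ids <- vocab[toks]
  ids[is.na(ids)] <- vocab[["<unk>"]]
  unname(ids)
}

init_re_params <- function(vocab_size, hp, n_labels) {
  H2 <- 2 * hp$hidden_dim
  list(E = glorot(vocab_size, hp$embedding_dim),
       f.Wx = glorot(hp$embedding_dim, 3 * hp$hidden_dim),
       f.Wh = glorot(hp$hidden_dim, 3 * hp$hidden_dim), f.b = numeric(3 * hp$hidden_dim),
       b.Wx = glorot(hp$embedding_dim, 3 * hp$hidden_dim),
       b.Wh = glorot(hp$hidden_dim, 3 * hp$hidden_dim), b.b = numeric(3 * hp$hidden_dim),
       Wa = glorot(H2, H2), ba = numeric(H2), va = stats::runif(H2, -0.1, 0.1),
       Ws = glorot(H2, H2), bs = numeric(H2), vs = stats::runif(H2, -0.1, 0.1),
       Wo = glorot(H2, n_labels), bo = numeric(n_labels))
}

## batched instance forward: ids B x Tmax -> instance vectors S (B x 2H)
re_forward_instances <- function(params, ids, lens, hp) {
  B <- nrow(ids); Tm <- ncol(ids)
  mask <- outer(lens, seq_len(Tm), `>=`) * 1
  X <- lapply(seq_len(Tm), function(t) params$E[ids[, t], , drop = FALSE])
  pf <- list(Wx = params$f.Wx, Wh = params$f.Wh, b = params$f.b)
  pb <- list(Wx = params$b.Wx, Wh = params$b.Wh, b = params$b.b)
  fwd <- gru_forward(X, mask, pf)
  Xr <- reverse_time(X, lens)
  bwd <- gru_forward(Xr, mask, pb)
  hb <- reverse_time(bwd$h, lens)
  H <- lapply(seq_len(Tm), function(t) cbind(fwd$h[[t]], hb[[t]]))
  U <- lapply(H, function(h) tanh(sweep(h %*% params$Wa, 2, params$ba, `+`)))
  scores <- vapply(U, function(u) as.vector(u %*% params$va), numeric(B))
  scores <- matrix(scores, B) # B x Tm
  scores[mask == 0] <- -Inf
  A <- exp(scores - apply(scores, 1, max))
  A <- A / rowSums(A)
  S <- matrix(0, B, 2 * hp$hidden_dim)
  for (t in seq_len(Tm)) S <- S + A[, t] * H[[t]]
  list(S = S, A = A, H = H, U = U, fwd = fwd, bwd = bwd, X = X, Xr = Xr,
       mask = mask, pf = pf, pb = pb)
}

re_backward_instances <- function(params, fw, dS, ids, lens, hp) {
  Tm <- length(fw$H); B <- nrow(ids)
  g <- lapply(params, function(p) p * 0)
  dH <- lapply(seq_len(Tm), function(t) fw$A[, t] * dS)
  dA <- vapply(seq_len(Tm), function(t) rowSums(dS * fw$H[[t]]), numeric(B))
  dA <- matrix(dA, B)
  dscore <- fw$A * (dA - rowSums(fw$A * dA))
  for (t in seq_len(Tm)) {
    g$va <- g$va + as.vector(crossprod(fw$U[[t]], dscore[, t]))
    dpre <- (dscore[, t] %o% params$va) * (1 - fw$U[[t]]^2)
    g$Wa <- g$Wa + crossprod(fw$H[[t]], dpre)
    g$ba <- g$ba + colSums(dpre)
    dH[[t]] <- dH[[t]] + dpre %*% t(params$Wa)
  }
  Hd <- hp$hidden_dim
  dHf <- lapply(dH, function(m) m[, 1:Hd, drop = FALSE])
  dHb <- lapply(dH, function(m) m[, (Hd + 1):(2 * Hd), drop = FALSE])
  bf <- gru_backward(fw$fwd, dHf, fw$pf)
  bb <- gru_backward(fw$bwd, reverse_time(dHb, lens), fw$pb)
  g$f.Wx <- bf$Wx; g$f.Wh <- bf$Wh; g$f.b <- bf$b
  g$b.Wx <- bb$Wx; g$b.Wh <- bb$Wh; g$b.b <- bb$b
  dXb <- reverse_time(bb$dX, lens)
  for (t in seq_len(Tm)) {
    act <- lens >= t
    if (!any(act)) next
    dxc <- (bf$dX[[t]] + dXb[[t]])[act, , drop = FALSE]
    tmp <- rowsum(dxc, group = ids[act, t])
    rid <- as.integer(rownames(tmp))
    g$E[rid, ] <- g$E[rid, ] + tmp
  }
  g
}

## sentence(bag)-level attention over instance vectors
bag_attention <- function(params, S_bag) {
  u <- tanh(sweep(S_bag %*% params$Ws, 2, params$bs, `+`))
  sc <- as.vector(u %*% params$vs)
  b <- exp(sc - max(sc)); b <- b / sum(b)
  list(vec = as.vector(crossprod(S_bag, b)), beta = b, u = u)
}

bag_attention_backward <- function(params, S_bag, att, dvec, g) {
  k <- nrow(S_bag)
  dS <- att$beta %o% dvec
  dbeta <- as.vector(S_bag %*% dvec)
  dsc <- att$beta * (dbeta - sum(att$beta * dbeta))
  g$vs <- g$vs + as.vector(crossprod(att$u, dsc))
  dpre <- (dsc %o% params$vs) * (1 - att$u^2)
  g$Ws <- g$Ws + crossprod(S_bag, dpre)
  g$bs <- g$bs + colSums(dpre)
  dS <- dS + dpre %*% t(params$Ws)
  list(dS = dS, g = g)
}

#' Train the dual-attention BiGRU relation classifier
#'
#' Instances are bagged by (document, head surface, tail surface, label);
#' word-level attention pools characters into an instance vector and
#' sentence-level attention pools each bag, which is scored with a softmax
#' over the labels present in the corpus (including the `no_relation` class
#' for co-occurring pairs without an asserted relation).
#'
#' @param candidates Candidates carrying a `gold_label` field (see the
#'   acceptance suite's use of gold corpora; [generate_candidates()] output
#'   labeled by matching gold relations).
#' @param hp [re_hyperparams()].
#' @param verbose Print per-epoch progress.
#' @return A `dstkg_re_model` with parameters, vocabulary, label set and
#'   training history.
#' @export
train_re <- function(candidates, hp = re_hyperparams(), verbose = FALSE) {
  labs <- vapply(candidates, function(cd) cd$gold_label %||% NA_character_, "")
  if (anyNA(labs)) stopf("all candidates must carry gold_label")
  labels <- sort(unique(labs))
  if (length(labels) < 2) stopf("need >= 2 distinct labels to train")
  set.seed(hp$seed)
  toks <- unique(unlist(lapply(candidates, re_tokens)))
  vocab <- stats::setNames(seq_along(toks) + 2L, toks)
  vocab <- c("<pad>" = 1L, "<unk>" = 2L, vocab)
  params <- init_re_params(length(vocab), hp, length(labels))
  enc <- lapply(candidates, re_encode, vocab = vocab)
  y <- match(labs, labels)
  bag_key <- vapply(candidates, function(cd)
    paste(cd$doc_id, cd$head$surface, cd$tail$surface, cd$gold_label, sep = "\r"), "")
  bags <- split(seq_along(candidates), bag_key)
  ## held-out bags for best-epoch selection
  n_val <- max(1L, round(length(bags) * hp$val_fraction))
  val_idx <- sample.int(length(bags), n_val)
  train_bags <- bags[-val_idx]; val_bags <- bags[val_idx]
  state <- adam_init(params)
  best <- list(acc = -Inf, params = params)
  history <- list()

  run_bags <- function(bag_list, train = TRUE) {
    ## reads/writes `params` and `state` in the enclosing training frame
    ## group bags into minibatches of roughly batch_size instances
    sizes <- lengths(bag_list)
    ord <- if (train) sample.int(length(bag_list)) else seq_along(bag_list)
    grp <- split(ord, ceiling(cumsum(sizes[ord]) / hp$batch_size))
    total_loss <- 0; n_ok <- 0; n_tot <- 0
    for (gset in grp) {
      inst <- unlist(bag_list[gset])
      lens <- lengths(enc[inst])
      B <- length(inst); Tm <- max(lens)
      ids <- matrix(1L, B, Tm)
      for (b in seq_len(B)) ids[b, seq_len(lens[b])] <- enc[[inst[b]]]
      fw <- re_forward_instances(params, ids, lens, hp)
      dS <- fw$S * 0
      g <- NULL
      if (train) g <- lapply(params, function(p) p * 0)
      ptr <- 0L
      for (bi in gset) {
        k <- length(bag_list[[bi]])
        rows <- ptr + seq_len(k); ptr <- ptr + k
        Sb <- fw$S[rows, , drop = FALSE]
        att <- bag_attention(params, Sb)
        logits <- as.vector(att$vec %*% params$Wo + params$bo)
        pr <- exp(logits - max(logits)); pr <- pr / sum(pr)
        yy <- y[inst[rows[1]]]
        total_loss <- total_loss - log(max(pr[yy], 1e-12))
        n_tot <- n_tot + 1L; n_ok <- n_ok + (which.max(pr) == yy)
        if (train) {
          dlog <- pr; dlog[yy] <- dlog[yy] - 1
          g$Wo <- g$Wo + att$vec %o% dlog
          g$bo <- g$bo + dlog
          dvec <- as.vector(params$Wo %*% dlog)
          bb <- bag_attention_backward(params, Sb, att, dvec, g)
          g <- bb$g
          dS[rows, ] <- dS[rows, ] + bb$dS
        }
      }
      if (train) {
        gi <- re_backward_instances(params, fw, dS, ids, lens, hp)
        for (nm in names(gi)) g[[nm]] <- g[[nm]] + gi[[nm]]
        upd <- adam_step(params, g, state, hp$learning_rate, clip = hp$clip)
        params <<- upd$params; state <<- upd$state
      }
    }
    c(loss = total_loss, acc = n_ok / max(1, n_tot))
  }

  for (epoch in seq_len(hp$epochs)) {
    tr <- run_bags(train_bags, train = TRUE)
    va <- run_bags(val_bags, train = FALSE)
    if (va["acc"] > best$acc + 1e-9) best <- list(acc = va[["acc"]], params = params)
    history[[epoch]] <- data.frame(epoch = epoch, loss = tr[["loss"]], val_acc = va[["acc"]])
    if (verbose) message(sprintf("epoch %d  loss %.2f  val acc %.4f", epoch, tr[["loss"]], va[["acc"]]))
  }
  structure(list(params = best$params, vocab = vocab, labels = labels, hp = hp,
                 best_val_acc = best$acc, history = do.call(rbind, history)),
            class = "dstkg_re_model")
}

#' Classify a relation candidate
#'
#' Scores are renormalized over the candidate's schema-admissible labels
#' (optionally plus `no_relation`), so the prediction always passes
#' [validate_edge()]; the returned instance's head/tail follow the
#' predicted label's canonical schema direction.
#'
#' @param model A `dstkg_re_model`.
#' @param candidate A `dstkg_re_candidate`.
#' @param allow_null Also admit the `no_relation` class.
#' @return A `dstkg_relation` list: `doc_id`, `head`, `tail`, `label`,
#'   `confidence` in `[0, 1]`, `provenance` (`"classifier"`, or `"rule"`
#'   when the admissible set was a singleton).
#' @export
classify <- function(model, candidate, allow_null = FALSE) {
  allowed <- candidate$allowed
  if (!nrow(allowed)) stopf("candidate has an empty admissible label set")
  if (nrow(allowed) == 1 && !allow_null) {
    ## a singleton admissible set forces the outcome; no model consulted
    h <- candidate$head; t <- candidate$tail
    if (allowed$direction == "reversed") { tmp <- h; h <- t; t <- tmp }
    return(structure(list(doc_id = candidate$doc_id, head = h, tail = t,
                          label = allowed$label, confidence = 1,
                          provenance = "rule"),
                     class = "dstkg_relation"))
  }
  pool <- allowed$label
  if (allow_null) pool <- c(pool, "no_relation")
  pool_ids <- match(pool, model$labels)
  if (all(is.na(pool_ids))) stopf("none of the admissible labels are known to the model")
  enc <- re_encode(candidate, model$vocab)
  fw <- re_forward_instances(model$params, matrix(enc, 1), length(enc), model$hp)
  att <- bag_attention(model$params, fw$S)
  logits <- as.vector(att$vec %*% model$params$Wo + model$params$bo)
  sc <- ifelse(is.na(pool_ids), -Inf, logits[ifelse(is.na(pool_ids), 1L, pool_ids)])
  pr <- exp(sc - max(sc)); pr <- pr / sum(pr)
  pick <- which.max(pr)
  label <- pool[pick]
  if (label == "no_relation") {
    return(structure(list(doc_id = candidate$doc_id, head = candidate$head,
                          tail = candidate$tail, label = "no_relation",
                          confidence = unname(pr[pick]), provenance = "classifier"),
                     class = "dstkg_relation"))
  }
  dir <- allowed$direction[allowed$label == label]
  h <- candidate$head; t <- candidate$tail
  if (dir == "reversed") { tmp <- h; h <- t; t <- tmp }
  structure(list(doc_id = candidate$doc_id, head = h, tail = t, label = label,
                 confidence = unname(pr[pick]),
                 provenance = if (nrow(allowed) == 1 && !allow_null) "rule" else "classifier"),
            class = "dstkg_relation")
}
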