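## Character-level BiLSTM-CRF named-entity recognition over the 12 span
## types. Each character is embedded and concatenated with its static
## features (POS one-hot, relative position, dictionary flags); forward and
## backward LSTM passes produce the left/right context whose concatenation
## feeds a linear emission layer and a CRF over BIO labels.

#' Hyperparameters for the sequence tagger
#'
#' Defaults follow the reference configuration: character embedding
#' dimension 100, batch size 50, learning rate 4e-4, dropout 0.5. The
#' remaining knobs (hidden size, epochs, gradient clip, early-stopping
#' patience) are unspecified there and exposed here with conventional
#' values.
#'
#' @param embedding_dim Character embedding dimension.
#' @param hidden_dim LSTM hidden units per direction.
#' @param batch_size Sentences per minibatch.
#' @param learning_rate Adam learning rate.
#' @param dropout Dropout probability on the BiLSTM output.
#' @param epochs Training epochs (0 returns the initialized model).
#' @param clip Global gradient-norm clip.
#' @param patience Early-stopping patience in epochs without validation
#'   F1 improvement.
#' @param seed RNG seed; training is deterministic given it.
#' @return A `dstkg_ner_hp` list.
#' @export
ner_hyperparams <- function(embedding_dim = 100L, hidden_dim = 100L, batch_size = 50L,
                            learning_rate = 4e-4, dropout = 0.5, epochs = 20L,
                            clip = 5, patience = 5L, seed = 1L) {
  structure(list(embedding_dim = as.integer(embedding_dim), hidden_dim = as.integer(hidden_dim),
                 batch_size = as.integer(batch_size), learning_rate = learning_rate,
                 dropout = dropout, epochs = as.integer(epochs), clip = clip,
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "dstkg_ner_hp")
}

ner_label_set <- function() {
  c("O", as.vector(rbind(paste0("B-", span_types()), paste0("I-", span_types()))))
}

## sentence records: text, doc offset, features, gold BIO labels
prepare_ner_sentences <- function(docs, dictionaries, segmenter, with_gold = TRUE) {
  out <- list()
  for (d in seq_along(docs)) {
    doc <- docs[[d]]
    sents <- split_sentences(doc$text)
    for (i in seq_len(nrow(sents))) {
      s <- sents$start[i]; e <- sents$end[i]
      txt <- sents$text[i]
      labels <- NULL
      if (with_gold) {
        m <- doc$mentions
        inside <- m$start >= s & m$end <= e
        if (any(m$start < e & m$end > s & !inside))
          stopf("mention crosses sentence boundary in %s", doc$patient_id)
        ms <- m[inside, , drop = FALSE]
        ms$start <- ms$start - s; ms$end <- ms$end - s
        labels <- spans_to_bio(nchar(txt), ms)
      }
      out[[length(out) + 1L]] <- list(doc = d, offset = s, text = txt,
                                      feats = featurize(txt, dictionaries, segmenter),
                                      labels = labels)
    }
  }
  out
}

## static (non-learned) feature matrix: POS one-hot + relative position +
## dictionary flags
static_features <- function(feats) {
  n <- nrow(feats)
  pos <- matrix(0, n, length(.POS_LEVELS))
  pos[cbind(seq_len(n), match(feats$pos_tag, .POS_LEVELS))] <- 1
  dict <- as.matrix(feats[, grep("^dict_", names(feats)), drop = FALSE]) * 1
  cbind(pos, if (n) feats$position / max(1L, n - 1L) else numeric(), dict)
}

init_ner_params <- function(vocab_size, input_dim, hp, k) {
  list(E = glorot(vocab_size, hp$embedding_dim),
       f.Wx = glorot(input_dim, 4 * hp$hidden_dim), f.Wh = glorot(hp$hidden_dim, 4 * hp$hidden_dim),
       f.b = init_lstm_params(1, hp$hidden_dim)$b,
       b.Wx = glorot(input_dim, 4 * hp$hidden_dim), b.Wh = glorot(hp$hidden_dim, 4 * hp$hidden_dim),
       b.b = init_lstm_params(1, hp$hidden_dim)$b,
       Wout = glorot(2 * hp$hidden_dim, k), bout = numeric(k),
       trans = matrix(0, k, k), start = numeric(k), stop = numeric(k))
}

encode_chars <- function(text, vocab) {
  ids <- vocab[chars(text)]
  ids[is.na(ids)] <- vocab[["<unk>"]]
  unname(ids)
}

## forward pass over a padded batch; returns emissions and caches
ner_forward <- function(params, ids, statics, lens, hp, drop_masks = NULL) {
  B <- nrow(ids); Tm <- ncol(ids)
  mask <- outer(lens, seq_len(Tm), `>=`) * 1
  X <- lapply(seq_len(Tm), function(t)
    cbind(params$E[ids[, t], , drop = FALSE], statics[[t]]))
  pf <- list(Wx = params$f.Wx, Wh = params$f.Wh, b = params$f.b)
  pb <- list(Wx = params$b.Wx, Wh = params$b.Wh, b = params$b.b)
  fwd <- lstm_forward(X, mask, pf)
  Xr <- reverse_time(X, lens)
  bwd <- lstm_backward_ready <- lstm_forward(Xr, mask, pb)
  hb <- reverse_time(bwd$h, lens)
  H <- lapply(seq_len(Tm), function(t) cbind(fwd$h[[t]], hb[[t]]))
  if (!is.null(drop_masks)) H <- lapply(seq_len(Tm), function(t) H[[t]] * drop_masks[[t]])
  emis <- lapply(H, function(h) sweep(h %*% params$Wout, 2, params$bout, `+`))
  list(emis = emis, H = H, fwd = fwd, bwd = bwd, X = X, Xr = Xr, mask = mask,
       pf = pf, pb = pb)
}

ner_backward <- function(params, fw, d_emis, ids, lens, hp, drop_masks = NULL) {
  Tm <- length(fw$emis); B <- nrow(ids)
  De <- hp$embedding_dim
  g <- lapply(params, function(p) p * 0)
  dH <- vector("list", Tm)
  for (t in seq_len(Tm)) {
    g$Wout <- g$Wout + crossprod(fw$H[[t]], d_emis[[t]])
    g$bout <- g$bout + colSums(d_emis[[t]])
    dh <- d_emis[[t]] %*% t(params$Wout)
    if (!is.null(drop_masks)) dh <- dh * drop_masks[[t]]
    dH[[t]] <- dh
  }
  Hd <- hp$hidden_dim
  dHf <- lapply(dH, function(m) m[, 1:Hd, drop = FALSE])
  dHb <- lapply(dH, function(m) m[, (Hd + 1):(2 * Hd), drop = FALSE])
  bf <- lstm_backward(fw$fwd, dHf, fw$pf)
  bb <- lstm_backward(fw$bwd, reverse_time(dHb, lens), fw$pb)
  g$f.Wx <- bf$Wx; g$f.Wh <- bf$Wh; g$f.b <- bf$b
  g$b.Wx <- bb$Wx; g$b.Wh <- bb$Wh; g$b.b <- bb$b
  dXb <- reverse_time(bb$dX, lens)
  for (t in seq_len(Tm)) {
    act <- lens >= t
    if (!any(act)) next
    dxc <- (bf$dX[[t]] + dXb[[t]])[act, 1:De, drop = FALSE]
    idx <- ids[act, t]
    tmp <- rowsum(dxc, group = idx)
    rid <- as.integer(rownames(tmp))
    g$E[rid, ] <- g$E[rid, ] + tmp
  }
  g
}

#' Train the BiLSTM-CRF tagger
#'
#' Minimizes the negative CRF log-likelihood with Adam and gradient-norm
#' clipping; validation entity-level F1 is computed each epoch and the best
#' checkpoint is returned (early stopping after `patience` stale epochs).
#' Fully deterministic for a fixed hyperparameter seed.
#'
#' @param train_docs,val_docs Gold documents (e.g. from [generate_corpus()]
#'   via [split_corpus()]).
#' @param hp [ner_hyperparams()].
#' @param dictionaries,segmenter Feature resources (see [featurize()]).
#' @param verbose Print per-epoch progress.
#' @return A `dstkg_ner_model` with fitted parameters, vocabulary, label
#'   set, and a per-epoch `history` data.frame.
#' @export
train_ner <- function(train_docs, val_docs, hp = ner_hyperparams(),
                      dictionaries = load_dictionaries(),
                      segmenter = default_segmenter(), verbose = FALSE) {
  if (!length(train_docs)) stopf("empty training set")
  set.seed(hp$seed)
  sents <- prepare_ner_sentences(train_docs, dictionaries, segmenter)
  sents <- Filter(function(s) nchar(s$text) > 0, sents)
  cs <- unique(unlist(lapply(sents, function(s) s$feats$char)))
  vocab <- stats::setNames(seq_along(cs) + 2L, cs)
  vocab <- c("<pad>" = 1L, "<unk>" = 2L, vocab)
  labels <- ner_label_set()
  lab_id <- stats::setNames(seq_along(labels), labels)
  static_dim <- ncol(static_features(sents[[1]]$feats))
  params <- init_ner_params(length(vocab), hp$embedding_dim + static_dim, hp, length(labels))
  for (s in seq_along(sents)) {
    sents[[s]]$ids <- encode_chars(sents[[s]]$text, vocab)
    sents[[s]]$static <- static_features(sents[[s]]$feats)
    sents[[s]]$y <- unname(lab_id[sents[[s]]$labels])
  }
  model <- structure(list(params = params, vocab = vocab, labels = labels,
                          hp = hp, dictionaries = dictionaries, segmenter = segmenter,
                          history = data.frame()),
                     class = "dstkg_ner_model")
  if (hp$epochs == 0L) return(model)

  state <- adam_init(params)
  best <- list(f1 = -Inf, params = params)
  stale <- 0L
  history <- list()
  val_gold <- lapply(val_docs, function(d) d$mentions[, c("start", "end", "sem_type")])
  for (epoch in seq_len(hp$epochs)) {
    ord <- order(vapply(sents, function(s) length(s$ids), 0L) +
                   stats::runif(length(sents))) # length-sorted with random ties
    batches <- split(ord, ceiling(seq_along(ord) / hp$batch_size))
    batches <- batches[sample.int(length(batches))]
    total_loss <- 0
    for (bt in batches) {
      bs <- sents[bt]
      lens <- vapply(bs, function(s) length(s$ids), 0L)
      B <- length(bs); Tm <- max(lens)
      ids <- matrix(1L, B, Tm)
      gold <- matrix(1L, B, Tm)
      statics <- lapply(seq_len(Tm), function(t) matrix(0, B, static_dim))
      for (b in seq_len(B)) {
        ids[b, seq_len(lens[b])] <- bs[[b]]$ids
        gold[b, seq_len(lens[b])] <- bs[[b]]$y
        for (t in seq_len(lens[b])) statics[[t]][b, ] <- bs[[b]]$static[t, ]
      }
      drop_masks <- if (hp$dropout > 0)
        lapply(seq_len(Tm), function(t)
          matrix(stats::rbinom(B * 2 * hp$hidden_dim, 1, 1 - hp$dropout), B) / (1 - hp$dropout))
      fw <- ner_forward(params, ids, statics, lens, hp, drop_masks)
      nll <- crf_batch_nll(fw$emis, lens, gold, params$trans, params$start, params$stop)
      total_loss <- total_loss + nll$loss
      g <- ner_backward(params, fw, nll$d_emis, ids, lens, hp, drop_masks)
      g$trans <- nll$d_trans; g$start <- nll$d_start; g$stop <- nll$d_stop
      upd <- adam_step(params, g, state, hp$learning_rate, clip = hp$clip)
      params <- upd$params; state <- upd$state
    }
    model$params <- params
    val_f1 <- NA_real_
    if (length(val_docs)) {
      pred <- lapply(val_docs, function(d) tag_document(model, d$text))
      val_f1 <- unname(ner_metrics(val_gold, pred)$micro["f1"])
      if (val_f1 > best$f1 + 1e-9) { best <- list(f1 = val_f1, params = params); stale <- 0L }
      else stale <- stale + 1L
    } else best <- list(f1 = NA_real_, params = params)
    history[[epoch]] <- data.frame(epoch = epoch, loss = total_loss, val_f1 = val_f1)
    if (verbose) message(sprintf("epoch %d  loss %.2f  val F1 %.4f", epoch, total_loss, val_f1))
    if (length(val_docs) && stale >= hp$patience) break
  }
  model$params <- best$params
  model$best_val_f1 <- best$f1
  model$history <- do.call(rbind, history)
  model
}

#' Tag a document with a trained model
#'
#' Splits the text into sentences, decodes each with Viterbi, converts BIO
#' labels to spans (orphan `I-` repaired to `B-`), and reports mentions in
#' 0-based half-open document offsets.
#'
#' @param model A `dstkg_ner_model`.
#' @param text Document text.
#' @return Mention data.frame (`id`, `start`, `end`, `surface`, `sem_type`).
#' @export
tag_document <- function(model, text) {
  empty <- data.frame(id = integer(), start = integer(), end = integer(),
                      surface = character(), sem_type = character(), stringsAsFactors = FALSE)
  if (!nzchar(text)) return(empty)
  sents <- prepare_ner_sentences(list(list(patient_id = "q", text = text,
                                           mentions = empty)),
                                 model$dictionaries, model$segmenter, with_gold = FALSE)
  sents <- Filter(function(s) nchar(s$text) > 0, sents)
  if (!length(sents)) return(empty)
  hp <- model$hp; params <- model$params
  lens <- vapply(sents, function(s) nchar(s$text), 0L)
  B <- length(sents); Tm <- max(lens)
  static_dim <- ncol(static_features(sents[[1]]$feats))
  ids <- matrix(1L, B, Tm)
  statics <- lapply(seq_len(Tm), function(t) matrix(0, B, static_dim))
  for (b in seq_len(B)) {
    v <- encode_chars(sents[[b]]$text, model$vocab)
    ids[b, seq_len(lens[b])] <- v
    st <- static_features(sents[[b]]$feats)
    for (t in seq_len(lens[b])) statics[[t]][b, ] <- st[t, ]
  }
  fw <- ner_forward(params, ids, statics, lens, hp)
  rows <- list()
  for (b in seq_len(B)) {
    e <- do.call(rbind, lapply(seq_len(lens[b]), function(t) fw$emis[[t]][b, ]))
    path <- viterbi_decode(e, params$trans, params$start, params$stop)$path
    sp <- bio_to_spans(model$labels[path], repair = TRUE)
    if (nrow(sp)) {
      sp$start <- sp$start + sents[[b]]$offset
      sp$end <- sp$end + sents[[b]]$offset
      rows[[length(rows) + 1L]] <- sp
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$start), , drop = FALSE]
  data.frame(id = seq_len(nrow(out)), start = out$start, end = out$end,
             surface = vapply(seq_len(nrow(out)), function(i) substr0(text, out$start[i], out$end[i]), ""),
             sem_type = out$sem_type, stringsAsFactors = FALSE)
}
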