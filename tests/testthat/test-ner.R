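test_that("featurize produces one record per character with the four families", {
  seg <- default_segmenter()
  dicts <- load_dictionaries()
  expect_equal(nrow(featurize("", dicts, seg)), 0)
  f <- featurize("行胃镜检查。", dicts, seg)
  expect_equal(nrow(f), 6)
  expect_equal(f$position, 0:5)
  ## characters inside the dictionary term get the test-dictionary flag
  expect_true(all(f$dict_test[2:5]))
  expect_false(f$dict_test[1])
  ## POS of a character equals the POS of its containing word
  expect_equal(f$pos_tag[2:5], rep("n", 4))
  expect_equal(f$pos_tag[6], "w")
})

test_that("crf_log_partition and viterbi_decode match brute-force enumeration", {
  set.seed(42)
  for (i in 1:40) {
    nt <- sample(1:6, 1); k <- sample(2:5, 1)
    e <- matrix(rnorm(nt * k, sd = 2), nt, k)
    tr <- matrix(rnorm(k * k), k, k)
    st <- rnorm(k); sp <- rnorm(k)
    b <- brute_crf(e, tr, st, sp)
    expect_equal(crf_log_partition(e, tr, st, sp), b$logZ, tolerance = 1e-8)
    v <- viterbi_decode(e, tr, st, sp)
    expect_equal(v$score, b$best_score, tolerance = 1e-8)
    expect_equal(v$path, b$best_path)
  }
})

test_that("crf closed forms, shift invariance and tie-breaks hold", {
  expect_equal(crf_log_partition(matrix(0, 1, 5), matrix(0, 5, 5)), log(5))
  set.seed(1)
  e <- matrix(rnorm(12), 3, 4); tr <- matrix(rnorm(16), 4, 4)
  e2 <- e; e2[2, ] <- e2[2, ] + 3.7
  expect_equal(crf_log_partition(e2, tr), crf_log_partition(e, tr) + 3.7)
  ## log-sum-exp dominance and decisive emissions
  v <- viterbi_decode(e, tr)
  expect_gte(crf_log_partition(e, tr), v$score)
  e3 <- matrix(-10, 4, 3); e3[cbind(1:4, c(2, 1, 3, 2))] <- 10
  expect_equal(viterbi_decode(e3, matrix(0, 3, 3))$path, c(2, 1, 3, 2))
  ## fully tied scores: first-index sequence
  expect_equal(viterbi_decode(matrix(0, 3, 4), matrix(0, 4, 4))$path, rep(1L, 3))
  expect_error(crf_log_partition(matrix(0, 2, 3), matrix(0, 4, 4)), "transitions")
})

test_that("analytic gradients of the BiLSTM-CRF match numerical differentiation", {
  set.seed(4)
  hp <- ner_hyperparams(embedding_dim = 5, hidden_dim = 4, dropout = 0)
  K <- 7; V <- 8; S <- 13
  params <- dstkg:::init_ner_params(V, 5 + S, hp, K)
  lens <- c(6L, 3L, 5L); B <- 3; Tm <- 6
  ids <- matrix(1L, B, Tm)
  for (b in 1:B) ids[b, 1:lens[b]] <- sample(2:V, lens[b], replace = TRUE)
  statics <- lapply(1:Tm, function(t) matrix(rnorm(B * S) * 0.3, B, S))
  gold <- matrix(1L, B, Tm)
  for (b in 1:B) gold[b, 1:lens[b]] <- sample(1:K, lens[b], replace = TRUE)
  loss_fn <- function(params) {
    fw <- dstkg:::ner_forward(params, ids, statics, lens, hp)
    dstkg:::crf_batch_nll(fw$emis, lens, gold, params$trans, params$start, params$stop)$loss
  }
  fw <- dstkg:::ner_forward(params, ids, statics, lens, hp)
  nll <- dstkg:::crf_batch_nll(fw$emis, lens, gold, params$trans, params$start, params$stop)
  g <- dstkg:::ner_backward(params, fw, nll$d_emis, ids, lens, hp)
  g$trans <- nll$d_trans; g$start <- nll$d_start; g$stop <- nll$d_stop
  for (nm in names(params)) {
    p0 <- params[[nm]]
    for (ii in sample(length(p0), min(6, length(p0)))) {
      eps <- 1e-5
      pp <- params
      pp[[nm]][ii] <- p0[ii] + eps; lp <- loss_fn(pp)
      pp[[nm]][ii] <- p0[ii] - eps; lm <- loss_fn(pp)
      expect_equal(g[[nm]][ii], (lp - lm) / (2 * eps), tolerance = 1e-4, info = nm)
    }
  }
})

test_that("decoding gold emissions recovers gold mentions exactly (F1 = 1)", {
  co <- small_corpus()[1:10]
  labels <- dstkg:::ner_label_set()
  pred <- lapply(co, function(d) {
    bio <- spans_to_bio(nchar(d$text), d$mentions)
    e <- matrix(-10, length(bio), length(labels))
    e[cbind(seq_along(bio), match(bio, labels))] <- 10
    path <- viterbi_decode(e, matrix(0, length(labels), length(labels)))$path
    bio_to_spans(labels[path], repair = TRUE)
  })
  gold <- lapply(co, function(d) d$mentions[, c("start", "end", "sem_type")])
  expect_equal(unname(ner_metrics(gold, pred)$micro["f1"]), 1)
})

test_that("training is seeded, zero-epoch safe, and rejects empty input", {
  co <- small_corpus()
  sp <- split_corpus(co[1:14], c(0.8, 0.1, 0.1), seed = 1)
  hp0 <- ner_hyperparams(embedding_dim = 12, hidden_dim = 10, epochs = 0, seed = 5)
  m0a <- train_ner(sp$train, sp$validation, hp0)
  m0b <- train_ner(sp$train, sp$validation, hp0)
  expect_identical(m0a$params, m0b$params) # initialization, seeded
  hp2 <- ner_hyperparams(embedding_dim = 12, hidden_dim = 10, batch_size = 16,
                         learning_rate = 0.01, dropout = 0.2, epochs = 2, seed = 5)
  m1 <- train_ner(sp$train, sp$validation, hp2)
  m2 <- train_ner(sp$train, sp$validation, hp2)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  expect_error(train_ner(list(), sp$validation, hp2), "empty training set")
  ## decoding contract: empty text, and offsets in document coordinates
  expect_equal(nrow(tag_document(m1, "")), 0)
  pred <- tag_document(m1, sp$train[[1]]$text)
  if (nrow(pred)) {
    expect_identical(pred$surface, vapply(seq_len(nrow(pred)), function(i)
      substr(sp$train[[1]]$text, pred$start[i] + 1, pred$end[i]), ""))
  }
})
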