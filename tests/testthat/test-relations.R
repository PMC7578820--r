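mk_mentions <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(seq_along(rows), function(i)
    data.frame(id = i, start = rows[[i]][[1]], end = rows[[i]][[2]],
               surface = rows[[i]][[3]], sem_type = rows[[i]][[4]],
               stringsAsFactors = FALSE)))
  df
}

test_that("split_sentences keeps delimiters and reconstructs the text", {
  expect_equal(nrow(split_sentences("A。B！C")), 3)
  expect_equal(nrow(split_sentences("no terminal punctuation")), 1)
  expect_equal(nrow(split_sentences("")), 0)
  for (d in small_corpus()[1:20]) {
    s <- split_sentences(d$text)
    expect_equal(paste(s$text, collapse = ""), d$text)
    expect_identical(s$text, vapply(seq_len(nrow(s)), function(i)
      substr(d$text, s$start[i] + 1, s$end[i]), ""))
  }
})

test_that("candidate generation follows type-pair constraints", {
  txt <- "行胃镜检查见恶心、呕吐。"
  m <- mk_mentions(list(1L, 5L, "胃镜检查", "test"),
                   list(6L, 8L, "恶心", "symptom"),
                   list(9L, 11L, "呕吐", "symptom"))
  cands <- generate_candidates(txt, m)
  expect_length(cands, 2)
  for (cd in cands) expect_true(all(cd$allowed$label %in% c("TeRS", "TeAS")))
  expect_true(all(vapply(cands, function(cd) is.na(cd$auto_label), NA)))
  ## single span type: no candidates
  expect_length(generate_candidates(txt, m[2:3, ]), 0)
  ## two findings + one body structure: auto-labeled LOCI
  m2 <- mk_mentions(list(0L, 2L, "便血", "symptom"),
                    list(3L, 5L, "腹胀", "symptom"),
                    list(8L, 9L, "胃", "body structure"))
  c2 <- generate_candidates("便血、腹胀位于胃。", m2)
  expect_length(c2, 2)
  expect_true(all(vapply(c2, function(cd) cd$auto_label, "") == "LOCI"))
  ## brute-force pairing count over generated sentences
  for (d in small_corpus()[1:15]) {
    sents <- split_sentences(d$text)
    for (i in seq_len(nrow(sents))) {
      m <- d$mentions[d$mentions$start >= sents$start[i] & d$mentions$end <= sents$end[i], ]
      m$start <- m$start - sents$start[i]; m$end <- m$end - sents$start[i]
      ents <- m[!is.na(vapply(m$sem_type, dstkg:::span_type_class, "")), ]
      expected <- 0L
      tys <- unique(ents$sem_type)
      if (length(tys) >= 2) {
        for (a in seq_len(length(tys) - 1)) for (b in (a + 1):length(tys)) {
          if (nrow(allowed_relations(tys[a], tys[b])))
            expected <- expected + sum(ents$sem_type == tys[a]) * sum(ents$sem_type == tys[b])
        }
      }
      expect_length(generate_candidates(sents$text[i], m), expected)
    }
  }
})

test_that("auto-labeling partitions candidates and conserves counts", {
  txt <- "行腹部CT以排查胃癌。"
  m <- mk_mentions(list(1L, 5L, "腹部CT", "test"), list(8L, 10L, "胃癌", "disease"))
  cands <- generate_candidates(txt, m)
  expect_length(cands, 1)
  part <- auto_label_corpus(cands)
  expect_length(part$labeled, 0) # disease-test admits TeCD and TeRD
  expect_length(part$ambiguous, 1)
  co <- small_corpus()[1:10]
  all_cands <- gold_candidates(co)
  part <- auto_label_corpus(all_cands)
  expect_equal(length(part$labeled) + length(part$ambiguous), length(all_cands))
  expect_true(all(vapply(part$labeled, function(cd) nrow(cd$allowed) == 1, NA)))
})

test_that("word attention satisfies its normalization contracts", {
  expect_equal(word_attention(matrix(rnorm(4), 1))$weights, 1)
  w <- word_attention(matrix(1, 4, 3), query = rnorm(3))$weights
  expect_equal(w, rep(0.25, 4))
  set.seed(8)
  h <- matrix(rnorm(24), 6, 4); q <- rnorm(4)
  wa <- word_attention(h, q)
  expect_true(all(wa$weights >= 0))
  expect_equal(sum(wa$weights), 1)
  wref <- exp(h %*% q - max(h %*% q)); wref <- wref / sum(wref)
  expect_equal(wa$output, as.vector(t(h) %*% wref), tolerance = 1e-9)
  expect_error(word_attention(matrix(0, 0, 3)), "empty")
})

test_that("relation classifier training is seeded and schema-masked", {
  co <- small_corpus()[1:25]
  cands <- gold_candidates(co)
  hp <- re_hyperparams(embedding_dim = 16, hidden_dim = 12, epochs = 2,
                       learning_rate = 5e-3, seed = 11)
  m1 <- train_re(cands, hp)
  m2 <- train_re(cands, hp)
  expect_identical(m1$history, m2$history)
  ## single-label corpus is rejected
  loci <- Filter(function(cd) identical(cd$gold_label, "LOCI"), cands)
  expect_error(train_re(loci, hp), ">= 2 distinct labels")
  ## classification contracts
  s <- build_default_schema()
  for (cd in cands[seq_len(min(30, length(cands)))]) {
    ## a 2-epoch toy model may not have seen every ambiguous label pair
    if (nrow(cd$allowed) > 1 && !any(cd$allowed$label %in% m1$labels)) next
    ri <- classify(m1, cd)
    expect_true(ri$label %in% cd$allowed$label)
    expect_gte(ri$confidence, 0); expect_lte(ri$confidence, 1)
    expect_equal(validate_edge(ri$head$sem_type, ri$label, ri$tail$sem_type, s), "valid")
    if (nrow(cd$allowed) == 1) {
      expect_equal(ri$label, cd$allowed$label)
      expect_equal(ri$confidence, 1)
      expect_equal(ri$provenance, "rule")
    }
  }
  bad <- cands[[1]]; bad$allowed <- bad$allowed[0, ]
  expect_error(classify(m1, bad), "empty admissible")
})

test_that("analytic gradients of the attention BiGRU match numerical differentiation", {
  set.seed(2)
  hp <- re_hyperparams(embedding_dim = 5, hidden_dim = 4, seed = 3)
  V <- 9; L <- 3
  params <- dstkg:::init_re_params(V, hp, L)
  lens <- c(6L, 4L, 5L); B <- 3; Tm <- 6
  ids <- matrix(1L, B, Tm)
  for (b in 1:B) ids[b, 1:lens[b]] <- sample(2:V, lens[b], replace = TRUE)
  bags <- list(1L, c(2L, 3L)); ys <- c(2L, 3L)
  loss_fn <- function(params) {
    fw <- dstkg:::re_forward_instances(params, ids, lens, hp)
    tot <- 0
    for (i in seq_along(bags)) {
      att <- dstkg:::bag_attention(params, fw$S[bags[[i]], , drop = FALSE])
      lg <- as.vector(att$vec %*% params$Wo + params$bo)
      pr <- exp(lg - max(lg)); pr <- pr / sum(pr)
      tot <- tot - log(pr[ys[i]])
    }
    tot
  }
  fw <- dstkg:::re_forward_instances(params, ids, lens, hp)
  g <- lapply(params, function(p) p * 0)
  dS <- fw$S * 0
  for (i in seq_along(bags)) {
    Sb <- fw$S[bags[[i]], , drop = FALSE]
    att <- dstkg:::bag_attention(params, Sb)
    lg <- as.vector(att$vec %*% params$Wo + params$bo)
    pr <- exp(lg - max(lg)); pr <- pr / sum(pr)
    dlog <- pr; dlog[ys[i]] <- dlog[ys[i]] - 1
    g$Wo <- g$Wo + att$vec %o% dlog; g$bo <- g$bo + dlog
    bb <- dstkg:::bag_attention_backward(params, Sb, att,
                                         as.vector(params$Wo %*% dlog), g)
    g <- bb$g; dS[bags[[i]], ] <- dS[bags[[i]], ] + bb$dS
  }
  gi <- dstkg:::re_backward_instances(params, fw, dS, ids, lens, hp)
  for (nm in names(gi)) g[[nm]] <- g[[nm]] + gi[[nm]]
  for (nm in names(params)) {
    p0 <- params[[nm]]
    for (ii in sample(length(p0), min(5, length(p0)))) {
      eps <- 1e-5
      pp <- params
      pp[[nm]][ii] <- p0[ii] + eps; lp <- loss_fn(pp)
      pp[[nm]][ii] <- p0[ii] - eps; lm <- loss_fn(pp)
      expect_equal(g[[nm]][ii], (lp - lm) / (2 * eps), tolerance = 1e-4, info = nm)
    }
  }
})
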