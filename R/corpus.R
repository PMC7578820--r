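## Synthetic Chinese-clinical-corpus generator. Documents emulate the
## structural properties the pipeline depends on: short clause-based
## sentences mixing at most 2 span types, negation cues scoping over
## comma-separated finding lists, type-pair-determined relations, and a
## per-patient record structure (admission diagnosis first, then findings,
## tests, treatments, pathology properties).

.NEGATABLE_TYPES <- c("disease", "symptom", "sign")
.DEFAULT_CUES <- c("无明显", "没有", "未见", "不伴", "无") # 无明显 没有 未见 不伴 无
.CLAUSE_BOUNDARIES <- c("，", ",", "；", ";", "。", "！", "？") # ，,；;。！？
.FILLER_CHARS <- c("等", "及", "和", " ") # 等 及 和

## sentence templates: head-first rendering "pre HEAD link TAIL1、TAIL2"
## with an optional trailing negation clause ", CUE NEG1, NEG2等"
.RE_TEMPLATES <- data.frame(
  label = c("TeCD", "TeRD", "TeRS", "TeAS", "TrAD", "TrCD", "TrAS", "TrCS",
            "DCS", "SID", "CLAS", "LOCI"),
  head_pool = c("test", "test", "test", "test", "treatment", "treatment",
                "treatment", "treatment", "disease", "finding", "disease", "finding_or_disease"),
  tail_pool = c("disease", "disease", "finding", "finding", "disease", "disease",
                "finding", "finding", "finding", "disease", "disease type", "body structure"),
  pre = c("行", "", "", "行", "予", "", "予", "",
          "", "", "", ""),
  link = c("以排查", "示", "见", "以评估",
           "治疗", "后并发", "以缓解",
           "后出现", "引起", "提示",
           "病理类型为", "位于"),
  stringsAsFactors = FALSE)

.HAS_A_LINKS <- c("disease" = "患有", "finding" = "出现",
                  "test" = "完善", "treatment" = "接受")

.DEFAULT_RELATION_MIX <- local({
  ## proportioned on the relation census of a comparable hand-built graph
  ## (11 clinical labels), with CLAS weighted like its disease-type support
  ## and a flat weight for explicit patient has_a sentences
  w <- c(TeCD = 96, TeRD = 990, TeRS = 2035, TeAS = 486, TrAD = 980,
         TrCD = 2, TrAS = 613, TrCS = 326, DCS = 29, SID = 261,
         CLAS = 452, LOCI = 3330, has_a = 1000)
  w / sum(w)
})

#' Configuration for the synthetic corpus generator
#'
#' @param n_patients Number of documents (one per patient).
#' @param vocab_sizes Optional named integer vector limiting how many
#'   bundled surface forms are used per span class (names among disease,
#'   symptom, sign, surgery, medicine, test, disease type, body structure);
#'   each must be >= 1. Default: the full bundled lexicon.
#' @param negation_prob Probability that any disease/clinical-finding
#'   mention is negated (rendered after a negation cue). Default 0.3.
#' @param relation_mix Named probability vector over the 13 non-structural
#'   relation labels governing sentence sampling; must sum to 1.
#' @param sentences_per_doc Length-2 integer range for sentences per
#'   document (in addition to the fixed admission-diagnosis sentence).
#' @param variant_prob Probability a mention surface is rendered as a
#'   nonpreferred/dictionary variant instead of the preferred term
#'   (synonym/abbreviation noise for the entity linker). Default 0.1.
#' @param property_prob Probability a sampled sentence is a pathology
#'   property sentence (disease type plus one of the 4 property span types).
#' @param seed Integer seed; generation is deterministic given the config.
#' @return A `dstkg_corpus_config` object.
#' @export
corpus_config <- function(n_patients = 100,
                          vocab_sizes = NULL,
                          negation_prob = 0.3,
                          relation_mix = NULL,
                          sentences_per_doc = c(5L, 10L),
                          variant_prob = 0.1,
                          property_prob = 0.15,
                          seed = 1L) {
  if (!is_count(n_patients) || n_patients < 1) stopf("n_patients must be a positive count")
  if (!is.numeric(negation_prob) || negation_prob < 0 || negation_prob > 1)
    stopf("negation_prob must lie in [0, 1]")
  mix <- relation_mix %||% .DEFAULT_RELATION_MIX
  if (is.null(names(mix)) || !all(names(mix) %in% names(.DEFAULT_RELATION_MIX)))
    stopf("relation_mix must be named by the 13 non-structural relation labels")
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-6) stopf("relation_mix must be a probability vector summing to 1")
  if (length(sentences_per_doc) != 2 || any(sentences_per_doc < 1) ||
      sentences_per_doc[1] > sentences_per_doc[2])
    stopf("sentences_per_doc must be an increasing positive range")
  if (!is.null(vocab_sizes) && any(vocab_sizes < 1)) stopf("vocab_sizes must be >= 1 per class")
  structure(list(n_patients = as.integer(n_patients), vocab_sizes = vocab_sizes,
                 negation_prob = negation_prob, relation_mix = mix,
                 sentences_per_doc = as.integer(sentences_per_doc),
                 variant_prob = variant_prob, property_prob = property_prob,
                 seed = as.integer(seed)),
            class = "dstkg_corpus_config")
}

## prepare per-class concept pools and preferred-term -> variant map
prepare_lexicon <- function(vocab_sizes = NULL) {
  concepts <- load_concepts()
  dicts <- load_dictionaries()
  concepts$sem_type <- unname(.concept_sem_type[concepts$class])
  concepts <- concepts[!is.na(concepts$sem_type), , drop = FALSE]
  pools <- split(concepts, concepts$sem_type)
  if (!is.null(vocab_sizes)) {
    for (nm in names(vocab_sizes)) {
      if (!is.null(pools[[nm]]))
        pools[[nm]] <- utils::head(pools[[nm]], max(1L, vocab_sizes[[nm]]))
    }
  }
  variants <- lapply(stats::setNames(seq_len(nrow(concepts)), concepts$preferred), function(i) {
    c(concepts$synonyms[[i]], dicts$surface[dicts$canonical == concepts$preferred[i]])
  })
  list(pools = pools, variants = variants, concepts = concepts)
}

sample_concepts <- function(lex, sem_type, k = 1L) {
  pool <- lex$pools[[sem_type]]
  if (is.null(pool) || !nrow(pool)) stopf("no bundled concepts for span type '%s'", sem_type)
  pool[sample.int(nrow(pool), min(k, nrow(pool))), , drop = FALSE]
}

resolve_pool <- function(pool_key) {
  switch(pool_key,
    "finding" = sample(c("symptom", "sign"), 1L, prob = c(0.75, 0.25)),
    "treatment" = sample(c("surgery", "medicine"), 1L),
    "finding_or_disease" = sample(c("symptom", "sign", "disease"), 1L, prob = c(0.45, 0.2, 0.35)),
    pool_key)
}

render_surface <- function(lex, concept_row, variant_prob) {
  vars <- lex$variants[[concept_row$preferred]]
  if (length(vars) && stats::runif(1) < variant_prob) sample(vars, 1L) else concept_row$preferred
}

## assemble segments (literal strings / mention stubs) into sentence text +
## offset-carrying mention table
assemble_segments <- function(segments) {
  text <- ""
  pos <- 0L
  rows <- list()
  for (seg in segments) {
    if (is.character(seg)) {
      text <- paste0(text, seg)
      pos <- pos + nchar(seg)
    } else {
      n <- nchar(seg$surface)
      rows[[length(rows) + 1L]] <- data.frame(
        start = pos, end = pos + n, surface = seg$surface, sem_type = seg$sem_type,
        state = seg$state, gold_concept = seg$gold_concept, stringsAsFactors = FALSE)
      text <- paste0(text, seg$surface)
      pos <- pos + n
    }
  }
  mentions <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(), end = integer(), surface = character(),
               sem_type = character(), state = character(), gold_concept = character(),
               stringsAsFactors = FALSE)
  list(text = text, mentions = mentions)
}

mention_stub <- function(lex, concept_row, negated, variant_prob) {
  sem <- concept_row$sem_type
  state <- if (!sem %in% .NEGATABLE_TYPES) "not-applicable" else if (negated) "negative" else "positive"
  list(surface = render_surface(lex, concept_row, variant_prob), sem_type = sem,
       state = state, gold_concept = concept_row$concept_id)
}

## one relation-template sentence; returns text, mentions, local relations
## (head/tail = row indices into the sentence mention table, 0 = patient)
build_relation_sentence <- function(label, lex, cfg, force_tail_class = NULL) {
  p <- cfg$negation_prob
  cue <- sample(.DEFAULT_CUES, 1L, prob = c(0.25, 0.2, 0.2, 0.25, 0.1))
  if (label == "has_a") {
    tail_class <- force_tail_class %||%
      sample(c("disease", "finding", "test", "treatment"),
             1L, prob = c(0.25, 0.4, 0.15, 0.2))
    k <- if (tail_class == "finding") sample.int(3L, 1L) else 1L
    pool <- resolve_pool(tail_class)
    tails <- sample_concepts(lex, pool, k)
    flags <- vapply(seq_len(nrow(tails)), function(i)
      tails$sem_type[i] %in% .NEGATABLE_TYPES && stats::runif(1) < p, NA)
    segs <- list("患者") # 患者
    pos_idx <- which(!flags); neg_idx <- which(flags)
    stubs <- lapply(seq_len(nrow(tails)), function(i)
      mention_stub(lex, tails[i, ], flags[i], cfg$variant_prob))
    if (length(pos_idx)) {
      segs <- c(segs, list(.HAS_A_LINKS[[tail_class]]))
      for (j in seq_along(pos_idx)) {
        if (j > 1) segs <- c(segs, list("、")) # 、
        segs <- c(segs, list(stubs[[pos_idx[j]]]))
      }
      if (length(neg_idx)) segs <- c(segs, list(paste0(", ", cue)))
    } else if (length(neg_idx)) {
      segs <- c(segs, list(cue))
    }
    if (length(neg_idx)) {
      for (j in seq_along(neg_idx)) {
        if (j > 1) segs <- c(segs, list(", "))
        segs <- c(segs, list(stubs[[neg_idx[j]]]))
      }
      segs <- c(segs, list("等")) # 等
    }
    segs <- c(segs, list("。")) # 。
    out <- assemble_segments(segs)
    ## mention rows appear positives-first then negatives (textual order)
    n_pos <- length(pos_idx)
    rels <- if (n_pos) data.frame(head = rep(0L, n_pos), tail = seq_len(n_pos),
                                  label = "has_a", stringsAsFactors = FALSE)
            else data.frame(head = integer(), tail = integer(), label = character(),
                            stringsAsFactors = FALSE)
    return(c(out, list(relations = rels)))
  }

  tpl <- .RE_TEMPLATES[.RE_TEMPLATES$label == label, ]
  head_row <- sample_concepts(lex, resolve_pool(tpl$head_pool), 1L)
  k <- if (tpl$tail_pool == "finding") sample.int(3L, 1L) else 1L
  tails <- sample_concepts(lex, resolve_pool(tpl$tail_pool), k)
  head_neg <- head_row$sem_type %in% .NEGATABLE_TYPES && stats::runif(1) < p
  tail_flags <- vapply(seq_len(nrow(tails)), function(i)
    tails$sem_type[i] %in% .NEGATABLE_TYPES && stats::runif(1) < p, NA)
  head_stub <- mention_stub(lex, head_row, head_neg, cfg$variant_prob)
  tail_stubs <- lapply(seq_len(nrow(tails)), function(i)
    mention_stub(lex, tails[i, ], tail_flags[i], cfg$variant_prob))

  if (head_neg) {
    ## negated head: positives (if negatable) lead, then cue + head + negated
    ## tails; non-negatable tails are dropped with the lost assertion
    negatable <- tails$sem_type %in% .NEGATABLE_TYPES
    pos_idx <- which(negatable & !tail_flags)
    neg_idx <- which(negatable & tail_flags)
    segs <- list()
    if (length(pos_idx)) {
      segs <- c(segs, list("伴")) # 伴
      for (j in seq_along(pos_idx)) {
        if (j > 1) segs <- c(segs, list("、"))
        segs <- c(segs, list(tail_stubs[[pos_idx[j]]]))
      }
      segs <- c(segs, list(", "))
    }
    segs <- c(segs, list(cue, head_stub))
    for (j in neg_idx) segs <- c(segs, list(", "), list(tail_stubs[[j]]))
    if (length(neg_idx)) segs <- c(segs, list("等"))
    segs <- c(segs, list("。"))
    out <- assemble_segments(segs)
    return(c(out, list(relations = data.frame(head = integer(), tail = integer(),
                                              label = character(), stringsAsFactors = FALSE))))
  }

  pos_idx <- which(!tail_flags); neg_idx <- which(tail_flags)
  segs <- list()
  if (nzchar(tpl$pre)) segs <- c(segs, list(tpl$pre))
  segs <- c(segs, list(head_stub))
  if (length(pos_idx)) {
    segs <- c(segs, list(tpl$link))
    for (j in seq_along(pos_idx)) {
      if (j > 1) segs <- c(segs, list("、"))
      segs <- c(segs, list(tail_stubs[[pos_idx[j]]]))
    }
  }
  if (length(neg_idx)) {
    segs <- c(segs, list(paste0(", ", cue)))
    for (j in seq_along(neg_idx)) {
      if (j > 1) segs <- c(segs, list(", "))
      segs <- c(segs, list(tail_stubs[[neg_idx[j]]]))
    }
    segs <- c(segs, list("等"))
  }
  segs <- c(segs, list("。"))
  out <- assemble_segments(segs)
  ## head is mention row 1; positive tails are rows 2..(1+n_pos)
  n_pos <- length(pos_idx)
  rels <- if (n_pos) data.frame(head = rep(1L, n_pos), tail = 1L + seq_len(n_pos),
                                label = label, stringsAsFactors = FALSE)
          else data.frame(head = integer(), tail = integer(), label = character(),
                          stringsAsFactors = FALSE)
  c(out, list(relations = rels))
}

## pathology property sentence: disease type + one property span, linked by
## a gold attribute_of relation (concept -> property value)
build_property_sentence <- function(lex, cfg) {
  dt <- sample_concepts(lex, "disease type", 1L)
  kind <- sample(c("histological grade", "pathological stage", "naked eye type", "tumor size"), 1L)
  val <- switch(kind,
    "histological grade" = sample(c("低分化", "中分化", "高分化"), 1L),
    "pathological stage" = sprintf("pT%dN%dM%d", sample(1:4, 1L), sample(0:3, 1L), sample(0:1, 1L)),
    "naked eye type" = sample(c("浸润溃疡型", "隆起型",
                                "溃疡型", "弥漫浸润型"), 1L),
    "tumor size" = sprintf("%.1f*%.1f*%.1fCM", stats::runif(1, 1, 15), stats::runif(1, 1, 9), stats::runif(1, 0.5, 3)))
  link <- switch(kind,
    "histological grade" = ", 分级为",    # , 分级为
    "pathological stage" = "病理分期为", # 病理分期为
    "naked eye type" = "肉眼类型为",     # 肉眼类型为
    "tumor size" = "体积")                            # 体积
  segs <- list(mention_stub(lex, dt, FALSE, cfg$variant_prob), link,
               list(surface = val, sem_type = kind, state = "not-applicable",
                    gold_concept = NA_character_),
               "。")
  out <- assemble_segments(segs)
  c(out, list(relations = data.frame(head = 1L, tail = 2L, label = "attribute_of",
                                     stringsAsFactors = FALSE)))
}

#' Generate a synthetic gold-annotated clinical corpus
#'
#' Deterministic for a fixed config (seed included). Every document starts
#' with an admission-diagnosis sentence (`患者患有<disease>`) so each patient
#' is grounded by at least one `has_a` relation; remaining sentences are
#' drawn from the configured relation mix and pathology-property templates.
#' Gold annotations satisfy the non-overlapping/non-nesting convention, and
#' every gold relation passes [validate_edge()].
#'
#' @param config A [corpus_config()].
#' @return A `dstkg_corpus`: list of documents, each with `patient_id`,
#'   `text`, `mentions` (0-based half-open character offsets, span type,
#'   state, gold concept id) and `relations` (mention ids; head 0 denotes
#'   the patient node).
#' @export
generate_corpus <- function(config = corpus_config()) {
  if (!inherits(config, "dstkg_corpus_config")) stopf("config must come from corpus_config()")
  set.seed(config$seed)
  lex <- prepare_lexicon(config$vocab_sizes)
  labels <- names(config$relation_mix)
  docs <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    n_extra <- sample(seq(config$sentences_per_doc[1], config$sentences_per_doc[2]), 1L)
    sents <- vector("list", n_extra + 1L)
    ## admission diagnosis grounds the patient (negation still Bernoulli so
    ## the corpus-wide negated fraction stays at negation_prob)
    sents[[1L]] <- build_relation_sentence("has_a", lex, config, force_tail_class = "disease")
    for (s in seq_len(n_extra)) {
      sents[[s + 1L]] <-
        if (stats::runif(1) < config$property_prob) build_property_sentence(lex, config)
        else build_relation_sentence(sample(labels, 1L, prob = config$relation_mix), lex, config)
    }
    text <- ""
    offset <- 0L
    mentions <- list()
    relations <- list()
    n_m <- 0L
    for (sent in sents) {
      m <- sent$mentions
      if (nrow(m)) {
        m$start <- m$start + offset
        m$end <- m$end + offset
        m$id <- n_m + seq_len(nrow(m))
      } else m$id <- integer()
      r <- sent$relations
      if (nrow(r)) {
        r$head <- ifelse(r$head == 0L, 0L, r$head + n_m)
        r$tail <- r$tail + n_m
      }
      mentions[[length(mentions) + 1L]] <- m
      relations[[length(relations) + 1L]] <- r
      n_m <- n_m + nrow(m)
      text <- paste0(text, sent$text)
      offset <- offset + nchar(sent$text)
    }
    mentions <- do.call(rbind, mentions)
    mentions <- mentions[, c("id", "start", "end", "surface", "sem_type", "state", "gold_concept")]
    docs[[i]] <- structure(list(patient_id = sprintf("patient_%04d", i),
                                text = text, mentions = mentions,
                                relations = do.call(rbind, relations)),
                           class = "dstkg_gold_doc")
  }
  structure(docs, class = "dstkg_corpus")
}

#' Split a corpus into train/test/validation partitions
#'
#' Sizes follow the largest-remainder method (ties to the earlier
#' partition), so the partition is disjoint, exhaustive, and matches the
#' ratios to rounding. Assignment shuffles documents deterministically under
#' `seed`.
#'
#' @param corpus A `dstkg_corpus` (or plain list of documents).
#' @param ratios Length-3 positive numeric summing to 1 (train, test,
#'   validation); the conventional split is `c(0.8, 0.1, 0.1)`.
#' @param seed Integer seed for the shuffle.
#' @return Named list `train`, `test`, `validation`.
#' @export
split_corpus <- function(corpus, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(ratios) != 3 || any(ratios < 0) || abs(sum(ratios) - 1) > 1e-6 || all(ratios == 0))
    stopf("ratios must be 3 non-negative numbers summing to 1")
  n <- length(corpus)
  sizes <- floor(n * ratios)
  rem <- n * ratios - sizes
  left <- n - sum(sizes)
  if (left > 0) {
    take <- order(rem, seq_along(rem), decreasing = c(TRUE, FALSE), method = "radix")[seq_len(left)]
    sizes[take] <- sizes[take] + 1L
  }
  set.seed(seed)
  idx <- sample.int(n)
  bounds <- cumsum(sizes)
  pick <- function(a, b) if (b < a) corpus[integer()] else corpus[idx[seq(a, b)]]
  list(train = pick(1, bounds[1]),
       test = pick(bounds[1] + 1, bounds[2]),
       validation = pick(bounds[2] + 1, bounds[3]))
}

#' Convert gold documents to character-level BIO label sequences
#'
#' @param corpus A `dstkg_corpus` or list of gold documents.
#' @return List per document: `doc_id`, `chars` (character vector), `labels`
#'   (`B-<type>` / `I-<type>` / `O`). Errors on overlapping gold spans.
#' @export
corpus_to_bio <- function(corpus) {
  lapply(corpus, function(doc) {
    cs <- chars(doc$text)
    list(doc_id = doc$patient_id, chars = cs,
         labels = spans_to_bio(length(cs), doc$mentions))
  })
}

## mentions (start, end, sem_type) -> BIO labels over n characters
spans_to_bio <- function(n, mentions) {
  labels <- rep("O", n)
  if (!nrow(mentions)) return(labels)
  m <- mentions[order(mentions$start), , drop = FALSE]
  last_end <- 0L
  for (i in seq_len(nrow(m))) {
    s <- m$start[i]; e <- m$end[i]
    if (s < last_end) stopf("overlapping gold spans at offset %d", s)
    if (e > n || s < 0 || e <= s) stopf("span [%d,%d) outside text of length %d", s, e, n)
    labels[s + 1L] <- paste0("B-", m$sem_type[i])
    if (e - s > 1) labels[(s + 2L):e] <- paste0("I-", m$sem_type[i])
    last_end <- e
  }
  labels
}

#' Decode BIO labels back to spans
#'
#' With `repair = TRUE` (the tagger's documented repair rule) an orphan
#' `I-X` — at sequence start, after `O`, or after a span of a different type
#' — is treated as `B-X`; with `repair = FALSE` such sequences are an error.
#'
#' @param labels Character vector of BIO labels.
#' @param repair Apply the orphan-I repair rule instead of failing.
#' @return data.frame with 0-based half-open `start`, `end`, `sem_type`.
#' @export
bio_to_spans <- function(labels, repair = FALSE) {
  starts <- integer(); ends <- integer(); types <- character()
  cur_type <- NULL; cur_start <- NA_integer_
  flush <- function(pos) {
    if (!is.null(cur_type)) {
      starts[[length(starts) + 1L]] <<- cur_start
      ends[[length(ends) + 1L]] <<- pos
      types[[length(types) + 1L]] <<- cur_type
    }
    cur_type <<- NULL
  }
  for (i in seq_along(labels)) {
    lab <- labels[i]
    if (lab == "O") { flush(i - 1L); next }
    tag <- substr(lab, 1, 1)
    typ <- substr(lab, 3, nchar(lab))
    if (tag == "B") { flush(i - 1L); cur_type <- typ; cur_start <- i - 1L }
    else if (tag == "I") {
      if (is.null(cur_type) || cur_type != typ) {
        if (!repair) stopf("invalid BIO transition at position %d (%s)", i - 1L, lab)
        flush(i - 1L); cur_type <- typ; cur_start <- i - 1L
      }
    } else stopf("unknown BIO label '%s'", lab)
  }
  flush(length(labels))
  data.frame(start = starts, end = ends, sem_type = types, stringsAsFactors = FALSE)
}

#' Write a corpus as JSONL documents plus a standoff annotation file
#'
#' Document records: `{"patient_id": ..., "text": ...}`. Standoff records:
#' `{"doc_id", "kind": "mention", "id", "start", "end", "type", "state",
#' "concept"}` and `{"doc_id", "kind": "relation", "head", "tail", "label"}`
#' (mention ids; head 0 is the patient).
#'
#' @param corpus A `dstkg_corpus`.
#' @param doc_path,ann_path Output paths (UTF-8 JSONL).
#' @return Invisibly, the two paths.
#' @export
write_corpus <- function(corpus, doc_path, ann_path) {
  doc_lines <- vapply(corpus, function(d)
    jsonlite::toJSON(list(patient_id = d$patient_id, text = d$text), auto_unbox = TRUE), "")
  ann_lines <- unlist(lapply(corpus, function(d) {
    m <- d$mentions; r <- d$relations
    c(vapply(seq_len(nrow(m)), function(i)
        jsonlite::toJSON(list(doc_id = d$patient_id, kind = "mention", id = m$id[i],
                              start = m$start[i], end = m$end[i], type = m$sem_type[i],
                              state = m$state[i], concept = m$gold_concept[i]),
                         auto_unbox = TRUE, null = "null"), ""),
      if (!is.null(r) && nrow(r)) vapply(seq_len(nrow(r)), function(i)
        jsonlite::toJSON(list(doc_id = d$patient_id, kind = "relation", head = r$head[i],
                              tail = r$tail[i], label = r$label[i]), auto_unbox = TRUE), ""))
  }))
  writeLines(doc_lines, doc_path, useBytes = TRUE)
  writeLines(ann_lines %||% character(), ann_path, useBytes = TRUE)
  invisible(c(doc_path, ann_path))
}

#' Read a corpus written by [write_corpus()]
#' @param doc_path,ann_path Paths written by [write_corpus()].
#' @return A `dstkg_corpus`.
#' @export
read_corpus <- function(doc_path, ann_path) {
  docs <- lapply(readLines(doc_path, encoding = "UTF-8"), jsonlite::fromJSON)
  anns <- lapply(readLines(ann_path, encoding = "UTF-8"), jsonlite::fromJSON)
  by_doc <- split(anns, vapply(anns, `[[`, "", "doc_id"))
  out <- lapply(docs, function(d) {
    recs <- by_doc[[d$patient_id]] %||% list()
    ms <- Filter(function(a) a$kind == "mention", recs)
    rs <- Filter(function(a) a$kind == "relation", recs)
    mentions <- if (length(ms)) data.frame(
      id = vapply(ms, function(a) as.integer(a$id), 0L),
      start = vapply(ms, function(a) as.integer(a$start), 0L),
      end = vapply(ms, function(a) as.integer(a$end), 0L),
      surface = vapply(ms, function(a) substr0(d$text, a$start, a$end), ""),
      sem_type = vapply(ms, function(a) a$type, ""),
      state = vapply(ms, function(a) a$state, ""),
      gold_concept = vapply(ms, function(a) if (is.null(a$concept)) NA_character_ else a$concept, ""),
      stringsAsFactors = FALSE)
    else data.frame(id = integer(), start = integer(), end = integer(), surface = character(),
                    sem_type = character(), state = character(), gold_concept = character(),
                    stringsAsFactors = FALSE)
    relations <- if (length(rs)) data.frame(
      head = vapply(rs, function(a) as.integer(a$head), 0L),
      tail = vapply(rs, function(a) as.integer(a$tail), 0L),
      label = vapply(rs, function(a) a$label, ""), stringsAsFactors = FALSE)
    else data.frame(head = integer(), tail = integer(), label = character(), stringsAsFactors = FALSE)
    structure(list(patient_id = d$patient_id, text = d$text,
                   mentions = mentions, relations = relations),
              class = "dstkg_gold_doc")
  })
  structure(out, class = "dstkg_corpus")
}
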