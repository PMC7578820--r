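## Relation extraction: sentence splitting, type-pair-constrained candidate
## generation with automatic labeling (unique admissible label => labeled;
## otherwise ambiguous, to be classified), and helpers to build a labeled
## training corpus from gold documents.

.SENTENCE_TERMINATORS <- c("。", "！", "？", "；", ";", "\n") # 。！？；;

#' Split text into sentences with document offsets
#'
#' Splits on the terminal punctuation 。！？； (plus ASCII `;` and newline),
#' keeping the terminator with its sentence, so concatenating the slices
#' reconstructs the input exactly.
#'
#' @param text Document text.
#' @return data.frame with 0-based half-open `start`, `end` and `text`.
#' @export
split_sentences <- function(text) {
  cs <- chars(text)
  n <- length(cs)
  if (!n) return(data.frame(start = integer(), end = integer(), text = character(),
                            stringsAsFactors = FALSE))
  ends <- which(cs %in% .SENTENCE_TERMINATORS)
  if (!length(ends) || ends[length(ends)] != n) ends <- c(ends, n)
  starts <- c(0L, ends[-length(ends)])
  data.frame(start = starts, end = ends,
             text = vapply(seq_along(ends), function(i)
               paste(cs[(starts[i] + 1L):ends[i]], collapse = ""), ""),
             stringsAsFactors = FALSE)
}

#' Generate schema-constrained relation candidates for one sentence
#'
#' Entity mentions are grouped by span type; every unordered pair of
#' distinct types whose [allowed_relations()] set is nonempty contributes
#' the full cross product of group members. Pairs of identical types yield
#' no candidates, property span types are skipped, and a candidate whose
#' admissible set is a single label carries it as `auto_label`. Candidate
#' head/tail follow textual order; the canonical direction of each label is
#' recorded in the `allowed` table.
#'
#' @param sentence_text Sentence text (for the classifier input).
#' @param mentions Mention data.frame with offsets local to the sentence.
#' @param schema A `dstkg_schema`.
#' @param doc_id Optional document id carried through.
#' @return List of `dstkg_re_candidate` objects.
#' @export
generate_candidates <- function(sentence_text, mentions, schema = build_default_schema(),
                                doc_id = NA_character_) {
  ents <- mentions[!is.na(vapply(mentions$sem_type, span_type_class, "")), , drop = FALSE]
  if (!nrow(ents)) return(list())
  types <- unique(ents$sem_type)
  out <- list()
  if (length(types) < 2) return(out)
  for (a in seq_len(length(types) - 1L)) for (b in (a + 1L):length(types)) {
    allowed <- allowed_relations(types[a], types[b], schema)
    if (!nrow(allowed)) next
    ga <- which(ents$sem_type == types[a]); gb <- which(ents$sem_type == types[b])
    for (i in ga) for (j in gb) {
      first <- if (ents$start[i] <= ents$start[j]) i else j
      second <- if (first == i) j else i
      ## direction of each label relative to (first, second) textual order
      rel <- allowed
      if (first != i) rel$direction <- ifelse(rel$direction == "as-given", "reversed", "as-given")
      out[[length(out) + 1L]] <- structure(
        list(doc_id = doc_id, sentence = sentence_text,
             head = ents[first, , drop = FALSE], tail = ents[second, , drop = FALSE],
             allowed = rel,
             auto_label = if (nrow(rel) == 1) rel$label else NA_character_),
        class = "dstkg_re_candidate")
    }
  }
  out
}

#' Partition candidates into auto-labeled and ambiguous sets
#'
#' @param candidates List of candidates from [generate_candidates()].
#' @return List with `labeled` (unique admissible label) and `ambiguous`;
#'   counts are conserved.
#' @export
auto_label_corpus <- function(candidates) {
  lab <- vapply(candidates, function(cd) !is.na(cd$auto_label), NA)
  list(labeled = candidates[lab], ambiguous = candidates[!lab])
}

#' Attention pooling over a state sequence
#'
#' Weights are a softmax of the states' scalar projections onto `query`
#' (uniform for a zero/absent query or identical states); the output is the
#' weighted sum of states. Used at the word level over BiGRU states and at
#' the sentence level over instance vectors.
#'
#' @param hidden_states Numeric matrix, one state per row.
#' @param query Optional numeric projection vector (default zeros).
#' @return List with `output` (vector) and `weights` (nonnegative, sum 1).
#' @export
word_attention <- function(hidden_states, query = NULL) {
  hidden_states <- as.matrix(hidden_states)
  if (!nrow(hidden_states)) stopf("empty state sequence")
  query <- query %||% numeric(ncol(hidden_states))
  sc <- as.vector(hidden_states %*% query)
  w <- exp(sc - max(sc)); w <- w / sum(w)
  list(output = as.vector(crossprod(hidden_states, w)), weights = w)
}

## gold-labeled candidate corpus: every candidate from every sentence of
## every document, labeled by the matching gold relation or "no_relation"
re_training_data <- function(corpus, schema = build_default_schema()) {
  out <- list()
  for (doc in corpus) {
    sents <- split_sentences(doc$text)
    for (i in seq_len(nrow(sents))) {
      s <- sents$start[i]; e <- sents$end[i]
      m <- doc$mentions[doc$mentions$start >= s & doc$mentions$end <= e, , drop = FALSE]
      if (nrow(m) < 2) next
      ml <- m; ml$start <- ml$start - s; ml$end <- ml$end - s
      cands <- generate_candidates(sents$text[i], ml, schema, doc_id = doc$patient_id)
      if (!length(cands)) next
      r <- doc$relations
      for (cd in cands) {
        hid <- m$id[match(cd$head$id, ml$id)]; tid <- m$id[match(cd$tail$id, ml$id)]
        hit <- which((r$head == hid & r$tail == tid) | (r$head == tid & r$tail == hid))
        cd$gold_label <- if (length(hit)) r$label[hit[1]] else "no_relation"
        out[[length(out) + 1L]] <- cd
      }
    }
  }
  out
}
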