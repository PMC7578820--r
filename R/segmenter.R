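## Pluggable word segmentation / POS tagging. Real Chinese lexical
## analyzers are out of scope; the bundled fallback does greedy
## longest-match over the package lexicon and assigns a coarse POS scheme.
## Any function(text) returning data.frame(word, pos) can be substituted.

.POS_LEVELS <- c("n", "v", "d", "m", "w", "x")

.VERB_WORDS <- c("行", "予", "给予", "治疗", "出现", "并发",
                 "提示", "引起", "位于", "患有", "接受",
                 "完善", "示", "见", "以排查", "以评估",
                 "以缓解", "分级为", "病理分期为",
                 "肉眼类型为", "病理类型为")
.ADV_WORDS <- c("无明显", "没有", "未见", "不伴", "无", "伴")

#' Construct the bundled rule-based segmenter
#'
#' Greedy longest-match segmentation over a term list (by default the
#' package lexicon: concept terms, synonyms, dictionary surfaces, cue and
#' predicate words), with a coarse POS scheme: `n` lexicon noun, `v`
#' predicate, `d` cue/adverb, `m` alphanumeric run, `w` punctuation, `x`
#' other. Every character of a word shares the word's POS tag.
#'
#' @param extra_terms Optional character vector of additional surface forms
#'   to segment as single noun words.
#' @return A `function(text)` returning `data.frame(word, pos, start)` with
#'   0-based word start offsets.
#' @export
default_segmenter <- function(extra_terms = NULL) {
  concepts <- load_concepts()
  dicts <- load_dictionaries()
  nouns <- unique(c(concepts$preferred, unlist(concepts$synonyms),
                    dicts$surface, dicts$canonical, extra_terms))
  vocab <- c(stats::setNames(rep("n", length(nouns)), nouns),
             stats::setNames(rep("v", length(.VERB_WORDS)), .VERB_WORDS),
             stats::setNames(rep("d", length(.ADV_WORDS)), .ADV_WORDS))
  ## longest-first match table indexed by word length
  max_len <- max(nchar(names(vocab)))
  lookup <- new.env(parent = emptyenv(), size = length(vocab) * 2L)
  for (w in names(vocab)) assign(w, vocab[[w]], envir = lookup)
  function(text) {
    cs <- chars(text)
    n <- length(cs)
    words <- character(); poss <- character(); starts <- integer()
    i <- 1L
    while (i <= n) {
      hit <- NULL
      upper <- min(max_len, n - i + 1L)
      if (upper >= 2L) for (L in upper:2L) {
        cand <- paste(cs[i:(i + L - 1L)], collapse = "")
        if (!is.null(p <- lookup[[cand]])) { hit <- list(word = cand, pos = p, len = L); break }
      }
      if (is.null(hit)) {
        ch <- cs[i]
        pos <- if (grepl("^[0-9A-Za-z.*]$", ch)) "m"
               else if (grepl("[[:punct:][:space:]]", ch) ||
                        ch %in% c(.HARD_BOUNDARIES, .COMMA_CHARS, "、")) "w"
               else if (!is.null(p <- lookup[[ch]])) p
               else "x"
        hit <- list(word = ch, pos = pos, len = 1L)
      }
      words <- c(words, hit$word); poss <- c(poss, hit$pos); starts <- c(starts, i - 1L)
      i <- i + hit$len
    }
    data.frame(word = words, pos = poss, start = starts, stringsAsFactors = FALSE)
  }
}

#' Per-character features for sequence labeling
#'
#' The four feature families: the character itself (bag of characters),
#' the POS tag of the containing word, the character position in the
#' sentence, and per-dictionary membership flags (one per bundled
#' dictionary category).
#'
#' @param sentence Sentence text.
#' @param dictionaries Dictionary data.frame from [load_dictionaries()].
#' @param segmenter A segmenter function (see [default_segmenter()]).
#' @return data.frame with one row per character: `char`, `pos_tag`,
#'   `position` (0-based), and logical `dict_*` columns in the fixed
#'   category order.
#' @export
featurize <- function(sentence, dictionaries = load_dictionaries(),
                      segmenter = default_segmenter()) {
  cs <- chars(sentence)
  n <- length(cs)
  cats <- c("disease", "drug", "surgery", "test", "symptom/sign", "body structure")
  flag_cols <- stats::setNames(
    lapply(cats, function(ct) {
      hit <- rep(FALSE, n)
      terms <- unique(c(dictionaries$surface[dictionaries$category == ct],
                        dictionaries$canonical[dictionaries$category == ct]))
      for (term in terms) {
        m <- gregexpr(term, sentence, fixed = TRUE)[[1]]
        if (m[1] == -1L) next
        for (s in m) hit[s:(s + nchar(term) - 1L)] <- TRUE
      }
      hit
    }),
    paste0("dict_", gsub("[ /]", "_", cats)))
  if (n == 0) {
    return(cbind(data.frame(char = character(), pos_tag = character(), position = integer(),
                            stringsAsFactors = FALSE),
                 as.data.frame(lapply(flag_cols, function(x) logical()))))
  }
  seg <- segmenter(sentence)
  pos_tag <- rep("x", n)
  for (i in seq_len(nrow(seg))) {
    span <- (seg$start[i] + 1L):(seg$start[i] + nchar(seg$word[i]))
    pos_tag[span] <- seg$pos[i]
  }
  cbind(data.frame(char = cs, pos_tag = pos_tag, position = 0:(n - 1L),
                   stringsAsFactors = FALSE),
        as.data.frame(flag_cols, check.names = FALSE))
}
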