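## Hierarchical, batch named-entity linking: per-document dedupe, class-
## scoped exact matching (preferred term, then nonpreferred terms / data
## property values), dictionary expansion for unmatched surfaces, and
## cosine-similarity ranking over character bigrams as the fallback.

#' Deduplicate mentions into unique linking keys
#'
#' @param mentions Mention data.frame with `surface` and `sem_type`.
#' @return List with `keys` (unique surface/sem_type pairs) and `map`
#'   (index into `keys` for every input mention), so linking each key once
#'   and fanning out restores exactly the input mentions.
#' @export
dedupe <- function(mentions) {
  if (!nrow(mentions)) {
    return(list(keys = data.frame(surface = character(), sem_type = character(),
                                  stringsAsFactors = FALSE),
                map = integer()))
  }
  kk <- paste(mentions$surface, mentions$sem_type, sep = "\r")
  keys <- !duplicated(kk)
  list(keys = data.frame(surface = mentions$surface[keys], sem_type = mentions$sem_type[keys],
                         stringsAsFactors = FALSE),
       map = match(kk, kk[keys]))
}

## concepts of the key's schema class (including subclasses)
scoped_concepts <- function(sem_type, concepts, schema) {
  cls <- span_type_class(sem_type)
  if (is.na(cls)) stopf("span type '%s' is not linkable", sem_type)
  if (is.null(schema$classes[[cls]])) stopf("unknown span class '%s'", cls)
  scope <- class_descendants(cls, schema)
  concepts[concepts$class %in% scope, , drop = FALSE]
}

#' Hierarchical exact matching of one key against the knowledge base
#'
#' The semantic type selects the schema class; the search is restricted to
#' concepts of that class and its subclasses. Stage 1 matches the surface
#' exactly against preferred terms; stage 2 against nonpreferred terms,
#' English names and data-property values. The first hit (concept-id order)
#' wins; exact methods carry score 1.
#'
#' @param surface,sem_type The key.
#' @param concepts Knowledge base from [load_concepts()].
#' @param schema A `dstkg_schema`.
#' @return A link record (`concept_id`, `method`, `score`) or `NULL`.
#' @export
hierarchical_match <- function(surface, sem_type, concepts = load_concepts(),
                               schema = build_default_schema()) {
  sc <- scoped_concepts(sem_type, concepts, schema)
  if (!nrow(sc)) return(NULL)
  sc <- sc[order(sc$concept_id), , drop = FALSE]
  hit <- which(sc$preferred == surface)
  if (length(hit)) {
    return(list(concept_id = sc$concept_id[hit[1]], method = "exact-concept", score = 1))
  }
  hit <- which(vapply(seq_len(nrow(sc)), function(i)
    surface %in% c(sc$synonyms[[i]], sc$english[i], unname(sc$properties[[i]])), NA))
  if (length(hit)) {
    return(list(concept_id = sc$concept_id[hit[1]], method = "exact-property", score = 1))
  }
  NULL
}

#' Expand an unmatched surface through the dictionaries
#'
#' @param surface Unmatched surface form.
#' @param dictionaries Dictionary table from [load_dictionaries()].
#' @return Character vector of canonical variants (never the input itself;
#'   empty when the surface is absent from all dictionaries).
#' @export
dictionary_expand <- function(surface, dictionaries = load_dictionaries()) {
  v <- unique(dictionaries$canonical[dictionaries$surface == surface])
  setdiff(v, surface)
}

## character-bigram count vector (single characters fall back to unigrams)
char_bigrams <- function(s) {
  cs <- chars(s)
  if (length(cs) < 2) return(table(s))
  table(paste0(cs[-length(cs)], cs[-1]))
}

cosine_bigram <- function(a, b) {
  ta <- char_bigrams(a); tb <- char_bigrams(b)
  shared <- intersect(names(ta), names(tb))
  if (!length(shared)) return(0)
  sum(as.numeric(ta[shared]) * as.numeric(tb[shared])) /
    (sqrt(sum(as.numeric(ta)^2)) * sqrt(sum(as.numeric(tb)^2)))
}

#' Rank candidate concepts by cosine similarity
#'
#' Similarity is the cosine between character-bigram count vectors of the
#' surface and each concept's terms (maximum over preferred plus
#' nonpreferred terms). Candidates sort by descending score with ties
#' broken by concept id; scores below `threshold` are dropped.
#'
#' @param surface Surface form to link.
#' @param candidates Concept data.frame (normally the class-scoped subset).
#' @param threshold Minimum score kept (default 0.5).
#' @return data.frame `concept_id`, `score`, ranked; zero rows if nothing
#'   clears the threshold.
#' @export
similarity_rank <- function(surface, candidates, threshold = 0.5) {
  if (!nrow(candidates)) {
    return(data.frame(concept_id = character(), score = numeric(), stringsAsFactors = FALSE))
  }
  sc <- vapply(seq_len(nrow(candidates)), function(i) {
    terms <- unique(c(candidates$preferred[i], candidates$synonyms[[i]]))
    max(vapply(terms, cosine_bigram, 0, a = surface))
  }, 0)
  out <- data.frame(concept_id = candidates$concept_id, score = sc, stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$concept_id), , drop = FALSE]
  out[out$score >= threshold, , drop = FALSE]
}

#' Link the mentions of one document to the knowledge base
#'
#' Runs the hierarchical pipeline per unique (surface, span type) key:
#' exact concept/property match, dictionary expansion with re-matching,
#' then cosine ranking, keeping the top-ranked hit (use [similarity_rank()]
#' directly for a top-k list). An exact match always preempts similarity. The
#' four property span types are not linkable and come back unlinked.
#'
#' @param mentions Mention data.frame of one document.
#' @param concepts,dictionaries Knowledge base and dictionaries.
#' @param schema A `dstkg_schema`.
#' @param threshold Similarity threshold (default 0.5).
#' @return `mentions` with `concept_id`, `link_method` (`exact-concept`,
#'   `exact-property`, `dictionary-expanded`, `similarity`, or `unlinked`)
#'   and `link_score` columns.
#' @export
link_mentions <- function(mentions, concepts = load_concepts(),
                          dictionaries = load_dictionaries(),
                          schema = build_default_schema(), threshold = 0.5) {
  dd <- dedupe(mentions)
  res <- lapply(seq_len(nrow(dd$keys)), function(i) {
    surface <- dd$keys$surface[i]; st <- dd$keys$sem_type[i]
    if (is.na(span_type_class(st)))
      return(list(concept_id = NA_character_, method = "not-applicable", score = NA_real_))
    hit <- hierarchical_match(surface, st, concepts, schema)
    if (!is.null(hit)) return(hit)
    for (v in dictionary_expand(surface, dictionaries)) {
      hit <- hierarchical_match(v, st, concepts, schema)
      if (!is.null(hit)) return(list(concept_id = hit$concept_id,
                                     method = "dictionary-expanded", score = 1))
    }
    ranked <- similarity_rank(surface, scoped_concepts(st, concepts, schema), threshold)
    if (nrow(ranked)) return(list(concept_id = ranked$concept_id[1],
                                  method = "similarity", score = ranked$score[1]))
    list(concept_id = NA_character_, method = "unlinked", score = NA_real_)
  })
  mentions$concept_id <- vapply(res, function(r) r$concept_id, "")[dd$map]
  mentions$link_method <- vapply(res, function(r) r$method, "")[dd$map]
  mentions$link_score <- vapply(res, function(r) r$score, 0)[dd$map]
  mentions
}
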