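test_that("dedupe produces unique keys whose fan-out restores the input", {
  m <- data.frame(surface = c("恶心", "呕吐", "恶心", "胃", "呕吐"),
                  sem_type = c("symptom", "symptom", "symptom", "body structure", "symptom"),
                  stringsAsFactors = FALSE)
  dd <- dedupe(m)
  expect_equal(nrow(dd$keys), 3)
  expect_length(dd$map, 5)
  expect_identical(dd$keys$surface[dd$map], m$surface)
  expect_identical(dd$keys$sem_type[dd$map], m$sem_type)
  empty <- dedupe(m[0, ])
  expect_equal(nrow(empty$keys), 0)
  expect_length(empty$map, 0)
})

test_that("hierarchical matching respects stage order and class scoping", {
  kb <- load_concepts()
  hit <- hierarchical_match("恶心", "symptom", kb)
  expect_equal(hit$method, "exact-concept"); expect_equal(hit$score, 1)
  ## synonym only: second stage
  hit2 <- hierarchical_match("希罗达", "medicine", kb)
  expect_equal(hit2$method, "exact-property")
  expect_equal(hit2$concept_id, "C0402")
  ## class scoping: the same surface in the wrong class finds nothing
  expect_null(hierarchical_match("恶心", "body structure", kb))
  expect_error(hierarchical_match("x", "tumor size", kb), "not linkable")
  ## scoped search equals a brute-force class-filtered search
  schema <- build_default_schema()
  set.seed(30)
  types <- c("disease", "symptom", "sign", "surgery", "medicine", "test",
             "disease type", "body structure")
  surfaces <- c(kb$preferred, unlist(kb$synonyms))
  for (i in 1:200) {
    st <- sample(types, 1); surf <- sample(surfaces, 1)
    got <- hierarchical_match(surf, st, kb, schema)
    scope <- dstkg:::class_descendants(dstkg:::span_type_class(st), schema)
    sub <- kb[kb$class %in% scope, ]
    sub <- sub[order(sub$concept_id), ]
    want <- NULL
    j <- which(sub$preferred == surf)
    if (length(j)) want <- sub$concept_id[j[1]]
    else {
      j <- which(vapply(seq_len(nrow(sub)), function(r)
        surf %in% c(sub$synonyms[[r]], sub$english[r], unname(sub$properties[[r]])), NA))
      if (length(j)) want <- sub$concept_id[j[1]]
    }
    expect_identical(got$concept_id, want)
  }
})

test_that("dictionary expansion maps abbreviations and never echoes the input", {
  expect_equal(dictionary_expand("胃癌根治"), "胃癌根治术")
  expect_equal(dictionary_expand("绝不存在"), character())
  d <- load_dictionaries()
  for (s in unique(d$surface)) expect_false(s %in% dictionary_expand(s))
})

test_that("cosine ranking matches exhaustive recomputation and its edge cases", {
  kb <- load_concepts()
  cand <- kb[kb$class %in% c("symptom", "sign"), ]
  r <- similarity_rank("恶心", cand, threshold = 0)
  expect_equal(r$score[1], 1); expect_equal(r$concept_id[1], "C0101")
  expect_equal(similarity_rank("XYZW", cand, threshold = 0)$score,
               rep(0, nrow(cand))) # disjoint character sets
  ## brute-force pairwise recomputation, including the tie-break
  set.seed(31)
  cosine <- function(a, b) {
    bg <- function(s) { cs <- strsplit(s, "")[[1]]
      if (length(cs) < 2) return(table(s))
      table(paste0(cs[-length(cs)], cs[-1])) }
    ta <- bg(a); tb <- bg(b); sh <- intersect(names(ta), names(tb))
    if (!length(sh)) return(0)
    sum(as.numeric(ta[sh]) * as.numeric(tb[sh])) /
      sqrt(sum(as.numeric(ta)^2) * sum(as.numeric(tb)^2))
  }
  for (i in 1:20) {
    surf <- sample(c(kb$preferred, "上腹部闷痛不适", "胃体部溃疡"), 1)
    sub <- cand[sample(nrow(cand), 10), ]
    got <- similarity_rank(surf, sub, threshold = 0)
    want <- vapply(seq_len(nrow(sub)), function(r)
      max(vapply(unique(c(sub$preferred[r], sub$synonyms[[r]])), cosine, 0, a = surf)), 0)
    ord <- order(-want, sub$concept_id)
    expect_equal(got$concept_id, sub$concept_id[ord])
    expect_equal(got$score, want[ord], tolerance = 1e-12)
  }
  ## duplicating a synonym list entry does not change the ranking
  dup <- cand
  dup$synonyms[[1]] <- rep(dup$synonyms[[1]], 3)
  expect_equal(similarity_rank("上腹部不适感", dup, 0)$concept_id,
               similarity_rank("上腹部不适感", cand, 0)$concept_id)
})

test_that("exact matches preempt similarity and linking is exact on gold corpora", {
  co <- small_corpus()[1:25]
  for (d in co) {
    lm <- link_mentions(d$mentions)
    ent <- !is.na(vapply(lm$sem_type, dstkg:::span_type_class, ""))
    expect_identical(lm$concept_id[ent], lm$gold_concept[ent], info = d$patient_id)
    expect_true(all(lm$link_score[ent] >= 0 & lm$link_score[ent] <= 1))
    ## exact-matchable surfaces never report the similarity method
    kb <- load_concepts()
    exactable <- lm$surface %in% c(kb$preferred, unlist(kb$synonyms))
    expect_false(any(lm$link_method[ent & exactable] == "similarity"))
  }
  ## a near-miss surface falls through to similarity, above threshold
  m <- data.frame(surface = "上腹部闷痛感", sem_type = "symptom", stringsAsFactors = FALSE)
  lm <- link_mentions(m)
  expect_equal(lm$link_method, "similarity")
  expect_lt(lm$link_score, 1)
  expect_equal(lm$concept_id, "C0105")
})
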