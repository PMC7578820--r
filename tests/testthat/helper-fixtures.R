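# Shared fixtures and independent oracles. Corpora are generated in code
# (no stored fixtures); expensive objects are cached per test run.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- force(expr)
  .fixture_env[[name]]
}

small_corpus <- function() cached("small_corpus",
  generate_corpus(corpus_config(n_patients = 60, seed = 101)))

## brute-force CRF oracle: enumerate every label sequence
brute_crf <- function(emissions, transitions, start, stop) {
  nt <- nrow(emissions); k <- ncol(emissions)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(k)), nt)))
  sc <- apply(seqs, 1, function(y) {
    s <- start[y[1]] + stop[y[nt]] + sum(emissions[cbind(seq_len(nt), y)])
    if (nt > 1) s <- s + sum(transitions[cbind(y[-nt], y[-1])])
    s
  })
  best <- which.max(sc) # expand.grid enumerates in lexicographic-first order
  list(logZ = log(sum(exp(sc - max(sc)))) + max(sc),
       best_score = max(sc), best_path = unname(seqs[best, ]))
}

## Fig 7-style fixture: n patients with rectal adenocarcinoma, printed
## per-treatment patient counts, TrAD edges treatment -> disease
treatment_fixture_graph <- function(counts = c(
                                      "Miles手术" = 365, "奥沙利铂" = 110,
                                      "XELOX方案" = 80, "卡培他滨" = 58,
                                      "替加氟" = 44, "亚叶酸钙制剂" = 29,
                                      "氟尿嘧啶" = 15, "FOLFOX方案" = 15,
                                      "Hartmann手术" = 15),
                                    n_patients = 731,
                                    disease = "直肠腺癌") {
  nodes <- list(); edges <- list()
  for (p in seq_len(n_patients)) {
    pid <- sprintf("p%04d", p)
    nodes[[length(nodes) + 1L]] <- data.frame(
      node_id = paste0("entity:", pid, ":DIS:1"), kind = "entity", label = disease,
      class = "disease", stringsAsFactors = FALSE)
  }
  for (ti in seq_along(counts)) {
    tname <- names(counts)[ti]
    for (p in seq_len(counts[[ti]])) {
      pid <- sprintf("p%04d", p)
      nid <- paste0("entity:", pid, ":T", ti, ":1")
      nodes[[length(nodes) + 1L]] <- data.frame(
        node_id = nid, kind = "entity", label = tname, class = "treatment",
        stringsAsFactors = FALSE)
      edges[[length(edges) + 1L]] <- data.frame(
        head = nid, tail = paste0("entity:", pid, ":DIS:1"), label = "TrAD",
        stringsAsFactors = FALSE)
    }
  }
  property_graph(do.call(rbind, nodes), do.call(rbind, edges))
}

## printed per-label relation counts (12 rows, N = 11,005)
relation_census <- c(TeCD = 96, TeRD = 990, TeRS = 2035, TeAS = 486,
                     TrAD = 980, TrCD = 2, TrAS = 613, TrCS = 326,
                     DCS = 29, SID = 261, LOCI = 3330, attribute_of = 1857)

## printed per-class entity counts (7 categories, N = 9,868)
entity_census <- c("disease" = 1002, "disease type" = 452,
                   "body structure" = 1874, "treatment" = 1606,
                   "clinical finding" = 2786, "test" = 924,
                   "properties of disease type" = 1224)

## fixture graph carrying exactly the printed censuses: one level-3 node
## per entity, one edge per relation (endpoints on two hub entities)
census_fixture_graph <- function() {
  n_ent <- sum(entity_census)
  cls <- rep(names(entity_census), entity_census)
  kind <- ifelse(cls == "properties of disease type", "property-value", "entity")
  nodes <- data.frame(node_id = sprintf("entity:p0001:C%05d:1", seq_len(n_ent)),
                      kind = kind, label = cls, class = cls, stringsAsFactors = FALSE)
  heads <- rep(nodes$node_id[1], sum(relation_census))
  tails <- rep(nodes$node_id[2], sum(relation_census))
  edges <- data.frame(head = heads, tail = tails,
                      label = rep(names(relation_census), relation_census),
                      stringsAsFactors = FALSE)
  property_graph(nodes, edges)
}

## build a gold-labeled candidate corpus (relation classifier training data)
gold_candidates <- function(corpus) dstkg:::re_training_data(corpus)
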