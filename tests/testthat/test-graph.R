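## a minimal linked one-patient document
mini_doc <- function() {
  list(patient_id = "p1", text = "患者患有直肠腺癌。",
       mentions = data.frame(id = 1L, start = 4L, end = 8L, surface = "直肠腺癌",
                             sem_type = "disease", state = "positive",
                             concept_id = "C0001", stringsAsFactors = FALSE),
       relations = data.frame(head = 0L, tail = 1L, label = "has_a",
                              stringsAsFactors = FALSE))
}

test_that("minimal construction yields the three-tier patient graph", {
  g <- build_graph(list(mini_doc()))
  expect_setequal(g$nodes$kind, c("patient", "class", "concept", "entity"))
  expect_setequal(g$edges$label, c("has_a", "instance_of", "is_a"))
  ## styling/level contracts
  pn <- g$nodes[g$nodes$kind == "patient", ]
  en <- g$nodes[g$nodes$kind == "entity", ]
  expect_equal(pn$color, "#e74c3c"); expect_equal(pn$level, 1L)
  expect_equal(en$color, "#2ecc71"); expect_equal(en$level, 3L)
  expect_true(all(pn$size > g$nodes$size[g$nodes$kind != "patient"]))
  expect_true(all(en$size <= g$nodes$size))
  ## empty input
  e <- build_graph(list())
  expect_equal(nrow(e$nodes), 0); expect_equal(nrow(e$edges), 0)
  expect_equal(count_summary(e)$n_entities, 0)
  expect_equal(count_summary(e)$n_relations, 0)
})

test_that("knowledge-base data properties become attribute_of edges", {
  ## the bundled KB carries pathological stage pT1N0M0 on C0003
  doc <- mini_doc()
  doc$mentions$concept_id <- "C0003"
  doc$mentions$surface <- "胃原发性恶性肿瘤"
  g <- build_graph(list(doc))
  val <- g$nodes[g$nodes$kind == "property-value", ]
  expect_equal(val$label, "pT1N0M0")
  att <- g$edges[g$edges$label == "attribute_of", ]
  expect_equal(att$head, "concept:C0003")
  expect_equal(att$tail, val$node_id)
})

test_that("graphs from linked corpora are closed and schema-valid", {
  co <- small_corpus()[1:20]
  linked <- lapply(co, function(d) { d$mentions <- link_mentions(d$mentions); d })
  g <- build_graph(linked)
  expect_equal(anyDuplicated(g$nodes$node_id), 0)
  expect_true(all(g$edges$head %in% g$nodes$node_id))
  expect_true(all(g$edges$tail %in% g$nodes$node_id))
  expect_true(all(g$edges$label %in% names(build_default_schema()$relations)))
  ## every entity node has an incoming has_a or instance_of edge
  ents <- g$nodes$node_id[g$nodes$kind == "entity"]
  anchored <- g$edges$tail[g$edges$label %in% c("has_a", "instance_of")]
  expect_true(all(ents %in% anchored))
  ## the display tiers are derivable from node levels alone
  expect_setequal(g$nodes$kind[g$nodes$level == 1L], c("patient", "class"))
  expect_setequal(g$nodes$kind[g$nodes$level == 2L], "concept")
  expect_true(all(g$nodes$kind[g$nodes$level == 3L] %in% c("entity", "property-value")))
  ## a schema-violating relation is rejected with the edge identified
  bad <- list(patient_id = "bad", text = "胃镜检查示胃。",
              mentions = data.frame(id = 1:2, start = c(0L, 5L), end = c(4L, 6L),
                                    surface = c("胃镜检查", "胃"),
                                    sem_type = c("test", "body structure"),
                                    state = "not-applicable",
                                    concept_id = c("C0501", "C0701"),
                                    stringsAsFactors = FALSE),
              relations = data.frame(head = 1L, tail = 2L, label = "LOCI",
                                     stringsAsFactors = FALSE))
  expect_error(build_graph(list(bad)), "schema violation.*LOCI")
})

test_that("patient_subgraph reproduces two-hop reachability", {
  co <- small_corpus()[1:10]
  linked <- lapply(co, function(d) { d$mentions <- link_mentions(d$mentions); d })
  g <- build_graph(linked)
  pid <- co[[3]]$patient_id
  sg <- patient_subgraph(g, pid)
  ## brute-force reference traversal
  pnode <- paste0("patient:", pid)
  b <- g$edges$tail[g$edges$head == pnode & g$edges$label == "has_a"]
  reach <- unique(c(pnode, b, g$edges$tail[g$edges$head %in% b]))
  expect_setequal(sg$nodes$node_id, reach)
  expect_true(all(sg$edges$edge_id %in% g$edges$edge_id |
                    paste(sg$edges$head, sg$edges$tail) %in% paste(g$edges$head, g$edges$tail)))
  ## a patient with no has_a edges yields a singleton subgraph
  lone <- list(patient_id = "hermit", text = "",
               mentions = mini_doc()$mentions[0, ], relations = mini_doc()$relations[0, ])
  g2 <- build_graph(list(lone))
  sg2 <- patient_subgraph(g2, "hermit")
  expect_equal(nrow(sg2$nodes), 1); expect_equal(nrow(sg2$edges), 0)
  expect_error(patient_subgraph(g, "no-such-patient"), "unknown patient")
})

test_that("treatment_frequency reproduces printed percentages and sorts by count", {
  g <- treatment_fixture_graph()
  tf <- treatment_frequency(g, "直肠腺癌", 731)
  expect_equal(tf$treatment[1:3], c("Miles手术", "奥沙利铂", "XELOX方案"))
  expect_equal(tf$count[1:3], c(365L, 110L, 80L))
  expect_equal(tf$percent[1:3], c(50, 15, 11))
  expect_equal(sort(tf$percent, decreasing = TRUE), tf$percent)
  ## internal consistency: percents recomputable from counts
  expect_equal(tf$percent, floor(100 * tf$count / 731 + 0.5))
  ## absent disease and zero counts
  expect_equal(nrow(treatment_frequency(g, "不存在病", 731)), 0)
  expect_error(treatment_frequency(g, "直肠腺癌", 0), "positive")
})

test_that("count_summary totals equal the sums of their categories", {
  g <- census_fixture_graph()
  cs <- count_summary(g)
  expect_equal(cs$n_entities, sum(cs$entities))
  expect_equal(cs$n_relations, sum(cs$relations))
  expect_equal(cs$n_entities, 9868)
  expect_equal(cs$n_relations, 11005)
})

test_that("exports are valid and the JSON dump round-trips isomorphically", {
  co <- small_corpus()[1:12]
  linked <- lapply(co, function(d) { d$mentions <- link_mentions(d$mentions); d })
  g <- build_graph(linked)
  fj <- withr::local_tempfile(fileext = ".json")
  export_graph(g, fj, "json")
  g2 <- import_graph_json(fj)
  expect_equal(g2$nodes, g$nodes, ignore_attr = TRUE)
  expect_equal(g2$edges, g$edges, ignore_attr = TRUE)
  ## graphml parses and carries every node and edge
  fg <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, fg, "graphml")
  x <- xml2::read_xml(fg)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(x), d1 = "g")
  expect_length(xml2::xml_find_all(x, "//g:node", ns), nrow(g$nodes))
  expect_length(xml2::xml_find_all(x, "//g:edge", ns), nrow(g$edges))
  labels <- xml2::xml_text(xml2::xml_find_all(x, "//g:edge/g:data[@key='d_elabel']", ns))
  expect_true(all(labels %in% names(build_default_schema()$relations)))
  ## cypher script: one CREATE per node and per edge
  fc <- withr::local_tempfile(fileext = ".cypher")
  export_graph(g, fc, "cypher")
  lines <- readLines(fc, encoding = "UTF-8")
  expect_equal(sum(grepl("^CREATE \\(:", lines)), nrow(g$nodes))
  expect_equal(sum(grepl("^MATCH ", lines)), nrow(g$edges))
  ## empty graph per format
  ge <- property_graph()
  for (fmt in c("json", "graphml", "cypher")) {
    f <- withr::local_tempfile()
    expect_no_error(export_graph(ge, f, fmt))
  }
  expect_error(export_graph(g, withr::local_tempfile(), "dot"), "arg")
})
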