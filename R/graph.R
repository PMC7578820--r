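## Patient-centered property graph: assembly from linked documents, the
## three display tiers (patient/class, concept, entity) with the fixed
## styling palette, subgraph and statistics queries, and exports to
## GraphML / Cypher / JSON.

.NODE_STYLE <- list(
  "patient" = list(level = 1L, color = "#e74c3c", size = 60), # red, largest
  "class" = list(level = 1L, color = "#8e44ad", size = 50),
  "concept" = list(level = 2L, color = "#f39c12", size = 40),
  "entity" = list(level = 3L, color = "#2ecc71", size = 20), # green, smallest
  "property-value" = list(level = 3L, color = "#95a5a6", size = 20))

.EDGE_COLORS <- c("instance_of" = "#e67e22", # orange
                  "TeRS" = "#ff69b4",        # pink
                  "TrAD" = "#2ecc71",        # green
                  ".default" = "#7f8c8d")

edge_color <- function(label) {
  unname(ifelse(label %in% names(.EDGE_COLORS), .EDGE_COLORS[label], .EDGE_COLORS[[".default"]]))
}

empty_nodes <- function() data.frame(node_id = character(), kind = character(),
                                     label = character(), level = integer(),
                                     color = character(), size = numeric(),
                                     class = character(), stringsAsFactors = FALSE)
empty_edges <- function() data.frame(edge_id = character(), head = character(),
                                     tail = character(), label = character(),
                                     color = character(), provenance = character(),
                                     stringsAsFactors = FALSE)

#' Construct a property graph from node and edge tables
#'
#' @param nodes data.frame with `node_id`, `kind`, `label`, `level`,
#'   `color`, `size`, `class` (missing style columns are filled from the
#'   default palette).
#' @param edges data.frame with `head`, `tail`, `label` and optional
#'   `color`/`provenance`.
#' @return A `dstkg_graph`.
#' @export
property_graph <- function(nodes = empty_nodes(), edges = empty_edges()) {
  if (nrow(nodes)) {
    if (anyDuplicated(nodes$node_id)) stopf("duplicate node ids")
    style <- .NODE_STYLE[nodes$kind]
    if (any(vapply(style, is.null, NA))) stopf("unknown node kind")
    if (is.null(nodes$level)) nodes$level <- vapply(style, `[[`, 1L, "level")
    if (is.null(nodes$color)) nodes$color <- vapply(style, `[[`, "", "color")
    if (is.null(nodes$size)) nodes$size <- vapply(style, `[[`, 0, "size")
    if (is.null(nodes$class)) nodes$class <- NA_character_
  }
  if (nrow(edges)) {
    if (is.null(edges$edge_id)) edges$edge_id <- sprintf("e%d", seq_len(nrow(edges)))
    if (is.null(edges$color)) edges$color <- edge_color(edges$label)
    if (is.null(edges$provenance)) edges$provenance <- "structural"
    miss <- setdiff(c(edges$head, edges$tail), nodes$node_id)
    if (length(miss)) stopf("dangling edge endpoint(s): %s", paste(utils::head(miss, 3), collapse = ", "))
  }
  structure(list(nodes = nodes, edges = edges), class = "dstkg_graph")
}

#' @export
print.dstkg_graph <- function(x, ...) {
  cat(sprintf("<dstkg_graph: %d nodes, %d edges>\n", nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

## top-level ancestor of a concept class (disease, treatment, ...)
top_ancestor <- function(cls, schema) {
  a <- class_ancestry(cls, schema)
  a[length(a)]
}

#' Assemble the patient-centered knowledge graph from linked documents
#'
#' One patient node per document (level 1); one concept node per linked
#' concept (level 2); one entity node per (patient, concept) fact
#' (level 3). Structural edges: `has_a` patient to each entity of the
#' disease / clinical finding / test / treatment classes, `instance_of`
#' concept to entity, `is_a` concept to its class node, and `attribute_of`
#' concept to data-property values (from the knowledge base and from
#' gold/predicted attribute relations). Mention-level relations are lifted
#' to the corresponding entity nodes; every edge is validated against the
#' schema and the offending edge is reported otherwise.
#'
#' @param docs Documents whose mentions carry `concept_id` (from
#'   [link_mentions()], or gold `gold_concept`) and whose `relations` hold
#'   mention-level relations (mention ids; head 0 = patient).
#' @param schema A `dstkg_schema`.
#' @param concepts Knowledge base (for concept labels, classes, property
#'   values).
#' @return A `dstkg_graph`.
#' @export
build_graph <- function(docs, schema = build_default_schema(), concepts = load_concepts()) {
  nodes <- list(); edges <- list()
  seen_node <- new.env(parent = emptyenv())
  seen_edge <- new.env(parent = emptyenv())
  add_node <- function(id, kind, label, class = NA_character_) {
    if (!is.null(seen_node[[id]])) return(invisible())
    st <- .NODE_STYLE[[kind]]
    nodes[[length(nodes) + 1L]] <<- data.frame(
      node_id = id, kind = kind, label = label, level = st$level,
      color = st$color, size = st$size, class = class, stringsAsFactors = FALSE)
    seen_node[[id]] <- TRUE
  }
  add_edge <- function(head, tail, label, provenance, head_class = NULL, tail_class = NULL) {
    key <- paste(head, label, tail, sep = "\r")
    if (!is.null(seen_edge[[key]])) return(invisible())
    if (!is.null(head_class)) {
      verdict <- validate_edge(head_class, label, tail_class, schema)
      if (verdict != "valid")
        stopf("schema violation (%s): %s -[%s]-> %s", verdict, head_class, label, tail_class)
    }
    edges[[length(edges) + 1L]] <<- data.frame(
      head = head, tail = tail, label = label, color = edge_color(label),
      provenance = provenance, stringsAsFactors = FALSE)
    seen_edge[[key]] <- TRUE
  }
  kb <- concepts[!duplicated(concepts$concept_id), , drop = FALSE]
  rownames(kb) <- kb$concept_id
  concept_node <- function(cid) {
    row <- kb[cid, ]
    ncls <- row$class
    add_node(paste0("class:", top_ancestor(ncls, schema)), "class",
             top_ancestor(ncls, schema), top_ancestor(ncls, schema))
    add_node(paste0("concept:", cid), "concept", row$preferred, ncls)
    add_edge(paste0("concept:", cid), paste0("class:", top_ancestor(ncls, schema)),
             "is_a", "structural")
    ## knowledge-base data-property values
    props <- row$properties[[1]]
    for (k in names(props)) {
      vid <- paste0("value:", k, ":", props[[k]])
      add_node(vid, "property-value", props[[k]], k)
      add_edge(paste0("concept:", cid), vid, "attribute_of", "structural")
    }
    paste0("concept:", cid)
  }

  for (doc in docs) {
    pid <- paste0("patient:", doc$patient_id)
    add_node(pid, "patient", doc$patient_id, "patient")
    m <- doc$mentions
    if (!is.null(m$concept_id)) cid_col <- m$concept_id
    else if (!is.null(m$gold_concept)) cid_col <- m$gold_concept
    else cid_col <- rep(NA_character_, nrow(m))
    entity_node <- function(i) {
      cid <- cid_col[i]
      cn <- concept_node(cid)
      eid <- paste0("entity:", doc$patient_id, ":", cid, ":1")
      if (is.null(seen_node[[eid]])) {
        add_node(eid, "entity", kb[cid, "preferred"], kb[cid, "class"])
        add_edge(cn, eid, "instance_of", "structural")
        if (top_ancestor(kb[cid, "class"], schema) %in%
              c("disease", "clinical finding", "test", "treatment"))
          add_edge(pid, eid, "has_a", "structural", "patient", kb[cid, "class"])
      }
      eid
    }
    linked <- which(!is.na(cid_col) & cid_col %in% kb$concept_id)
    for (i in linked) entity_node(i)
    r <- doc$relations
    if (!is.null(r) && nrow(r)) for (j in seq_len(nrow(r))) {
      lab <- r$label[j]
      if (lab %in% c("has_a", "is_a", "instance_of")) next # produced structurally
      hrow <- match(r$head[j], m$id); trow <- match(r$tail[j], m$id)
      if (lab == "attribute_of") {
        ## concept -> property value from a mention-level attribution
        if (is.na(hrow) || is.na(trow) || !(hrow %in% linked)) next
        vid <- paste0("value:", m$sem_type[trow], ":", m$surface[trow])
        add_node(vid, "property-value", m$surface[trow], m$sem_type[trow])
        add_edge(paste0("concept:", cid_col[hrow]), vid, "attribute_of",
                 r$provenance[j] %||% "structural")
        next
      }
      if (is.na(hrow) || is.na(trow)) next
      if (!(hrow %in% linked) || !(trow %in% linked)) next
      add_edge(entity_node(hrow), entity_node(trow), lab,
               r$provenance[j] %||% "rule",
               m$sem_type[hrow], m$sem_type[trow])
    }
  }
  property_graph(if (length(nodes)) do.call(rbind, nodes) else empty_nodes(),
                 if (length(edges)) do.call(rbind, edges) else empty_edges())
}

#' Extract a patient's neighborhood subgraph
#'
#' Mirrors the two-hop query pattern
#' `(patient)-[has_a]->(b)-[r]->(c)`: the patient node, everything it
#' `has_a`, and one further outgoing hop from those nodes.
#'
#' @param graph A `dstkg_graph`.
#' @param patient_id Patient identifier (node label).
#' @return A `dstkg_graph` whose nodes/edges are subsets of the input.
#' @export
patient_subgraph <- function(graph, patient_id) {
  pid <- paste0("patient:", patient_id)
  if (!pid %in% graph$nodes$node_id) stopf("unknown patient '%s'", patient_id)
  e <- graph$edges
  e1 <- e[e$head == pid & e$label == "has_a", , drop = FALSE]
  b <- unique(e1$tail)
  e2 <- e[e$head %in% b, , drop = FALSE]
  keep_nodes <- unique(c(pid, b, e2$tail))
  keep_edges <- rbind(e1, e2)
  property_graph(graph$nodes[graph$nodes$node_id %in% keep_nodes, , drop = FALSE],
                 keep_edges)
}

#' Treatment frequency for a disease across patients
#'
#' Counts, per treatment concept, the distinct patients holding a `TrAD`
#' edge between one of their entities and the named disease, and reports
#' integer percentages of `n_patients` under round-half-up — the
#' convention that reproduces printed clinic-frequency tables (e.g. 365 of
#' 731 is 50%).
#'
#' @param graph A `dstkg_graph`.
#' @param disease_name Disease display label (concept preferred term).
#' @param n_patients Denominator (total patients in the graph's corpus).
#' @return data.frame `treatment`, `count`, `percent`, sorted by
#'   descending count; zero rows when the disease is absent.
#' @export
treatment_frequency <- function(graph, disease_name, n_patients) {
  if (!is_count(n_patients) || n_patients <= 0) stopf("n_patients must be positive")
  nd <- graph$nodes
  lab <- stats::setNames(nd$label, nd$node_id)
  e <- graph$edges[graph$edges$label == "TrAD", , drop = FALSE]
  if (!nrow(e)) return(data.frame(treatment = character(), count = integer(),
                                  percent = numeric(), stringsAsFactors = FALSE))
  ## entity node ids carry their patient: "entity:<patient>:<concept>:<occ>"
  ent_patient <- function(id) vapply(strsplit(id, ":", fixed = TRUE), `[`, "", 2L)
  hit <- lab[e$head] == disease_name | lab[e$tail] == disease_name
  e <- e[hit, , drop = FALSE]
  if (!nrow(e)) return(data.frame(treatment = character(), count = integer(),
                                  percent = numeric(), stringsAsFactors = FALSE))
  treat <- ifelse(lab[e$head] == disease_name, e$tail, e$head)
  pat <- ent_patient(treat)
  dd <- !duplicated(paste(lab[treat], pat, sep = "\r"))
  counts <- table(lab[treat][dd])
  out <- data.frame(treatment = names(counts), count = as.integer(counts),
                    stringsAsFactors = FALSE)
  out$percent <- round_half_up(100 * out$count / n_patients)
  out[order(-out$count, out$treatment), , drop = FALSE]
}

#' Per-class entity counts and per-label edge counts
#'
#' Level-3 nodes (entities and property values) are grouped by their
#' `class` field; edges by relation label. Totals are the sums of the
#' per-category counts.
#'
#' @param graph A `dstkg_graph`.
#' @return List with `entities` (named counts), `n_entities`, `relations`
#'   (named counts), `n_relations`.
#' @export
count_summary <- function(graph) {
  lv3 <- graph$nodes[graph$nodes$level == 3L, , drop = FALSE]
  ents <- if (nrow(lv3)) table(lv3$class) else table(character())
  rels <- if (nrow(graph$edges)) table(graph$edges$label) else table(character())
  list(entities = c(ents), n_entities = sum(ents),
       relations = c(rels), n_relations = sum(rels))
}

## ---- exports ---------------------------------------------------------------

cypher_quote <- function(x) paste0("'", gsub("'", "\\\\'", x), "'")

#' Export a property graph
#'
#' Formats: `graphml` (schema-valid GraphML with node/edge styling carried
#' as data keys), `cypher` (a CREATE-statement script loadable into a
#' property-graph store), `json` (lossless dump; [import_graph_json()]
#' restores an identical graph).
#'
#' @param graph A `dstkg_graph`.
#' @param path Output file.
#' @param format One of `"graphml"`, `"cypher"`, `"json"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "cypher", "json")) {
  format <- match.arg(format)
  nd <- graph$nodes; ed <- graph$edges
  if (format == "json") {
    jsonlite::write_json(list(nodes = nd, edges = ed), path, dataframe = "rows",
                         na = "null", auto_unbox = FALSE, digits = NA)
  } else if (format == "cypher") {
    lines <- c("// property-graph export (Cypher CREATE script)",
               vapply(seq_len(nrow(nd)), function(i) sprintf(
                 "CREATE (:%s {id: %s, name: %s, level: %d, color: %s, size: %g, class: %s});",
                 gsub("-", "_", nd$kind[i]), cypher_quote(nd$node_id[i]), cypher_quote(nd$label[i]),
                 nd$level[i], cypher_quote(nd$color[i]), nd$size[i],
                 cypher_quote(ifelse(is.na(nd$class[i]), "", nd$class[i]))), ""),
               vapply(seq_len(nrow(ed)), function(i) sprintf(
                 "MATCH (a {id: %s}), (b {id: %s}) CREATE (a)-[:%s {color: %s, provenance: %s}]->(b);",
                 cypher_quote(ed$head[i]), cypher_quote(ed$tail[i]), ed$label[i],
                 cypher_quote(ed$color[i]), cypher_quote(ed$provenance[i])), ""))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    doc <- xml2::xml_new_root("graphml",
                              xmlns = "http://graphml.graphdrawing.org/xmlns")
    keydefs <- list(c("d_kind", "node", "kind", "string"),
                    c("d_label", "node", "label", "string"),
                    c("d_level", "node", "level", "int"),
                    c("d_color", "node", "color", "string"),
                    c("d_size", "node", "size", "double"),
                    c("d_class", "node", "class", "string"),
                    c("d_elabel", "edge", "label", "string"),
                    c("d_ecolor", "edge", "color", "string"),
                    c("d_eprov", "edge", "provenance", "string"))
    for (k in keydefs) {
      xml2::xml_add_child(doc, "key", id = k[1], `for` = k[2],
                          attr.name = k[3], attr.type = k[4])
    }
    gr <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "directed")
    for (i in seq_len(nrow(nd))) {
      n <- xml2::xml_add_child(gr, "node", id = nd$node_id[i])
      vals <- c(d_kind = nd$kind[i], d_label = nd$label[i], d_level = as.character(nd$level[i]),
                d_color = nd$color[i], d_size = as.character(nd$size[i]),
                d_class = ifelse(is.na(nd$class[i]), "", nd$class[i]))
      for (k in names(vals)) xml2::xml_add_child(n, "data", vals[[k]], key = k)
    }
    for (i in seq_len(nrow(ed))) {
      e <- xml2::xml_add_child(gr, "edge", id = ed$edge_id[i],
                               source = ed$head[i], target = ed$tail[i])
      vals <- c(d_elabel = ed$label[i], d_ecolor = ed$color[i], d_eprov = ed$provenance[i])
      for (k in names(vals)) xml2::xml_add_child(e, "data", vals[[k]], key = k)
    }
    xml2::write_xml(doc, path)
  }
  invisible(path)
}

#' Import a JSON graph dump
#' @param path File written by `export_graph(..., format = "json")`.
#' @return A `dstkg_graph` structurally identical to the exported one.
#' @export
import_graph_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  nodes <- if (length(raw$nodes)) as.data.frame(raw$nodes, stringsAsFactors = FALSE) else empty_nodes()
  edges <- if (length(raw$edges)) as.data.frame(raw$edges, stringsAsFactors = FALSE) else empty_edges()
  if (nrow(nodes)) nodes$level <- as.integer(nodes$level)
  property_graph(nodes, edges)
}
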