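## Schema layer: classes, subconcept tree, data properties, and the 16
## semantic relationship types with head/tail (domain/range) constraints.
## The schema ships as a versioned JSON file under inst/extdata so that
## classes and relations can be added or removed without touching code.

.dstkg_env <- new.env(parent = emptyenv())

#' Path to the bundled knowledge-graph schema definition
#'
#' @return File path of the versioned JSON schema shipped with the package.
#' @export
dstkg_schema_file <- function() {
  system.file("extdata", "dstkg_schema.json", package = "dstkg", mustWork = TRUE)
}

#' Load a knowledge-graph schema from a definition file
#'
#' Reads a JSON schema definition (classes with parents/data properties and
#' relationship types with head/tail constraints) and validates its
#' structural invariants: unique class and label names, resolvable parents
#' and relation endpoints, and an acyclic subclass tree.
#'
#' @param path Path to a schema JSON file (see [dstkg_schema_file()] for the
#'   bundled default).
#' @return An object of class `dstkg_schema` with elements `classes`
#'   (named list), `relations` (named list) and `schema_version`.
#' @export
load_schema <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  classes <- raw$classes
  names(classes) <- vapply(classes, function(cl) cl$name, "")
  relations <- raw$relations
  names(relations) <- vapply(relations, function(r) r$label, "")
  schema <- structure(
    list(schema_version = raw$schema_version %||% "0",
         description = raw$description %||% "",
         classes = lapply(classes, function(cl) {
           list(name = cl$name,
                parent = cl$parent %||% NA_character_,
                data_properties = as.character(unlist(cl$data_properties)),
                source = cl$source %||% "")
         }),
         relations = lapply(relations, function(r) {
           list(label = r$label,
                definition = r$definition,
                coarse_category = r$coarse_category %||% "",
                structural = isTRUE(r$structural),
                pairs = lapply(r$pairs, function(p) c(head = p$head, tail = p$tail)))
         })),
    class = "dstkg_schema")
  validate_schema(schema)
  schema
}

#' Write a schema back to its JSON definition format
#'
#' `load_schema(dump_schema(s, f))` reproduces `s` exactly (lossless
#' round-trip).
#'
#' @param schema A `dstkg_schema` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
dump_schema <- function(schema, path) {
  stopifnot(inherits(schema, "dstkg_schema"))
  out <- list(
    schema_version = schema$schema_version,
    description = schema$description,
    classes = lapply(unname(schema$classes), function(cl) {
      list(name = cl$name,
           parent = if (is.na(cl$parent)) NULL else cl$parent,
           data_properties = as.list(cl$data_properties),
           source = cl$source)
    }),
    relations = lapply(unname(schema$relations), function(r) {
      list(label = r$label, definition = r$definition,
           coarse_category = r$coarse_category, structural = r$structural,
           pairs = lapply(r$pairs, function(p) list(head = unname(p["head"]), tail = unname(p["tail"]))))
    }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

validate_schema <- function(schema) {
  cls <- names(schema$classes)
  if (anyDuplicated(cls)) stopf("duplicate class names in schema")
  labs <- names(schema$relations)
  if (anyDuplicated(labs)) stopf("duplicate relation labels in schema")
  for (cl in schema$classes) {
    if (!is.na(cl$parent) && !cl$parent %in% cls)
      stopf("class '%s' has undeclared parent '%s'", cl$name, cl$parent)
  }
  ## subclass tree must be acyclic
  for (cl in cls) {
    seen <- character()
    cur <- cl
    while (!is.na(schema$classes[[cur]]$parent)) {
      cur <- schema$classes[[cur]]$parent
      if (cur %in% seen || cur == cl) stopf("cycle in subclass tree at '%s'", cl)
      seen <- c(seen, cur)
    }
  }
  for (r in schema$relations) {
    for (p in r$pairs) {
      for (endp in p) {
        if (!identical(endp, "any-concept") && !endp %in% cls)
          stopf("relation '%s' references undeclared class '%s'", r$label, endp)
      }
    }
  }
  invisible(schema)
}

#' Build the default tumor knowledge-graph schema
#'
#' Returns the bundled schema: 7 top-level classes (patient, disease,
#' disease type, test, body structure, clinical finding, treatment) with
#' their data properties, the subconcept tree (disease into noncancerous
#' disease/cancer, clinical finding into symptom/sign, treatment into
#' surgery/medicine/radiotherapy, test into 4 configurable subconcepts), and
#' 16 relationship types of which 13 are clinical (non-structural) and 3
#' structural (`attribute_of`, `instance_of`, `is_a`).
#'
#' Deterministic and idempotent: repeated calls return equal structures.
#'
#' @param test_subconcepts Optional character vector of exactly 4 names to
#'   use for the subconcepts of class `test` (their names are placeholders;
#'   the source vocabularies leave them unnamed).
#' @return A `dstkg_schema` object.
#' @export
build_default_schema <- function(test_subconcepts = NULL) {
  if (is.null(.dstkg_env$default_schema)) {
    .dstkg_env$default_schema <- load_schema(dstkg_schema_file())
  }
  schema <- .dstkg_env$default_schema
  if (!is.null(test_subconcepts)) {
    old <- names(Filter(function(cl) identical(cl$parent, "test"), schema$classes))
    if (length(test_subconcepts) != length(old))
      stopf("expected %d test subconcept names, got %d", length(old), length(test_subconcepts))
    names(schema$classes)[match(old, names(schema$classes))] <- test_subconcepts
    for (i in seq_along(old)) schema$classes[[test_subconcepts[i]]]$name <- test_subconcepts[i]
  }
  schema
}

#' Names of the 7 top-level schema classes
#' @param schema A `dstkg_schema`.
#' @return Character vector of classes without a parent.
#' @export
top_level_classes <- function(schema = build_default_schema()) {
  names(Filter(function(cl) is.na(cl$parent), schema$classes))
}

#' Data properties declared for a class
#' @param class_name Class identifier.
#' @param schema A `dstkg_schema`.
#' @return Character vector of property names.
#' @export
data_properties <- function(class_name, schema = build_default_schema()) {
  cl <- schema$classes[[class_name]]
  if (is.null(cl)) stopf("unknown class '%s'", class_name)
  cl$data_properties
}

## class_name and all its ancestors, in order
class_ancestry <- function(class_name, schema) {
  cl <- schema$classes[[class_name]]
  if (is.null(cl)) stopf("unknown class '%s'", class_name)
  out <- class_name
  while (!is.na(cl$parent)) {
    out <- c(out, cl$parent)
    cl <- schema$classes[[cl$parent]]
  }
  out
}

## does `x` satisfy a constraint naming `constraint_class`?
## (subclass substitution: a subconcept satisfies its ancestors)
satisfies_class <- function(x, constraint_class, schema) {
  identical(constraint_class, "any-concept") || constraint_class %in% class_ancestry(x, schema)
}

## all declared classes that are constraint_class or a descendant of it
class_descendants <- function(class_name, schema) {
  names(Filter(function(cl) class_name %in% class_ancestry(cl$name, schema), schema$classes))
}

#' Relation labels admissible between two entity classes
#'
#' Because relationship types constrain their head and tail classes, the
#' admissible labels between two mentions are (roughly) determined by their
#' types alone: e.g. disease/test admits only TeCD and TeRD. Matching honours
#' subclass substitution (a `surgery` mention satisfies a `treatment`
#' constraint) and both argument orders; each row records the canonical
#' direction declared in the schema.
#'
#' @param head_type,tail_type Declared class identifiers (the order given by
#'   the caller, e.g. textual order of two mentions).
#' @param schema A `dstkg_schema`.
#' @param include_structural Include `attribute_of`/`instance_of`/`is_a`
#'   (default `FALSE`: those are produced structurally, never classified).
#' @return data.frame with columns `label`, `head_class`, `tail_class` (the
#'   canonical declared pair) and `direction` (`"as-given"` when
#'   (head_type, tail_type) matches the declared order, `"reversed"`
#'   otherwise). Zero rows when no label is admissible.
#' @export
allowed_relations <- function(head_type, tail_type, schema = build_default_schema(),
                              include_structural = FALSE) {
  for (x in c(head_type, tail_type)) {
    if (is.null(schema$classes[[x]])) stopf("unknown class '%s'", x)
  }
  rows <- list()
  for (r in schema$relations) {
    if (r$structural && !include_structural) next
    for (p in r$pairs) {
      fwd <- satisfies_class(head_type, p["head"], schema) && satisfies_class(tail_type, p["tail"], schema)
      rev <- satisfies_class(tail_type, p["head"], schema) && satisfies_class(head_type, p["tail"], schema)
      if (fwd || rev) {
        rows[[length(rows) + 1L]] <- data.frame(
          label = r$label, head_class = unname(p["head"]), tail_class = unname(p["tail"]),
          direction = if (fwd) "as-given" else "reversed",
          stringsAsFactors = FALSE)
        break
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(label = character(), head_class = character(),
                      tail_class = character(), direction = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Validate a typed edge against the schema
#'
#' @param head_class,tail_class Declared class identifiers of the edge
#'   endpoints.
#' @param label A declared relation label.
#' @param schema A `dstkg_schema`.
#' @return `"valid"` if (head, tail) matches the label's declared pair(s)
#'   under subclass substitution, `"wrong-direction"` if only the reversed
#'   pair matches, `"disallowed"` otherwise.
#' @export
validate_edge <- function(head_class, label, tail_class, schema = build_default_schema()) {
  r <- schema$relations[[label]]
  if (is.null(r)) stopf("undeclared relation label '%s'", label)
  ## the structural three (attribute_of/instance_of/is_a) are declared over
  ## "any-concept": endpoints (including property-value kinds) unconstrained
  if (r$structural) return("valid")
  for (x in c(head_class, tail_class)) {
    if (is.null(schema$classes[[x]])) stopf("unknown class '%s'", x)
  }
  fwd <- any(vapply(r$pairs, function(p)
    satisfies_class(head_class, p["head"], schema) && satisfies_class(tail_class, p["tail"], schema), NA))
  if (fwd) return("valid")
  rev <- any(vapply(r$pairs, function(p)
    satisfies_class(tail_class, p["head"], schema) && satisfies_class(head_class, p["tail"], schema), NA))
  if (rev) return("wrong-direction")
  "disallowed"
}

#' @export
print.dstkg_schema <- function(x, ...) {
  ns <- sum(vapply(x$relations, function(r) r$structural, NA))
  cat(sprintf("<dstkg_schema v%s: %d classes (%d top-level), %d relation types (%d structural)>\n",
              x$schema_version, length(x$classes), length(top_level_classes(x)),
              length(x$relations), ns))
  invisible(x)
}
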