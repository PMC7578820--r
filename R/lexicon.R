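## Bundled terminology: a synthetic concept knowledge base (concept id,
## class, preferred/English/nonpreferred terms, data-property values) and the
## 6 surface-form dictionaries used for entity-linking expansion.

#' Load a concept knowledge base from TSV
#'
#' Columns: `concept_id`, `class`, `preferred`, `english`, `synonyms`
#' (`|`-separated), `properties` (`;`-separated `key=value` pairs).
#'
#' @param path TSV path; default is the bundled synthetic knowledge base.
#' @return data.frame with list-columns `synonyms` and `properties`.
#' @export
load_concepts <- function(path = system.file("extdata", "concepts.tsv", package = "dstkg", mustWork = TRUE)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "", encoding = "UTF-8")
  stopifnot(all(c("concept_id", "class", "preferred") %in% names(df)))
  if (anyDuplicated(df$concept_id)) stopf("duplicate concept ids in %s", path)
  df$synonyms <- lapply(df$synonyms, function(s) {
    if (is.na(s) || !nzchar(s)) character() else strsplit(s, "|", fixed = TRUE)[[1]]
  })
  df$properties <- lapply(df$properties, function(s) {
    if (is.na(s) || !nzchar(s)) return(character())
    kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  })
  df
}

#' Load surface-form dictionaries from TSV
#'
#' Columns: `category`, `surface`, `canonical`. Six categories ship by
#' default: disease, drug, surgery, test, symptom/sign, body structure.
#'
#' @param path TSV path; default is the bundled dictionary set.
#' @return data.frame with one row per surface-to-canonical entry.
#' @export
load_dictionaries <- function(path = system.file("extdata", "dictionaries.tsv", package = "dstkg", mustWork = TRUE)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "", encoding = "UTF-8")
  stopifnot(all(c("category", "surface", "canonical") %in% names(df)))
  df
}

## concept class -> mention span type (the 12 NER span types live at the
## subconcept level for clinical finding and treatment; radiotherapy has no
## span type in the annotation scheme and is not generated)
.concept_sem_type <- c(
  "cancer" = "disease", "noncancerous disease" = "disease",
  "symptom" = "symptom", "sign" = "sign",
  "surgery" = "surgery", "medicine" = "medicine",
  "test" = "test", "disease type" = "disease type",
  "body structure" = "body structure")

#' The 12 span types recognized by the sequence tagger
#'
#' Eight entity types plus four data-property types (histological grade,
#' pathological stage, naked eye type, tumor size), recognized as spans and
#' later attached via `attribute_of`.
#' @return Character vector of length 12.
#' @export
span_types <- function() {
  c("body structure", "symptom", "sign", "surgery", "medicine",
    "disease", "disease type", "test",
    "histological grade", "pathological stage", "naked eye type", "tumor size")
}

## span type -> schema class used for relation constraints / linking scope
span_type_class <- function(sem_type) {
  if (sem_type %in% c("histological grade", "pathological stage",
                      "naked eye type", "tumor size")) return(NA_character_)
  sem_type
}
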