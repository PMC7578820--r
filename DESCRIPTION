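Package: dstkg
Title: Digestive System Tumor Knowledge Graphs from Chinese Clinical Text
Version: 0.1.0
Authors@R:
    person("DSTKG", "Maintainers", email = "maintainers@dstkg.example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for building patient-centered knowledge
    graphs of digestive system tumors from Chinese electronic medical record
    (CEMR) free text. Ships a versioned schema (7 classes, 16 semantic
    relationship types with domain/range constraints), a seeded synthetic
    clinical-corpus generator with gold standoff annotations, a character-level
    BiLSTM-CRF named-entity recognizer over 12 span types, rule-based
    negation (state) tagging, schema-constrained relation extraction with a
    dual-attention BiGRU classifier, hierarchical dictionary-backed entity
    linking with cosine-similarity ranking, property-graph assembly with
    GraphML/Cypher/JSON export, and evaluation utilities (entity-level
    precision/recall/F1, intraclass correlation with 95% confidence
    intervals, Likert summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
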