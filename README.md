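# dstkg — digestive system tumor knowledge graphs from Chinese clinical text

`dstkg` builds patient-centered knowledge graphs of digestive-system
tumors from Chinese electronic medical record (CEMR) free text. It is
aimed at clinical NLP researchers and medical-informatics engineers who
need the whole chain in one auditable place:

1. **Schema** — 7 classes (patient, disease, disease type, test, body
   structure, clinical finding, treatment), a subconcept tree, per-class
   data properties, and 16 semantic relationship types (13 clinical with
   head/tail class constraints — TeCD, TeRD, TeRS, TeAS, TrAD, TrCD, TrAS,
   TrCS, DCS, SID, CLAS, LOCI, has_a — plus structural `attribute_of`,
   `instance_of`, `is_a`), shipped as a versioned JSON file.
2. **NER** — a character-level BiLSTM-CRF over 12 span types (8 entity +
   4 property types) with bag-of-characters, POS, position and dictionary
   features, trained by exact CRF maximum likelihood
   (emission/transition scores, forward algorithm, Viterbi decoding).
3. **Assertion** — rule-based positive/negative state tagging driven by
   the negation cues 无明显 / 没有 / 未见 / 不伴 (and bare 无), with
   enumeration-aware cue scope.
4. **Relation extraction** — schema-constrained candidate generation
   (type pairs determine the admissible labels; singletons auto-label) and
   a dual-attention BiGRU classifier for the ambiguous pairs, masked so
   every prediction satisfies the schema.
5. **Entity linking** — per-document dedupe, class-scoped exact matching,
   dictionary expansion (胃癌根治 → 胃癌根治术), and character-bigram
   cosine ranking.
6. **Graph** — three-tier property graph (patient/class → concept →
   entity) with the fixed styling palette, patient subgraphs, treatment
   frequency statistics, entity/relation censuses, and GraphML / Cypher /
   JSON export.
7. **Evaluation** — entity-level P/R/F1, ICC(A,1)/(A,k) with 95% CI and
   the verbal reliability bands, Likert summaries.

The external 731-record corpus behind the original study is not
redistributable, so the package includes a first-class synthetic-corpus
generator (gold mentions, states, relations, standoff/JSONL I/O); every
model is trained and every claim tested against it. See
`vignettes/dstkg-methods.Rmd` for the methods account.

## Worked example

```r
library(dstkg)

schema <- build_default_schema()
schema
#> <dstkg_schema v1.0.0: 18 classes (7 top-level), 16 relation types (3 structural)>

allowed_relations("disease", "test")
#>   label head_class tail_class direction
#> 1  TeCD       test    disease  reversed
#> 2  TeRD       test    disease  reversed
```

A disease/test pair admits exactly the two test–disease labels, in the
canonical direction test → disease: this is what lets candidate
generation auto-label unambiguous pairs and mask the classifier for the
rest.

```r
corpus <- generate_corpus(corpus_config(n_patients = 50, seed = 42))
head(corpus[[2]]$mentions[, c("surface", "sem_type", "state")], 5)
#>            surface sem_type    state
#> 1           肠梗阻  disease positive
#> 2 胃原发性恶性肿瘤  disease negative
#> 3   浅表淋巴结肿大     sign negative
#> 4         肝细胞癌  disease negative
#> 5             腹胀  symptom negative

linked <- lapply(corpus, function(d) { d$mentions <- link_mentions(d$mentions); d })
graph  <- build_graph(linked)
graph
#> <dstkg_graph: 880 nodes, 1696 edges>
export_graph(graph, "graph.json", "json")     # also "graphml", "cypher"
```

Frequency queries reproduce printed-style clinic statistics with
round-half-up integer percentages (counting distinct patients):

```r
treatment_frequency(graph731, "直肠腺癌", 731)
#>   treatment count percent
#> 1 Miles手术   365      50
#> 3  奥沙利铂   110      15
#> 2 XELOX方案    80      11
```

Interrater reliability of a 5-expert rating panel:

```r
r <- icc(ratings)   # raters in rows, items in columns
#> ICC 0.94 (0.79 to 0.99), excellent
```

`icc()` reports the two-way random-effects absolute-agreement
average-measures coefficient with its F-based 95% CI and the verbal band
(perfect / excellent / substantial / moderate / fair / slight).

A command-line interface covering generate / train-ner / tag /
assert-state / link / build-graph / export / stats / eval-icc ships at
`inst/cli/dstkg` (run with `Rscript`).

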