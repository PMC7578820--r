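---
title: "Methods: building tumor knowledge graphs from Chinese clinical text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building tumor knowledge graphs from Chinese clinical text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`dstkg` implements a complete pipeline for turning Chinese electronic
medical record (CEMR) free text about digestive-system tumors into a
patient-centered property graph: a fixed schema constrains what may exist in
the graph; a character-level BiLSTM-CRF finds typed spans; negation rules
assign each disease/finding a positive or negative state; a schema-
constrained BiGRU classifier types the relations between co-occurring
mentions; hierarchical dictionary linking maps surfaces to canonical
concepts; and the assembled graph supports subgraph queries, frequency
statistics, and GraphML/Cypher/JSON export.

Because the original 731-record corpus (a CCKS 2018 shared-task derivative)
is not redistributable, the package ships a first-class synthetic-corpus
generator. All training, evaluation and acceptance checks run against that
generator; nothing in the package requires external data.

# The schema

The schema (shipped as a versioned JSON file, `dstkg_schema.json`) declares
7 top-level classes — patient, disease, disease type, test, body structure,
clinical finding, treatment — with their data properties, a subconcept tree
(disease → noncancerous disease/cancer; clinical finding → symptom/sign;
treatment → surgery/medicine/radiotherapy; test → 4 subconcepts), and 16
relationship types: 13 clinical labels (TeCD, TeRD, TeRS, TeAS, TrAD, TrCD,
TrAS, TrCS, DCS, SID, CLAS, LOCI, has_a) with head/tail class constraints,
plus 3 structural labels (`attribute_of`, `instance_of`, `is_a`).

Design choices where the source material was ambiguous:

* **LOCI domain.** The descriptive text restricts disease–body structure
  pairs to LOCI while the relationship table declares LOCI between clinical
  finding and body structure. We declare LOCI with tail *body structure*
  and a union head {clinical finding, disease}: both readings validate, and
  candidate generation still auto-labels both pairs uniquely.
* **CLAS head.** "Cancer disease type" suggests a cancer-specific head, but
  the coarse category is *disease–disease type* and subclass substitution
  makes cancer valid under a disease-level head while the converse would
  reject disease-level heads. CLAS is declared disease → disease type.
* **has_a** is one label with four endpoint pairs (patient → disease,
  clinical finding, test, treatment).
* **Subclass substitution.** A subconcept satisfies any constraint naming
  its ancestor (surgery satisfies treatment); the relationship table is
  written at the 7-class level.
* **test subconcepts** are never named by the source vocabularies; the
  bundled placeholders (laboratory test, imaging test, endoscopy, pathology
  test) are renameable via `build_default_schema(test_subconcepts = ...)`.
* The three structural labels are declared over "any-concept" and are not
  class-validated: they attach property values, entities and hyponyms to
  concepts of every class.

# The synthetic corpus: what it emulates, and what it does not

`generate_corpus()` renders per-patient documents from sentence templates
keyed by relation label, over a bundled Chinese lexicon (~80 concepts across
the 8 entity span types, with nonpreferred terms and dictionary variants
such as 胃癌根治 for 胃癌根治术). Structural properties the pipeline relies
on, all of which the generator reproduces:

* every sentence mixes at most 2 span types (the candidate-generation
  assumption);
* negated mentions follow a cue from 无明显/没有/未见/不伴/无 within the
  clause, and enumeration commas inside a negated list do not end the cue's
  scope (the 不伴恶心, 呕吐, 返酸, 嗳气 reading);
* relations between co-occurring mentions are determined by the type pair,
  with wording that disambiguates the two-label pairs (示 "reveals" vs
  以排查 "to investigate", 治疗 vs 后并发, …);
* each document opens with an admission-diagnosis sentence, giving every
  patient at least one `has_a` anchor;
* pathology-property sentences pair a disease type with one of the four
  property span types and carry a gold `attribute_of` relation.

Defaults are the stated world: `negation_prob = 0.3` (negation is applied
per disease/finding mention as an independent Bernoulli draw, so the
corpus-wide negated fraction is calibrated to the parameter); the relation
mix is proportioned on the published per-label relation census (TeCD 96 …
LOCI 3330), with weights chosen once for the two labels absent from that
census (CLAS 452, matching the disease-type entity count; has_a 1000);
5–10 sampled sentences per document; a 10% synonym/abbreviation rate;
8:1:1 train/test/validation splits by largest remainder. Radiotherapy
concepts exist in the schema and knowledge base but are not generated:
the annotation scheme's 12 span types include surgery and medicine but no
radiotherapy span.

What the generator does **not** emulate: real clause syntax, discourse
structure, typos, segmentation ambiguity, cross-sentence relations, or
class-overlapping vocabulary at realistic rates. A green label-recovery
test therefore establishes that the models implement their objectives
correctly and can fit a separable corpus at desk scale — it does not
establish field performance on hospital text, and the published
corpus-dependent scores (NER F1 0.9678, RE F1 0.5167) are explicitly out
of scope.

# Sequence models

**NER** is a character-level BiLSTM-CRF over 25 BIO labels (12 span types).
Each character contributes four feature families: the character embedding
(dimension 100 by default), the POS tag of its containing word (one-hot,
from a pluggable segmenter; the bundled fallback does greedy longest-match
over the package lexicon), its relative position in the sentence, and six
dictionary-membership flags. Printed defaults are kept: embedding 100,
batch 50, learning rate 4e-4, dropout 0.5. Unstated knobs are exposed with
conventional values: hidden size 100, Adam, global-norm clip 5, early
stopping on validation entity F1 with patience 5. Training minimizes the
negative CRF log-likelihood; all forward/backward passes are hand-written
batched matrix algebra and are verified in the test suite against
brute-force enumeration (CRF partition and Viterbi, tolerance 1e-6) and
numerical differentiation (every parameter tensor).

Decoding repairs invalid BIO transitions (orphan `I-X` becomes `B-X`).
Viterbi ties break toward the smallest label index at each step.

**Relation extraction** first generates candidates: mentions grouped by
span type; each unordered pair of distinct types with a nonempty admissible
label set contributes its full cross product; a singleton admissible set
auto-labels the candidate, the rest go to the classifier. The classifier is
a character BiGRU with boundary markers inserted around the two mentions
(the minimal mechanism making the pair identifiable), word-level attention
pooling characters into an instance vector, and sentence-level attention
pooling the instances that share (document, head surface, tail surface) —
for singleton bags it degenerates to identity. A `no_relation` class covers
co-occurring pairs without an asserted relation. At prediction time scores
are renormalized over the candidate's admissible labels, so no emitted edge
can violate the schema; the predicted label's canonical direction from the
schema is applied regardless of textual order.

# Negation rules

A disease/finding mention is negative iff a cue precedes it in the same
clause. Hard boundaries (。！？；;) always end a cue's scope; commas end it
unless the following clause consists only of disease/finding mentions plus
closed-class filler (等, 及, 和, whitespace) — the enumeration reading.
Bare 无 is a cue by default (the record-narrative reading of 无阵发性加剧);
passing `cues = c("无明显", "没有", "未见", "不伴")` restores the strict
four-cue reading. Cue matches inside mention spans are ignored. The rule is
deterministic, idempotent, and monotone in the cue list.

# Entity linking

Per document, mentions are deduplicated into (surface, span type) keys.
Each key is matched hierarchically: the span type scopes the search to the
concepts of its schema class and subclasses; stage 1 matches preferred
terms exactly, stage 2 nonpreferred terms, English names and property
values; unmatched keys are expanded through the six dictionaries and
re-matched; the residue is ranked by cosine similarity over
character-bigram count vectors (maximum over each concept's terms),
descending, ties by concept id, with links below 0.5 dropped. Bigram counts
were chosen because the reference procedure names only "cosine similarity":
they are robust for Chinese, dependency-free, and exactly reproducible by
the exhaustive recomputation oracle in the tests. The threshold 0.5 is a
package default (none is stated); top-1 is kept, with `similarity_rank()`
exposing the full ranking for top-k use.

# Graph construction and statistics

One patient node per document (level 1, red, largest); one concept node per
linked concept (level 2); one entity node per (patient, concept) fact
(level 3, green, smallest); property values as level-3 value nodes.
Structural edges — `has_a` from patient to each entity of the four
patient-fact classes, `instance_of` concept → entity, `is_a` concept →
class node, `attribute_of` concept → property value (both from the
knowledge base and from attribution relations in the text) — are produced
by construction, never by the classifier. Mention-level relations are
lifted to entity nodes and every edge is validated against the schema; a
violating edge aborts the build naming the edge. Edge palette: instance_of
orange, TeRS pink, TrAD green, the rest a fixed gray; the remaining palette
is arbitrary but frozen.

`treatment_frequency()` counts *distinct patients* per treatment holding a
TrAD edge to the named disease and reports integer percentages under
round-half-up — the convention that reproduces all printed frequencies
(365/731 → 50, 110/731 → 15, 80/731 → 11, 58/731 → 8, 44/731 → 6,
29/731 → 4, 15/731 → 2) from their fractions. Counting patients rather
than edge instances resolves the duplicate-treatment ambiguity: the printed
fractions are per 731 patients.

# Reliability statistics

`icc()` implements the two-way random-effects, absolute-agreement
intraclass correlation. The default form is average-measures (ICC(A,k)):
five raters scored every item and one coefficient is reported per
dimension; `form = "single"` switches to ICC(A,1). The 95% CI uses the
F-approximation with Satterthwaite degrees of freedom; average-measure
bounds are the Spearman–Brown step-up of the single-measure bounds. The
implementation is frozen against an independent reference implementation
in the test suite and recovers analytic values on simulated two-way data.
The printed category bands leave (0.80, 0.81] unassigned; bands are
half-open with "excellent" strictly above 0.81, so the gap folds into
"substantial" (0.97 → excellent, 0.76 → substantial, 0.23 → fair, exact
1.0 → perfect). Verbal quality labels for mean Likert scores are not
computed: no numeric bands for them are published.

# Numerical choices and degenerate inputs

* CRF forward/backward run in log space via a scaled exp-matrix product —
  exact up to float rounding for any finite scores.
* LSTM/GRU padding masks zero the hidden/cell state, so the time-reversed
  pass starts fresh when crossing from padding into a real sequence;
  gradients at padded positions are identically zero.
* F1 and precision/recall use the 0/0 → 0 convention.
* Degenerate inputs are rejected loudly: empty training sets, single-label
  relation corpora, constant rating matrices, overlapping gold spans,
  out-of-text mention offsets, degenerate split ratios.
* Largest-remainder splitting breaks remainder ties toward the earlier
  partition, making 1 document under 8:1:1 go to the training set.

# Scale of the shipped tests

The acceptance suite trains the NER on 300 synthetic documents and the
relation classifier on ≥2000 candidates with reduced model sizes
(embedding/hidden 48 and 32, higher learning rate, ≤6 epochs) so the whole
suite fits a single-CPU budget of minutes; the paper-default
hyperparameters remain the package defaults. Published corpus-dependent F1
values are not reproduced — the underlying corpus is external — and the
label-recovery thresholds (entity F1 ≥ 0.90, relation accuracy ≥ 0.85)
stand in for them, as stated in the acceptance contract.

# Known limitations

* Only positive/negative assertion states are modeled (no uncertainty,
  hypothetical, or family-history classes).
* No live Neo4j/Bolt connectivity: exports only.
* The bundled segmenter is a longest-match fallback, not a real lexical
  analyzer; POS features degrade gracefully to the coarse scheme on
  out-of-lexicon text.
* Cross-sentence relations are out of scope; the concept knowledge base is
  a small synthetic stand-in for licensed terminologies.
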