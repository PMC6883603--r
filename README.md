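# varcurate

Clinical cancer variant knowledgebases live or die by curation
discipline: every claim must be typed, sourced, scored and moderated
before it can inform an interpretation.  `varcurate` implements that
discipline as a validating, scoring and classifying R toolkit for the
people who build and audit such resources — knowledgebase maintainers,
curation leads, and methodologists who want the rules executable rather
than prose.

It provides, as Bioconductor-style S4 classes and functions:

* a **typed knowledge model** — genes, broadly-defined variants,
  evidence items (12 required fields, five types, five levels, 1–5 star
  ratings) and assertions — with pluggable ontology registries (Disease
  Ontology, Sequence Ontology, HPO, NCIt drugs; offline mini-subsets
  bundled);
* a **rule engine** returning violations as ordered data, never
  exceptions;
* **evidence scoring**: an evidence item scores
  `rating × w(level)` with `w(A,B,C,D,E) = 10, 5, 3, 1, 0.5`, and a
  variant's evidence score is the exact sum over its accepted items —
  conflicting directions add, they do not cancel;
* an **ACMG-AMP 2015 criteria combination engine** for germline
  classification (Pathogenic … Benign, conflict ⇒ VUS), with strength
  overrides (`"PS1@moderate"`) and a data-driven combining table;
* **AMP-ASCO-CAP 2017 tier/level assignment** (Tier I–IV, Level A–D)
  for somatic assertions from their accepted supporting evidence;
* **coordinate tools**: reference checking against FASTA and 1-based
  left-shift indel normalization (idempotent, allele-equivalent,
  leftmost);
* an **event-sourced moderation state machine** (submit / accept /
  reject / revise / flag) with editor conflict-of-interest and
  self-acceptance guards and a replayable event log;
* deterministic **JSON/TSV corpus I/O** and a seeded
  **synthetic-corpus generator** with labelled defect injection;
* a **CLI** (`inst/cli/varcurate`) wiring it all:
  `validate | score | classify acmg | classify amp | normalize |
  simulate | export | replay | rules`.

## Worked example

```r
library(varcurate)

corpus <- generateCorpus(generatorConfig(seed = 7, nEids = 40,
                                         violationRate = 0.1))
corpus
#> Corpus:
#>   genes: 6 | variants: 11 | evidence items: 40 | assertions: 8
#>   registries: disease, sequence, phenotype, drug | actors: 7 | events: 106

head(scoreCorpus(corpus), 4)
#>         variant n_items variant_evidence_score
#> 1 ALK::Mutation       6                     27
#> 2   BRAF::M516L       3                     18
#> 3   BRAF::R464A       1                      6
#> 4   EGFR::K551N       3                     70
```

`variant_evidence_score` is a curation-quantity measure: *EGFR* K551N's
70 means its three accepted items (stars × level weight each) sum to
70 points, not that the variant is 70-anything clinically.  The 10%
injected defects are recovered by the rule engine with their exact rule
ids:

```r
head(validateCorpus(corpus)[, c("entity_ref", "rule_id", "severity")], 3)
#>   entity_ref                          rule_id severity
#> 1    EID0021       EID_DRUGS_ON_NONPREDICTIVE    error
#> 2    EID0023 EID_PREDISPOSING_SIGNIFICANCE_NA    error
#> 3    EID0025       EID_DRUGS_ON_NONPREDICTIVE    error

combineAcmg(c("PVS1", "PS1"))
#> AcmgClassification: Pathogenic
#>   fired rules: P1a

assignAmp(corpusAssertions(corpus)[[1]], corpus)
#> AmpAssignment: Tier I, Level B
#>   - clinical evidence: EID0001, EID0037
```

`Pathogenic` here fires rule `P1a` (one very-strong plus one strong
criterion); the assertion lands in Tier I / Level B because its best
accepted Supports-direction evidence is clinical (Level B) without a
regulatory anchor.  See the vignette
(`vignettes/curation-model.Rmd`) for the model, the combining table,
the tier mapping and every documented design decision.

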