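---
title: "The varcurate curation model: scoring, classification and moderation"
author: "varcurate authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The varcurate curation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varcurate)
```

# The knowledge model

`varcurate` implements a four-level knowledge model for clinical cancer
variant curation: **genes** own broadly-defined **variants** (specific
alterations like *BRAF* V600E, or categorical collections like "Exon 20
Insertion"); each variant accumulates **evidence items** — single
literature-derived clinical claims — and collections of evidence items are
synthesised into disease-specific **assertions** that carry a formal
clinical classification.

An evidence item has twelve universally required fields
(`requiredEvidenceFields()`): gene symbol, variant name, source type,
source id, variant origin, disease, evidence statement, evidence type,
evidence level, evidence direction, clinical significance and star
rating.  The enumerable fields draw on controlled vocabularies: five
evidence types (Predictive, Diagnostic, Prognostic, Predisposing,
Functional), five levels (A validated, B clinical, C case study, D
preclinical, E inferential), two directions, and a per-type clinical
significance vocabulary.  Conditional fields exist beyond the twelve:
Predictive items require at least one drug, and more than one drug
requires a drug interaction type (Combination, Sequential or
Substitutes).  Predisposing items carry significance N/A — single-study
germline evidence is not classified directly; classification happens at
the assertion level.

The per-type significance vocabularies are not fully enumerated in
public summaries of the model, so the package adopts a documented set
(Sensitivity/Response, Resistance, Reduced Sensitivity, Adverse
Response, N/A for Predictive; Positive/Negative for Diagnostic;
Better/Poor Outcome, N/A for Prognostic; six functional categories;
N/A for Predisposing) and makes every vocabulary overridable from a YAML
configuration (`loadConfig()`), so a corrected table drops in without a
code change.

Everything is validated by a rule engine, not by constructors: an
incomplete or wrong record is representable, and
`validateEvidenceItem()` / `validateVariant()` / `validateAssertion()` /
`validateCorpus()` return every violated rule as one row of an ordered
violations table.  Two details matter for how violations compose:

* dependent checks are suppressed while their prerequisite is missing
  (no significance-vocabulary check without an evidence type), so
  ablating one required field produces exactly one violation — this
  makes validator recall well defined;
* the Predisposing significance rule *specialises* the generic
  vocabulary rule (you get `EID_PREDISPOSING_SIGNIFICANCE_NA`, never
  both), for the same reason.

Disease terms must resolve in the Disease Ontology registry; the
"could not find disease" escape hatch downgrades the unresolved-disease
error to a free-text warning, mirroring curation practice.  Drug names
are checked against a bundled generic-name table and a trade-name alias
table (trade names are a warning: `"Herceptin"` should be
`"Trastuzumab"`); unknown drugs warn rather than fail because NCIt
linkage is best-effort.

# Evidence scoring

```{r}
evidenceItemScore(1, "A")
evidenceItemScore(5, "E")
```

An evidence item scores `stars x level weight` with weights A=10, B=5,
C=3, D=1, E=0.5.  The **variant evidence score** is the plain sum over
the variant's counted evidence items.  Direction and significance are
deliberately ignored — the quantity measures how much vetted curation a
variant has attracted, not a clinical verdict, so opposing claims add
rather than cancel.

Two design choices:

* **Exactness.** All default weights are multiples of one half, so the
  engine computes in integer half-points and divides by two at the end;
  sums are exact, and scores always serialize with at most one decimal.
  Alternative weight vectors are accepted but must also be half-point
  multiples, cover all five levels and be positive.
* **Which moderation states count.** Public-facing scores should
  reflect vetted content, so only *accepted* items count by default;
  `includedStatuses = c("accepted", "submitted")` is available for
  pre-moderation views.

# Germline classification: combining ACMG codes

Predisposing assertions are classified by combining ACMG evidence codes
(PVS1, PS1–PS4, PM1–PM6, PP1–PP5; BA1, BS1–BS4, BP1–BP7).  Each token
carries a default strength from its prefix; a suffix such as
`"PS1@moderate"` applies a ClinGen-style strength override before
counting.  The combining rules are encoded as a data table
(`acmgCombiningTable()`) of minimum strength counts, evaluated strongest
classification first:

```{r}
classificationValue(combineAcmg(c("PVS1", "PS1")))
classificationValue(combineAcmg(c("PS1", "PM1", "PM2")))
```

**Conflict rule.** The guideline prose leaves "contradictory evidence"
loosely specified.  The package's rule: if one side reaches a
classification while the set also contains codes from the opposite side
(or both sides classify), the result is VUS with `conflict = TRUE` and
the firing rows of both sides retained for audit.  So `{BA1, PVS1}` is a
conflicted VUS even though PVS1 alone fires no pathogenic row, while
`{PM1, BP1}` — where neither side classifies — is a plain VUS.  This
errs on the side of flagging contradiction, which is the conservative
choice for germline reporting.

The test suite checks the combiner against an independent evaluator
that implements each rule literally (including the "1 strong AND 1–2
moderate" ranges), exhaustively over every code set of size ≤ 4.

# Somatic classification: AMP-ASCO-CAP tiers

Predictive, Prognostic and Diagnostic assertions receive an AMP tier
(I–IV) and, for tiers I/II, a level (A–D).  The published guideline
links tiers to regulatory approval and strength of clinical evidence
but leaves the minimal-evidence mapping to supplementary material that
is not publicly reproduced, so the package ships its own documented
mapping, isolated in `ampLevelTable()` for easy replacement:

* **Level A**: a regulatory anchor (FDA approval, companion diagnostic,
  or an NCCN guideline entry) corroborated by an accepted Level A
  evidence item;
* **Level B**: an accepted Level B Supports item — or an accepted
  Level A item *without* a regulatory anchor (validated evidence that
  has not yet reached guidelines is treated as strong clinical
  evidence, not discarded);
* **Level C / D**: best accepted Supports item is a case study (C) or
  preclinical/inferential (D/E);
* **Tier I ⇔ level A/B; Tier II ⇔ level C/D**;
* **Tier III**: evidence exists but no significance consensus — no
  accepted supporting items, all counted items N/A, or accepted items
  contradicting each other (both directions) on the asserted
  significance;
* **Tier IV**: the asserted significance is benign-side.  Somatic
  evidence-item vocabularies contain no benign category, so the
  assertion-level vocabulary adds Benign / Likely Benign to express
  this outcome.

Only Supports-direction items count toward the level;
Does-not-support items on the asserted significance count toward
contradiction detection.  Predisposing assertions are refused with a
pointer to `combineAcmg()`.

# Representative coordinates and left-shift normalization

Coordinates are 1-based and fully closed, on a named build (GRCh37 by
default), with trimmed alleles: an absent allele is `"-"`.  The
convention for insertions — which the trimmed dialect leaves open — is
`start` = base before the insertion point, `stop = start + 1`; this
keeps `start <= stop` and matches common knowledgebase practice.  An
insertion normalized to before the first base is emitted with
`start = 0, stop = 1`, a documented edge.

`checkReference()` verifies the reference allele against a FASTA contig
(insertions instead have their two-base span checked);
`leftShiftNormalize()` then produces the canonical leftmost
representation:

1. trim the shared allele suffix, then the shared prefix (advancing
   `start`) — this phase sets the `trimmed` flag;
2. while one allele is empty, prepend the preceding reference base to
   both alleles, decrement the position, and re-trim — bases the
   shifter itself prepends do not count as trimming;
3. emit the trimmed dialect.

```{r}
leftShiftNormalize(GenomicCoordinates("toy1", 6, 6, "T", "-"),
                   readReferenceFasta(system.file("extdata",
                     "example_ref.fa", package = "varcurate")))
```

The result is idempotent and allele-equivalent to the input (applying
either representation to the contig yields the same alternate
sequence).  A variant whose alleles cancel entirely is a degenerate
error.  Only primary coordinates are normalized; fusion partner
(secondary) coordinates get a reference check only, because shifting
across a breakpoint is undefined.  Right-shift (3'-rule) normalization
and build liftover are out of scope.

# The moderation state machine

Records move `submitted → accepted | rejected` under editor review,
with guards:

* only Editors/Admins holding a conflict-of-interest statement may
  accept; the statement's validity window is 365 days (configurable) —
  the underlying policy requires a statement but no period, and a year
  matches annual re-attestation practice;
* nobody may accept their own submission; submitters may reject their
  own pending records;
* rejections require a rationale comment.  The written rule demands
  comments for *revisions* only; the package extends it to rejections
  because a rejection without rationale is as unauditable as an
  uncommented revision;
* an assertion cannot be accepted until at least one supporting
  evidence item is accepted, and — a situation the written workflow
  does not address — rejecting the *last* accepted supporting item of
  an accepted assertion automatically demotes the assertion to
  `submitted` and flags it, so the gate invariant holds at all times;
* revisions queue against an entity and apply only when an editor (not
  their proposer — treated like accepting one's own submission) accepts
  them; an applied revision can put the record in violation, which the
  next validation reports rather than blocks;
* anyone can flag; editors resolve flags with a comment.

Every operation appends one event to the corpus log; timestamps are
logical sequence numbers and the corpus clock (used for
conflict-of-interest checks) is a fixed date, never wall-clock, so
`replayEvents()` over a corpus's own log reproduces it byte-for-byte.

# The synthetic corpus generator

`generateCorpus()` builds corpora *through the lifecycle operations*,
so generated event logs are real histories.  Its defaults are chosen
once to resemble a curated knowledgebase: evidence levels
A/B/C/D/E = 5/20/30/30/15% (case studies and preclinical work dominate;
validated associations are rare), star ratings 1–5 = 10/20/40/20/10%,
moderation outcomes ≈ 70% accepted / 20% pending / 10% rejected, 80%
Supports direction.  Predictive items draw 1–3 generic drug names;
Predisposing assertions cycle through code sets spanning every ACMG
outcome, somatic assertions span the tiers.  Random contigs with
planted homopolymer and dinucleotide runs, plus indel fixtures placed
inside those runs, feed the normalization oracle.

With `violationRate > 0`, the chosen fraction of evidence items each
receive exactly one labelled defect, drawn from eight single-rule kinds
(missing field, rating out of range, missing interaction type,
non-N/A Predisposing significance, wrong significance vocabulary,
drugs on a non-Predictive item, unresolvable disease, trade-name drug).
Defects are constructed to be non-overlapping, so validator
recall/precision of 1.0/1.0 is meaningful, not lucky.

What the generator does *not* emulate: real literature text (statements
are templated single sentences — length warnings are exercised, meaning
never), real coordinate distributions, inter-curator disagreement, or
ontology churn.  Passing tests on synthetic corpora therefore
demonstrate the engine's rule logic and determinism, not performance on
free-text curation.

# Serialization

The canonical JSON dialect (see `inst/extdata/corpus-schema.json`)
serializes the full corpus — records, moderation threads, actors, event
log — with C-locale-sorted keys, a fixed field order and no nulls
(absent fields are omitted), so a corpus always writes byte-identically
and a write→read→write cycle is a fixpoint.  Unknown record fields are
preserved in an extras map.  The flat TSV dialect is one row per record
with a `record_type` column and comma-joined multi-valued cells
(backslash escaping); it carries the canonical flat fields and is
byte-stable and round-trippable on those, but comment threads,
revisions and the event log are JSON-only.  `writeCorpus(...,
withScores = TRUE)` adds a computed `variant_evidence_score` column.

# Problem sizes and numerical choices

The shipped test-suite exercises: the full evidence-field ablation
(12 single + random multiple ablations); every ordered term pair of the
bundled ontology subtree against a brute-force closure; all ~24,000
ACMG code sets of size ≤ 4 against the literal-rule oracle plus 300
randomised override cases; 10,000 seeded random indels on ≤ 60 bp
contigs for idempotence and allele-equivalence plus exhaustive
leftmost checks on repeat fixtures; 1,000 random moderation action
streams for the self-acceptance and assertion-gate invariants; and a
seed-7, 100-item corpus at 20% injected defects for validator recall.
These sizes were chosen to exhaust the discrete rule spaces (ACMG,
ontology pairs, field ablation) and to give the stochastic properties
enough trials to be convincing while keeping a full run within minutes
on one core.

Known limitations: no HGVS parsing beyond well-formedness, no liftover,
no transcript projection, no automated ACMG code derivation from
population or in-silico data (codes are curator inputs), and the AMP
level mapping is this package's documented substitute for
non-public guideline supplements.
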