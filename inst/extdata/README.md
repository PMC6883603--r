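# Bundled fixtures

Small plain-text term tables and reference sequences so the toolkit never
needs a network connection.

- `so_subset.tsv`, `doid_subset.tsv`, `hpo_subset.tsv`: hand-curated
  mini-subsets of the Sequence Ontology `sequence_variant` subtree, the
  Disease Ontology cancer branch and the HPO phenotypic-abnormality branch.
  Term ids and labels are real; parentage is simplified to the is-a chains
  needed for ancestor queries (intermediate terms may be elided).
- `ncit_drug_terms.tsv`, `ncit_drugs.tsv`: synthetic drug term table.
  Generic drug names are real; the `NCIT:C9xxxxx` identifiers are synthetic
  placeholders, not real NCI Thesaurus codes (the root
  `NCIT:C1909` Pharmacologic Substance is real).
- `drug_aliases.tsv`: trade-name/old-name to generic-name map used by the
  trade-name validation rule.
- `example_ref.fa`: toy reference contigs (with homopolymer and
  dinucleotide-repeat runs) for coordinate checking and left-shift
  normalization examples.
- `corpus-schema.json`: informal schema of the canonical JSON corpus
  dialect.
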