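Package: varcurate
Title: Knowledge Model, Scoring and Classification Engine for Clinical
    Variant Curation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Typed S4 knowledge model for clinical cancer variant curation:
    genes, broadly-defined variants, literature-derived evidence items and
    disease-specific assertions, with controlled vocabularies and pluggable
    ontology registries (Disease Ontology, Sequence Ontology, HPO, NCIt
    drugs). Provides a rule engine that validates records against
    standard-operating-procedure curation rules, evidence scoring (star
    rating times evidence-level weight) aggregated into variant evidence
    scores, an ACMG-AMP 2015 criteria combination engine for germline
    classification, AMP-ASCO-CAP 2017 tier and level assignment for somatic
    assertions, reference-checked left-shift indel normalization, an
    event-sourced curation and moderation state machine, deterministic
    JSON and TSV corpus input/output, a seeded synthetic-corpus generator,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'constructors.R'
    'config.R'
    'ontology.R'
    'validate.R'
    'scoring.R'
    'acmg.R'
    'amp.R'
    'coordinates.R'
    'lifecycle.R'
    'corpus-io.R'
    'generate.R'
    'cli.R'
    'varcurate-package.R'
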