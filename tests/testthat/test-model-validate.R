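test_that("a compliant Predictive item with one drug passes cleanly", {
  expect_identical(nrow(validateEvidenceItem(compliantEid(), REG)), 0L)
})

test_that("two drugs without an interaction type are flagged", {
  item <- compliantEid()
  item@drugs <- c("Gefitinib", "Erlotinib")
  v <- validateEvidenceItem(item, REG)
  expect_identical(v$rule_id, "EID_DRUG_INTERACTION_REQUIRED")
  item@drugInteractionType <- "Substitutes"
  expect_identical(nrow(validateEvidenceItem(item, REG)), 0L)
})

test_that("Predisposing items must keep significance N/A", {
  item <- compliantEid()
  item@evidenceType <- "Predisposing"
  item@drugs <- character()
  item@clinicalSignificance <- "Positive"
  item@evidenceStatement <- "Variant segregates with disease."
  v <- validateEvidenceItem(item, REG)
  expect_identical(v$rule_id, "EID_PREDISPOSING_SIGNIFICANCE_NA")
  item@clinicalSignificance <- "N/A"
  expect_identical(nrow(validateEvidenceItem(item, REG)), 0L)
})

test_that("ablating each required field yields exactly one missing-field violation", {
  fields <- requiredEvidenceFields()
  expect_length(fields, 12L)
  for (f in fields) {
    v <- validateEvidenceItem(ablateField(compliantEid(), f), REG)
    expect_identical(v$rule_id, "EID_REQUIRED_FIELD_MISSING",
                     info = paste("field:", f))
    expect_identical(v$field, f)
  }
  # ablating k fields yields k violations
  set.seed(11)
  for (rep in 1:5) {
    k <- sample(2:12, 1)
    chosen <- sample(fields, k)
    item <- compliantEid()
    for (f in chosen) item <- ablateField(item, f)
    v <- validateEvidenceItem(item, REG)
    expect_identical(sum(v$rule_id == "EID_REQUIRED_FIELD_MISSING"),
                     as.integer(k))
    expect_identical(nrow(v), as.integer(k))
    expect_setequal(v$field, chosen)
  }
})

test_that("vocabulary closure holds over a generated corpus", {
  corpus <- generateCorpus(generatorConfig(seed = 3, nEids = 30))
  cfg <- defaultConfig()
  for (e in corpusEvidence(corpus)) {
    expect_true(e@evidenceType %in% cfg$evidence_types)
    expect_true(e@evidenceLevel %in% cfg$evidence_levels)
    expect_true(e@evidenceDirection %in% cfg$evidence_directions)
    expect_true(e@variantOrigin %in% cfg$variant_origins)
    expect_true(e@clinicalSignificance %in%
                  significanceVocabulary(e@evidenceType))
  }
  expect_identical(nrow(validateCorpus(corpus)), 0L)
})

test_that("free-text diseases downgrade to a warning with the escape hatch", {
  item <- compliantEid()
  item@diseaseDoid <- "angiosarcoma of the scalp"
  v <- validateEvidenceItem(item, REG)
  expect_identical(v$rule_id, "EID_DISEASE_UNRESOLVED")
  expect_identical(v$severity, "error")
  item@couldNotFindDisease <- TRUE
  v2 <- validateEvidenceItem(item, REG)
  expect_identical(v2$rule_id, "EID_DISEASE_FREETEXT")
  expect_identical(v2$severity, "warning")
})

test_that("trade names and unknown ACMG tokens are caught", {
  item <- compliantEid()
  item@drugs <- "Herceptin"
  v <- validateEvidenceItem(item, REG)
  expect_identical(v$rule_id, "EID_DRUG_TRADE_NAME")
  expect_identical(v$severity, "warning")

  pd <- compliantEid()
  pd@evidenceType <- "Predisposing"
  pd@drugs <- character()
  pd@clinicalSignificance <- "N/A"
  pd@evidenceStatement <- "Supported by PM2 and PP9 in this family."
  v2 <- validateEvidenceItem(pd, REG)
  expect_identical(v2$rule_id, "EID_ACMG_CODE_UNKNOWN")
  expect_match(v2$message, "PP9")
})

test_that("variant type rules mirror the ontology structure", {
  v <- VariantRecord("BRAF", "V600E", variantTypes = "SO:0001583")
  expect_identical(nrow(validateVariant(v, REG)), 0L)

  nested <- VariantRecord("BRAF", "V600E",
                          variantTypes = c("SO:0001583", "SO:0001060"))
  out <- validateVariant(nested, REG)
  expect_identical(out$rule_id, "VAR_SO_ANCESTRY")

  unk <- VariantRecord("BRAF", "V600E", variantTypes = "SO:9999999")
  expect_identical(validateVariant(unk, REG)$rule_id, "VAR_SO_UNKNOWN")
})

test_that("unversioned transcripts and stray secondary coordinates are flagged", {
  co <- GenomicCoordinates("7", 140453136, 140453136, "A", "T",
                           representativeTranscript = "ENST00000078429")
  v <- VariantRecord("BRAF", "V600E", variantTypes = "SO:0001583",
                     primaryCoordinates = co)
  expect_identical(validateVariant(v, REG)$rule_id, "VAR_TX_UNVERSIONED")
  co@representativeTranscript <- "ENST00000078429.1"
  v@primaryCoordinates <- co
  expect_identical(nrow(validateVariant(v, REG)), 0L)

  sv <- VariantRecord("EML4", "EML4-ALK", variantTypes = "SO:0001583",
                      secondaryCoordinates =
                        GenomicCoordinates("2", 100, 100, "A", "G"))
  expect_identical(validateVariant(sv, REG)$rule_id,
                   "VAR_SECONDARY_COORDS_UNEXPECTED")
  fusion <- VariantRecord("EML4", "EML4-ALK", variantTypes = "SO:0001565",
                          secondaryCoordinates =
                            GenomicCoordinates("2", 100, 100, "A", "G"))
  expect_identical(nrow(validateVariant(fusion, REG)), 0L)
})

test_that("assertion rules cover the guideline-field separation and gate", {
  corpus <- miniCorpus()
  ok <- Assertion("AID1", "EGFR", "L858R", "Somatic", "DOID:3910",
                  "Predictive", "Supports", "Sensitivity/Response",
                  drugs = "Gefitinib", ampTier = "I", ampLevel = "A",
                  supportingEids = c("EID1", "EID2"))
  expect_identical(nrow(validateAssertion(ok, corpus)), 0L)

  pd <- Assertion("AID2", "EGFR", "L858R", "Rare Germline", "DOID:3910",
                  "Predisposing", "Supports", "N/A", ampTier = "I",
                  ampLevel = "A", supportingEids = "EID1")
  expect_identical(validateAssertion(pd, corpus)$rule_id,
                   "ASRT_AMP_ON_PREDISPOSING")

  dangling <- Assertion("AID3", "EGFR", "L858R", "Somatic", "DOID:3910",
                        "Prognostic", "Supports", "Better Outcome",
                        supportingEids = "EID99")
  expect_identical(validateAssertion(dangling, corpus)$rule_id,
                   "ASRT_EID_DANGLING")

  # assertion on a variant with no evidence items at all
  c2 <- emptyCorpus()
  c2 <- registerActor(c2, "cur1", "Curator")
  c2 <- submitEntity(c2, VariantRecord("KRAS", "G12D",
                                       variantTypes = "SO:0001583"),
                     "cur1")
  noEv <- Assertion("AID4", "KRAS", "G12D", "Somatic", "DOID:9256",
                    "Prognostic", "Supports", "Poor Outcome")
  expect_identical(validateAssertion(noEv, c2)$rule_id,
                   "ASRT_NO_EVIDENCE")
})

test_that("violation reports are deterministic for identical corpora", {
  c1 <- generateCorpus(generatorConfig(seed = 9, nEids = 25,
                                       violationRate = 0.3))
  c2 <- generateCorpus(generatorConfig(seed = 9, nEids = 25,
                                       violationRate = 0.3))
  expect_identical(validateCorpus(c1), validateCorpus(c2))
})

test_that("the rule catalogue is complete for emitted rule ids", {
  cat <- ruleCatalogue()
  expect_true(all(c("EID_REQUIRED_FIELD_MISSING", "VAR_SO_ANCESTRY",
                    "ASRT_NO_EVIDENCE", "COORD_REF_MISMATCH") %in%
                    cat$rule_id))
  expect_true(all(cat$severity %in% c("error", "warning")))
  corpus <- generateCorpus(generatorConfig(seed = 5, nEids = 40,
                                           violationRate = 0.5))
  v <- validateCorpus(corpus)
  expect_true(all(v$rule_id %in% cat$rule_id))
})
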