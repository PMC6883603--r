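## SOP rule engine.  Validators never throw for content problems: every
## violated rule comes back as one row of a violations data.frame, ordered
## deterministically (entity_ref, then rule_id, then field) so reports are
## byte-stable.

.violationRow <- function(rule_id, severity, entity_ref, field = NA,
                          message = "") {
  data.frame(rule_id = rule_id, severity = severity,
             entity_ref = as.character(entity_ref),
             field = as.character(field), message = message,
             stringsAsFactors = FALSE)
}

#' An empty violations table
#'
#' @return Zero-row data.frame with columns \code{rule_id},
#'   \code{severity}, \code{entity_ref}, \code{field}, \code{message}.
#' @export
emptyViolations <- function() {
  data.frame(rule_id = character(), severity = character(),
             entity_ref = character(), field = character(),
             message = character(), stringsAsFactors = FALSE)
}

.bindViolations <- function(rows) {
  if (!length(rows)) return(emptyViolations())
  out <- do.call(rbind, rows)
  out[order(out$entity_ref, out$rule_id, out$field,
            method = "radix"), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' The documented rule catalogue
#'
#' Machine-readable table of every rule the engine can report, with its
#' severity and a one-line description.  Rule ids are stable identifiers;
#' the \code{rules} CLI subcommand dumps this table.
#'
#' @return data.frame with columns \code{rule_id}, \code{severity},
#'   \code{description}.
#' @export
ruleCatalogue <- function() {
  rows <- list(
    c("EID_REQUIRED_FIELD_MISSING", "error",
      "One of the 12 universally required evidence-item fields is empty"),
    c("EID_MULTI_DISEASE", "error",
      "More than one disease attached to an evidence item"),
    c("EID_RATING_RANGE", "error", "Evidence rating outside 1-5 stars"),
    c("EID_TYPE_VOCAB", "error", "Evidence type not in vocabulary"),
    c("EID_LEVEL_VOCAB", "error", "Evidence level not one of A-E"),
    c("EID_DIRECTION_VOCAB", "error",
      "Evidence direction not Supports/Does not support"),
    c("EID_ORIGIN_VOCAB", "error", "Variant origin not in vocabulary"),
    c("EID_SOURCE_TYPE_VOCAB", "error",
      "Source type not PubMed or ASCO"),
    c("EID_SIGNIFICANCE_VOCAB", "error",
      "Clinical significance not in the vocabulary for the evidence type"),
    c("EID_PREDISPOSING_SIGNIFICANCE_NA", "error",
      "Predisposing evidence items must carry clinical significance N/A"),
    c("EID_DRUGS_REQUIRED", "error",
      "Predictive evidence items require at least one drug"),
    c("EID_DRUGS_ON_NONPREDICTIVE", "error",
      "Drugs attached to a non-Predictive evidence item"),
    c("EID_DRUG_INTERACTION_REQUIRED", "error",
      "More than one drug without a drug interaction type"),
    c("EID_DRUG_INTERACTION_UNEXPECTED", "error",
      "Drug interaction type set with fewer than two drugs"),
    c("EID_DISEASE_UNRESOLVED", "error",
      "Disease does not resolve in the disease ontology registry"),
    c("EID_DISEASE_FREETEXT", "warning",
      "Free-text disease used via the could-not-find-disease escape hatch"),
    c("EID_DRUG_TRADE_NAME", "warning",
      "Trade name used for a drug; use the generic name"),
    c("EID_DRUG_UNKNOWN", "warning",
      "Drug name not found in the bundled drug table"),
    c("EID_PHENOTYPE_UNRESOLVED", "error",
      "Phenotype does not resolve in the HPO registry"),
    c("EID_ACMG_CODE_UNKNOWN", "error",
      "Predisposing statement cites an unrecognized ACMG code token"),
    c("EID_STATEMENT_LENGTH", "warning",
      "Evidence statement longer than the recommended 1-3 sentences"),
    c("EID_DUPLICATE", "warning",
      "Resubmission of an identical pending evidence item"),
    c("VAR_NAME_MISSING", "error", "Variant name empty"),
    c("VAR_SO_UNKNOWN", "error",
      "Variant type not in the sequence ontology registry"),
    c("VAR_SO_ANCESTRY", "error",
      "Two variant types are ancestor/descendant of one another"),
    c("VAR_SO_NOT_SEQUENCE_VARIANT", "warning",
      "Variant type does not descend from sequence_variant"),
    c("VAR_TX_UNVERSIONED", "error",
      "Representative transcript lacks a version suffix"),
    c("VAR_SECONDARY_COORDS_UNEXPECTED", "error",
      "Secondary coordinates on a variant without a two-locus type"),
    c("VAR_HGVS_MALFORMED", "warning",
      "HGVS expression fails the well-formedness check"),
    c("VAR_CLINVAR_MALFORMED", "warning",
      "ClinVar id neither numeric nor the NONE_FOUND sentinel"),
    c("ASRT_TYPE_VOCAB", "error", "Assertion type not in vocabulary"),
    c("ASRT_GENE_UNKNOWN", "error", "Assertion gene not in corpus"),
    c("ASRT_VARIANT_UNKNOWN", "error", "Assertion variant not in corpus"),
    c("ASRT_NO_EVIDENCE", "error",
      "Assertion on a variant with no evidence items"),
    c("ASRT_EID_DANGLING", "error",
      "Supporting evidence id does not resolve"),
    c("ASRT_MULTI_DISEASE", "error",
      "More than one disease attached to an assertion"),
    c("ASRT_DISEASE_UNRESOLVED", "error",
      "Assertion disease does not resolve in the registry"),
    c("ASRT_SIGNIFICANCE_VOCAB", "error",
      "Clinical significance not in the vocabulary for the assertion type"),
    c("ASRT_AMP_ON_PREDISPOSING", "error",
      "AMP tier/level on a Predisposing assertion"),
    c("ASRT_ACMG_ON_SOMATIC", "error",
      "ACMG classification on a non-Predisposing assertion"),
    c("ASRT_ACMG_CODE_UNKNOWN", "error",
      "Unrecognized ACMG code token on an assertion"),
    c("ASRT_AMP_PAIRING", "error",
      "AMP tier/level pairing invalid (I:A/B, II:C/D, III/IV: none)"),
    c("ASRT_DRUG_INTERACTION_REQUIRED", "error",
      "Predictive assertion with several drugs lacks an interaction type"),
    c("ASRT_DRUGS_ON_NONPREDICTIVE", "error",
      "Drugs attached to a non-Predictive assertion"),
    c("ASRT_ACCEPTED_WITHOUT_ACCEPTED_EID", "error",
      "Accepted assertion without an accepted supporting evidence item"),
    c("GENE_NO_VARIANTS", "error",
      "Gene record persisted without any variant referencing it"),
    c("CORPUS_DANGLING_REF", "error",
      "Record references a gene/variant absent from the corpus"),
    c("COORD_REF_MISMATCH", "error",
      "Reference allele does not match the reference sequence"),
    c("COORD_INSERTION_SPAN", "error",
      "Insertion coordinates must satisfy stop == start + 1"),
    c("COORD_START_GT_STOP", "error", "start greater than stop"),
    c("COORD_ALLELES_BLANK", "error",
      "Reference and variant alleles are both blank")
  )
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(rule_id = r[1], severity = r[2], description = r[3],
               stringsAsFactors = FALSE)))
  out[order(out$rule_id), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

.isBlank <- function(x) {
  length(x) == 0L || all(is.na(x)) || all(trimws(as.character(x)) == "")
}

.countSentences <- function(text) {
  if (is.na(text)) return(0L)
  pieces <- strsplit(text, "[.!?]+(\\s|$)")[[1]]
  sum(nzchar(trimws(pieces)))
}

.acmgTokenPattern <- "(PVS|PS|PM|PP|BA|BS|BP)[0-9]+"

#' Validate an evidence item against the SOP rules
#'
#' Checks the twelve universally required fields, vocabulary membership of
#' every enumerated field, the 1-5 star rating bound, the single-disease
#' rule and its free-text escape hatch, the Predictive drug rules
#' (drugs required, interaction type with more than one drug, no trade
#' names), the Predisposing significance-N/A rule, phenotype resolution
#' and ACMG code tokens cited in Predisposing statements.  Dependent checks
#' are suppressed while their prerequisite field is missing, so ablating
#' one required field yields exactly one violation.
#'
#' @param item An \linkS4class{EvidenceItem}.
#' @param registries Named list of \linkS4class{OntologyRegistry} objects
#'   (keys \code{disease}, \code{phenotype} used here).
#' @param config Configuration list (see \code{\link{loadConfig}}).
#' @return Violations data.frame (zero rows when compliant); problems are
#'   returned, never raised.
#' @examples
#' reg <- bundledRegistries()
#' item <- EvidenceItem("EID1", "EGFR", "L858R",
#'   source = SourceRef("PubMed", "15118073"),
#'   variantOrigin = "Somatic", diseaseDoid = "DOID:3908",
#'   evidenceStatement = "Responds to gefitinib.",
#'   evidenceType = "Predictive", evidenceLevel = "B",
#'   evidenceDirection = "Supports",
#'   clinicalSignificance = "Sensitivity/Response",
#'   evidenceRating = 4L, drugs = "Gefitinib")
#' validateEvidenceItem(item, reg)
#' @export
validateEvidenceItem <- function(item, registries = bundledRegistries(),
                                 config = defaultConfig()) {
  v <- list()
  ref <- if (is.na(item@eid)) "<unsaved>" else item@eid
  add <- function(rule, sev, field = NA, msg = "")
    v[[length(v) + 1L]] <<- .violationRow(rule, sev, ref, field, msg)
  miss <- function(field, msg = paste0("required field '", field,
                                       "' is missing"))
    add("EID_REQUIRED_FIELD_MISSING", "error", field, msg)

  ## required fields --------------------------------------------------------
  if (.isBlank(item@geneSymbol)) miss("gene_symbol")
  if (.isBlank(item@variantName)) miss("variant_name")
  if (.isBlank(item@source@sourceType)) miss("source_type")
  if (.isBlank(item@source@sourceId)) miss("source_id")
  if (.isBlank(item@variantOrigin)) miss("variant_origin")
  diseaseMissing <- .isBlank(item@diseaseDoid)
  if (diseaseMissing) miss("disease")
  if (.isBlank(item@evidenceStatement)) miss("evidence_statement")
  typeMissing <- .isBlank(item@evidenceType)
  if (typeMissing) miss("evidence_type")
  if (.isBlank(item@evidenceLevel)) miss("evidence_level")
  if (.isBlank(item@evidenceDirection)) miss("evidence_direction")
  sigMissing <- .isBlank(item@clinicalSignificance)
  if (sigMissing) miss("clinical_significance")
  if (.isBlank(item@evidenceRating)) miss("evidence_rating")

  ## vocabulary membership (skipped while the field is missing) -------------
  if (!.isBlank(item@source@sourceType) &&
      !item@source@sourceType %in% config$source_types)
    add("EID_SOURCE_TYPE_VOCAB", "error", "source_type",
        paste0("'", item@source@sourceType, "' is not an accepted source type"))
  if (!.isBlank(item@variantOrigin) &&
      !item@variantOrigin %in% config$variant_origins)
    add("EID_ORIGIN_VOCAB", "error", "variant_origin", item@variantOrigin)
  if (!typeMissing && !item@evidenceType %in% config$evidence_types)
    add("EID_TYPE_VOCAB", "error", "evidence_type", item@evidenceType)
  if (!.isBlank(item@evidenceLevel) &&
      !item@evidenceLevel %in% config$evidence_levels)
    add("EID_LEVEL_VOCAB", "error", "evidence_level", item@evidenceLevel)
  if (!.isBlank(item@evidenceDirection) &&
      !item@evidenceDirection %in% config$evidence_directions)
    add("EID_DIRECTION_VOCAB", "error", "evidence_direction",
        item@evidenceDirection)
  if (!.isBlank(item@evidenceRating) &&
      (item@evidenceRating < config$rating_range[1] ||
       item@evidenceRating > config$rating_range[2]))
    add("EID_RATING_RANGE", "error", "evidence_rating",
        paste0("rating ", item@evidenceRating, " outside 1-5"))

  ## significance: per-type vocabulary; Predisposing has its own rule -------
  if (!typeMissing && !sigMissing &&
      item@evidenceType %in% config$evidence_types) {
    if (item@evidenceType == "Predisposing") {
      if (item@clinicalSignificance != "N/A")
        add("EID_PREDISPOSING_SIGNIFICANCE_NA", "error",
            "clinical_significance",
            "Predisposing clinical significance defaults to N/A")
    } else if (!item@clinicalSignificance %in%
               significanceVocabulary(item@evidenceType, config = config)) {
      add("EID_SIGNIFICANCE_VOCAB", "error", "clinical_significance",
          paste0("'", item@clinicalSignificance, "' not allowed for ",
                 item@evidenceType))
    }
  }

  ## single disease + resolution --------------------------------------------
  if (!diseaseMissing) {
    dd <- item@diseaseDoid[!is.na(item@diseaseDoid) &
                           nzchar(item@diseaseDoid)]
    if (length(dd) > 1L) {
      add("EID_MULTI_DISEASE", "error", "disease",
          "only a single disease term per evidence item")
    } else {
      reg <- registries$disease
      resolved <- grepl("^DOID:", dd) && !is.null(reg) && termExists(reg, dd)
      if (!resolved) {
        if (isTRUE(item@couldNotFindDisease))
          add("EID_DISEASE_FREETEXT", "warning", "disease",
              paste0("free-text disease '", dd, "'"))
        else
          add("EID_DISEASE_UNRESOLVED", "error", "disease",
              paste0("'", dd, "' not found in the disease registry"))
      }
    }
  }

  ## drug rules --------------------------------------------------------------
  if (!typeMissing) {
    nd <- length(item@drugs)
    if (item@evidenceType == "Predictive") {
      if (nd == 0L)
        add("EID_DRUGS_REQUIRED", "error", "drugs",
            "Predictive evidence items require a drug")
      if (nd > 1L && .isBlank(item@drugInteractionType))
        add("EID_DRUG_INTERACTION_REQUIRED", "error",
            "drug_interaction_type",
            "a drug interaction type is required with more than one drug")
      if (nd <= 1L && !.isBlank(item@drugInteractionType))
        add("EID_DRUG_INTERACTION_UNEXPECTED", "error",
            "drug_interaction_type",
            "interaction type only applies with several drugs")
      if (!.isBlank(item@drugInteractionType) &&
          !is.na(item@drugInteractionType) &&
          !item@drugInteractionType %in% config$drug_interaction_types &&
          nd > 1L)
        add("EID_DRUG_INTERACTION_REQUIRED", "error",
            "drug_interaction_type",
            paste0("'", item@drugInteractionType,
                   "' is not a drug interaction type"))
      if (nd > 0L) {
        aliases <- drugAliases()
        known <- knownDrugs()$drug_name
        for (d in item@drugs) {
          hit <- match(tolower(d), tolower(aliases$alias))
          if (!is.na(hit))
            add("EID_DRUG_TRADE_NAME", "warning", "drugs",
                paste0("'", d, "' is a trade name for ",
                       aliases$generic[hit]))
          else if (!tolower(d) %in% tolower(known))
            add("EID_DRUG_UNKNOWN", "warning", "drugs",
                paste0("'", d, "' not in the bundled drug table"))
        }
      }
    } else if (nd > 0L) {
      add("EID_DRUGS_ON_NONPREDICTIVE", "error", "drugs",
          paste0("drugs are not applicable to ", item@evidenceType,
                 " evidence"))
    }
  }

  ## phenotypes ---------------------------------------------------------------
  reg <- registries$phenotype
  if (!is.null(reg)) for (p in item@phenotypes)
    if (!termExists(reg, p))
      add("EID_PHENOTYPE_UNRESOLVED", "error", "phenotypes", p)

  ## ACMG tokens in Predisposing statements ----------------------------------
  if (!typeMissing && item@evidenceType == "Predisposing" &&
      !.isBlank(item@evidenceStatement)) {
    toks <- regmatches(item@evidenceStatement,
                       gregexpr(.acmgTokenPattern, item@evidenceStatement))[[1]]
    bad <- setdiff(unique(toks), acmgCodeTokens())
    for (b in bad)
      add("EID_ACMG_CODE_UNKNOWN", "error", "evidence_statement",
          paste0("'", b, "' is not an ACMG code"))
  }

  ## statement length guidance ------------------------------------------------
  if (!.isBlank(item@evidenceStatement) &&
      .countSentences(item@evidenceStatement) >
        config$statement_sentence_warning)
    add("EID_STATEMENT_LENGTH", "warning", "evidence_statement",
        "statements should typically be 1 to 3 sentences")

  .bindViolations(v)
}

.twoLocusTypes <- function(registry) {
  base <- c("SO:0001565", "SO:0001886")   # gene_fusion, transcript_fusion
  if (is.null(registry)) return(base)
  present <- base[vapply(base, termExists, logical(1), registry = registry)]
  desc <- registry@terms$term_id[vapply(registry@terms$term_id, function(t)
    any(vapply(present, function(b) isDescendant(t, b, registry),
               logical(1))), logical(1))]
  unique(c(base, desc))
}

.hgvsPattern <- "^[A-Za-z0-9_.()-]+:[cgnmpr]\\.[^[:space:]]+$"

#' Validate a variant record against the SOP rules
#'
#' Flags missing names, variant types absent from the sequence ontology,
#' ancestor/descendant pairs among the chosen types, types outside the
#' sequence_variant subtree (warning), unversioned representative
#' transcripts, secondary coordinates on variants without a two-locus
#' (fusion) type, malformed HGVS expressions and malformed ClinVar ids.
#' Reference-base agreement is the coordinates module's job
#' (\code{\link{checkReference}}).
#'
#' @param variant A \linkS4class{VariantRecord}.
#' @param registries Named list of registries (key \code{sequence} used).
#' @param config Configuration list.
#' @return Violations data.frame.
#' @export
validateVariant <- function(variant, registries = bundledRegistries(),
                            config = defaultConfig()) {
  v <- list()
  ref <- variantKey(variant@geneSymbol, variant@variantName)
  add <- function(rule, sev, field = NA, msg = "")
    v[[length(v) + 1L]] <<- .violationRow(rule, sev, ref, field, msg)

  if (.isBlank(variant@variantName))
    add("VAR_NAME_MISSING", "error", "variant_name")

  reg <- registries$sequence
  types <- unique(variant@variantTypes)
  resolved <- character()
  for (t in types) {
    if (!is.null(reg) && termExists(reg, t)) resolved <- c(resolved, t)
    else add("VAR_SO_UNKNOWN", "error", "variant_types", t)
  }
  if (length(resolved) >= 2L) {
    for (i in seq_len(length(resolved) - 1L))
      for (j in seq(i + 1L, length(resolved))) {
        a <- resolved[i]; b <- resolved[j]
        if (isDescendant(a, b, reg) || isDescendant(b, a, reg))
          add("VAR_SO_ANCESTRY", "error", "variant_types",
              paste0(a, " and ", b,
                     " are ancestor/descendant of one another"))
      }
  }
  root <- "SO:0001060"
  if (!is.null(reg) && termExists(reg, root)) for (t in resolved)
    if (t != root && !isDescendant(t, root, reg))
      add("VAR_SO_NOT_SEQUENCE_VARIANT", "warning", "variant_types", t)

  for (co in list(variant@primaryCoordinates,
                  variant@secondaryCoordinates)) {
    tx <- co@representativeTranscript
    if (!is.na(tx) && !grepl("^[^[:space:]]+\\.[0-9]+$", tx))
      add("VAR_TX_UNVERSIONED", "error", "representative_transcript",
          paste0("'", tx, "' lacks a version suffix"))
  }

  if (!is.na(variant@secondaryCoordinates@chromosome) &&
      !any(resolved %in% .twoLocusTypes(reg)))
    add("VAR_SECONDARY_COORDS_UNEXPECTED", "error",
        "secondary_coordinates",
        "secondary coordinates are reserved for two-locus variants")

  for (h in variant@hgvsExpressions)
    if (!grepl(.hgvsPattern, h))
      add("VAR_HGVS_MALFORMED", "warning", "hgvs_expressions", h)

  for (cid in variant@clinvarIds)
    if (!grepl("^[0-9]+$", cid) && !cid %in% c("NONE_FOUND", "N/A"))
      add("VAR_CLINVAR_MALFORMED", "warning", "clinvar_ids", cid)

  .bindViolations(v)
}

#' Validate an assertion against the SOP rules
#'
#' Checks the per-type significance vocabulary, the single-disease rule,
#' the guideline-field separation (AMP tier/level only on Predictive,
#' Prognostic, Diagnostic assertions; ACMG classification only on
#' Predisposing ones), tier/level pairing, drug rules, reference integrity
#' (gene, variant, supporting evidence ids) and the acceptance gate (an
#' accepted assertion needs an accepted supporting evidence item).
#'
#' @param assertion An \linkS4class{Assertion}.
#' @param corpus A \linkS4class{Corpus} used to resolve references.
#' @param config Configuration list.
#' @return Violations data.frame; dangling references are reported, never
#'   raised.
#' @export
validateAssertion <- function(assertion, corpus, config = defaultConfig()) {
  v <- list()
  ref <- if (is.na(assertion@aid)) "<unsaved>" else assertion@aid
  add <- function(rule, sev, field = NA, msg = "")
    v[[length(v) + 1L]] <<- .violationRow(rule, sev, ref, field, msg)

  typeKnown <- !.isBlank(assertion@assertionType) &&
    assertion@assertionType %in% config$assertion_types
  if (!.isBlank(assertion@assertionType) && !typeKnown)
    add("ASRT_TYPE_VOCAB", "error", "assertion_type",
        assertion@assertionType)

  ## reference integrity
  if (!.isBlank(assertion@geneSymbol) &&
      !assertion@geneSymbol %in% names(corpus@genes))
    add("ASRT_GENE_UNKNOWN", "error", "gene_symbol", assertion@geneSymbol)
  vkey <- variantKey(assertion@geneSymbol, assertion@variantName)
  variantKnown <- vkey %in% names(corpus@variants)
  if (!.isBlank(assertion@variantName) && !variantKnown)
    add("ASRT_VARIANT_UNKNOWN", "error", "variant_name",
        assertion@variantName)
  if (variantKnown) {
    eidsOfVariant <- Filter(function(e)
      identical(variantKey(e@geneSymbol, e@variantName), vkey),
      corpus@evidenceItems)
    if (!length(eidsOfVariant))
      add("ASRT_NO_EVIDENCE", "error", NA,
          "assertions require a variant with at least one evidence item")
  }
  for (e in assertion@supportingEids)
    if (!e %in% names(corpus@evidenceItems))
      add("ASRT_EID_DANGLING", "error", "supporting_eids", e)

  ## disease
  dd <- assertion@diseaseDoid[!is.na(assertion@diseaseDoid) &
                              nzchar(assertion@diseaseDoid)]
  if (length(dd) > 1L) {
    add("ASRT_MULTI_DISEASE", "error", "disease",
        "only one disease is permitted per assertion")
  } else if (length(dd) == 1L) {
    reg <- corpus@registries$disease
    if (!(grepl("^DOID:", dd) && !is.null(reg) && termExists(reg, dd)))
      add("ASRT_DISEASE_UNRESOLVED", "error", "disease", dd)
  }

  ## significance
  if (typeKnown && !.isBlank(assertion@clinicalSignificance)) {
    if (assertion@assertionType == "Predisposing") {
      if (assertion@clinicalSignificance != "N/A")
        add("ASRT_SIGNIFICANCE_VOCAB", "error", "clinical_significance",
            assertion@clinicalSignificance)
    } else if (!assertion@clinicalSignificance %in%
               significanceVocabulary(assertion@assertionType,
                                      assertion = TRUE, config = config)) {
      add("ASRT_SIGNIFICANCE_VOCAB", "error", "clinical_significance",
          assertion@clinicalSignificance)
    }
  }

  ## guideline-field separation and pairing
  isPredisposing <- identical(assertion@assertionType, "Predisposing")
  if (isPredisposing &&
      (!is.na(assertion@ampTier) || !is.na(assertion@ampLevel)))
    add("ASRT_AMP_ON_PREDISPOSING", "error", "amp_tier",
        "somatic tier/level fields do not apply to Predisposing assertions")
  if (typeKnown && !isPredisposing && !is.na(assertion@acmgClassification))
    add("ASRT_ACMG_ON_SOMATIC", "error", "acmg_classification",
        "ACMG classification applies only to Predisposing assertions")
  if (!isPredisposing && !is.na(assertion@ampTier)) {
    t <- assertion@ampTier; l <- assertion@ampLevel
    ok <- (t == "I" && !is.na(l) && l %in% c("A", "B")) ||
          (t == "II" && !is.na(l) && l %in% c("C", "D")) ||
          (t %in% c("III", "IV") && is.na(l))
    if (!ok)
      add("ASRT_AMP_PAIRING", "error", "amp_level",
          paste0("tier ", t, " with level ", ifelse(is.na(l), "none", l)))
  }
  for (code in assertion@acmgCodes)
    if (!.acmgTokenValid(code))
      add("ASRT_ACMG_CODE_UNKNOWN", "error", "acmg_codes", code)

  ## drugs
  if (typeKnown) {
    nd <- length(assertion@drugs)
    if (assertion@assertionType == "Predictive") {
      if (nd > 1L && .isBlank(assertion@drugInteractionType))
        add("ASRT_DRUG_INTERACTION_REQUIRED", "error",
            "drug_interaction_type", "")
    } else if (nd > 0L) {
      add("ASRT_DRUGS_ON_NONPREDICTIVE", "error", "drugs", "")
    }
  }

  ## acceptance gate
  if (assertion@moderation@state == "accepted") {
    acc <- vapply(assertion@supportingEids, function(e) {
      it <- corpus@evidenceItems[[e]]
      !is.null(it) && it@moderation@state == "accepted"
    }, logical(1))
    if (!any(acc))
      add("ASRT_ACCEPTED_WITHOUT_ACCEPTED_EID", "error", NA,
          "an assertion cannot be accepted without an accepted evidence item")
  }

  .bindViolations(v)
}

#' Validate every record in a corpus
#'
#' Runs the evidence-item, variant and assertion validators over all
#' records, adds corpus-level referential checks (evidence items pointing
#' at absent genes/variants, gene records no variant references), and
#' returns one deterministic violations table.
#'
#' @param corpus A \linkS4class{Corpus}.
#' @param config Configuration list.
#' @return Violations data.frame ordered by entity then rule.
#' @export
validateCorpus <- function(corpus, config = defaultConfig()) {
  parts <- list()
  for (it in corpus@evidenceItems)
    parts[[length(parts) + 1L]] <-
      validateEvidenceItem(it, corpus@registries, config)
  for (va in corpus@variants)
    parts[[length(parts) + 1L]] <-
      validateVariant(va, corpus@registries, config)
  for (a in corpus@assertions)
    parts[[length(parts) + 1L]] <- validateAssertion(a, corpus, config)

  extra <- list()
  referenced <- unique(vapply(corpus@variants, function(v) v@geneSymbol,
                              character(1)))
  for (g in names(corpus@genes))
    if (!g %in% referenced)
      extra[[length(extra) + 1L]] <-
        .violationRow("GENE_NO_VARIANTS", "error", g, "gene_symbol",
                      "gene records require at least one variant")
  for (it in corpus@evidenceItems) {
    if (!is.na(it@geneSymbol) && !it@geneSymbol %in% names(corpus@genes))
      extra[[length(extra) + 1L]] <-
        .violationRow("CORPUS_DANGLING_REF", "error", it@eid, "gene_symbol",
                      paste0("gene ", it@geneSymbol, " not in corpus"))
    vk <- variantKey(it@geneSymbol, it@variantName)
    if (!is.na(it@variantName) && !vk %in% names(corpus@variants))
      extra[[length(extra) + 1L]] <-
        .violationRow("CORPUS_DANGLING_REF", "error", it@eid,
                      "variant_name",
                      paste0("variant ", vk, " not in corpus"))
  }
  .bindViolations(c(parts, extra))
}
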