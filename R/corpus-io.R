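## Canonical JSON and flat TSV corpus dialects.  Writers are deterministic
## (C-locale sorted keys, fixed column order, fixed field order), so the
## same corpus always produces byte-identical files.  Readers preserve
## unknown record fields in an extras map for forward compatibility.

.sortKeys <- function(x) {
  if (!length(x) || is.null(names(x))) return(x)
  x[order(names(x), method = "radix")]
}

## canonical JSON form: no nulls — absent fields are omitted, so a
## write -> read -> write cycle reaches a fixpoint after one read
.dropNA <- function(lst) {
  keep <- vapply(lst, function(x)
    !(is.null(x) || (is.atomic(x) && length(x) == 1L && is.na(x))),
    logical(1))
  lst[keep]
}
.jsonSanitize <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, .jsonSanitize)
    if (!is.null(names(x))) x <- .dropNA(x) else
      x <- x[!vapply(x, is.null, logical(1))]
  }
  x
}

.asChrVec <- function(x) {
  if (is.null(x) || !length(x)) character() else as.character(unlist(x))
}
.asChrOne <- function(x) {
  if (is.null(x) || !length(x) || (length(x) == 1L && is.na(x)))
    NA_character_
  else as.character(x)[1L]
}
.asNumOne <- function(x) {
  if (is.null(x) || !length(x) || (length(x) == 1L && is.na(x))) NA_real_
  else as.numeric(x)[1L]
}

## ---- entity <-> list codecs ---------------------------------------------

.srcToList <- function(s) {
  .dropNA(list(source_type = s@sourceType, source_id = s@sourceId,
       citation = s@citation,
       clinical_trial_ids = as.list(s@clinicalTrialIds)))
}
.srcFromList <- function(l) {
  if (is.null(l)) return(SourceRef())
  SourceRef(.asChrOne(l$source_type), .asChrOne(l$source_id),
            .asChrOne(l$citation), .asChrVec(l$clinical_trial_ids))
}

.coordsToList <- function(co) {
  .dropNA(list(chromosome = co@chromosome, start = co@start,
       stop = co@stop,
       reference_base = co@referenceBase, variant_base = co@variantBase,
       reference_build = co@referenceBuild,
       representative_transcript = co@representativeTranscript))
}
.coordsFromList <- function(l) {
  if (is.null(l)) return(GenomicCoordinates())
  GenomicCoordinates(.asChrOne(l$chromosome), .asNumOne(l$start),
                     .asNumOne(l$stop), .asChrOne(l$reference_base),
                     .asChrOne(l$variant_base),
                     .asChrOne(l$reference_build),
                     .asChrOne(l$representative_transcript))
}

.modToList <- function(m) {
  .dropNA(list(state = m@state, flagged = m@flagged,
       submitter_id = m@submitterId, decided_by = m@decidedBy,
       comments = lapply(seq_len(nrow(m@comments)), function(i)
         list(actor_id = m@comments$actor_id[i],
              text = m@comments$text[i],
              timestamp = m@comments$timestamp[i])),
       revisions = .jsonSanitize(m@revisions)))
}
.modFromList <- function(l) {
  if (is.null(l)) return(ModerationRecord())
  comments <- if (length(l$comments))
    do.call(rbind, lapply(l$comments, function(c)
      data.frame(actor_id = .asChrOne(c$actor_id),
                 text = .asChrOne(c$text),
                 timestamp = as.integer(.asNumOne(c$timestamp)),
                 stringsAsFactors = FALSE)))
  else NULL
  ModerationRecord(.asChrOne(l$state), isTRUE(l$flagged),
                   .asChrOne(l$submitter_id), .asChrOne(l$decided_by),
                   comments,
                   if (is.null(l$revisions)) list() else l$revisions)
}

.geneCanonical <- c("gene_symbol", "entrez_id", "summary",
                    "summary_sources", "aliases", "linkouts")
.geneToList <- function(g) {
  base <- list(gene_symbol = g@geneSymbol, entrez_id = g@entrezId,
               summary = g@summary,
               summary_sources = lapply(g@summarySources, .srcToList),
               aliases = as.list(g@aliases),
               linkouts = as.list(g@linkouts))
  c(.dropNA(base), .sortKeys(.jsonSanitize(g@extras)))
}
.geneFromList <- function(l) {
  extras <- l[setdiff(names(l), .geneCanonical)]
  GeneRecord(.asChrOne(l$gene_symbol), .asNumOne(l$entrez_id),
             .asChrOne(l$summary),
             lapply(l$summary_sources, .srcFromList),
             .asChrVec(l$aliases), .asChrVec(l$linkouts),
             extras = extras)
}

.variantCanonical <- c("gene_symbol", "variant_name", "aliases", "summary",
                       "summary_sources", "variant_types",
                       "hgvs_expressions", "clinvar_ids",
                       "primary_coordinates", "secondary_coordinates",
                       "variant_group_ids", "allele_registry_key",
                       "moderation")
.variantToList <- function(v) {
  base <- list(gene_symbol = v@geneSymbol, variant_name = v@variantName,
               aliases = as.list(v@aliases), summary = v@summary,
               summary_sources = lapply(v@summarySources, .srcToList),
               variant_types = as.list(v@variantTypes),
               hgvs_expressions = as.list(v@hgvsExpressions),
               clinvar_ids = as.list(v@clinvarIds),
               primary_coordinates = .coordsToList(v@primaryCoordinates),
               secondary_coordinates = .coordsToList(v@secondaryCoordinates),
               variant_group_ids = as.list(v@variantGroupIds),
               allele_registry_key = v@alleleRegistryKey,
               moderation = .modToList(v@moderation))
  c(.dropNA(base), .sortKeys(.jsonSanitize(v@extras)))
}
.variantFromList <- function(l) {
  extras <- l[setdiff(names(l), .variantCanonical)]
  VariantRecord(.asChrOne(l$gene_symbol), .asChrOne(l$variant_name),
                .asChrVec(l$aliases), .asChrOne(l$summary),
                lapply(l$summary_sources, .srcFromList),
                .asChrVec(l$variant_types),
                .asChrVec(l$hgvs_expressions), .asChrVec(l$clinvar_ids),
                .coordsFromList(l$primary_coordinates),
                .coordsFromList(l$secondary_coordinates),
                .asChrVec(l$variant_group_ids),
                .asChrOne(l$allele_registry_key),
                .modFromList(l$moderation), extras = extras)
}

.eidCanonical <- c("eid", "gene_symbol", "variant_name", "source",
                   "variant_origin", "disease", "could_not_find_disease",
                   "evidence_statement", "evidence_type", "evidence_level",
                   "evidence_direction", "clinical_significance",
                   "evidence_rating", "drugs", "drug_interaction_type",
                   "phenotypes", "submission_comment", "moderation")
.eidToList <- function(e) {
  base <- list(eid = e@eid, gene_symbol = e@geneSymbol,
               variant_name = e@variantName,
               source = .srcToList(e@source),
               variant_origin = e@variantOrigin,
               disease = if (length(e@diseaseDoid) == 1L) e@diseaseDoid
                         else as.list(e@diseaseDoid),
               could_not_find_disease = e@couldNotFindDisease,
               evidence_statement = e@evidenceStatement,
               evidence_type = e@evidenceType,
               evidence_level = e@evidenceLevel,
               evidence_direction = e@evidenceDirection,
               clinical_significance = e@clinicalSignificance,
               evidence_rating = e@evidenceRating,
               drugs = as.list(e@drugs),
               drug_interaction_type = e@drugInteractionType,
               phenotypes = as.list(e@phenotypes),
               submission_comment = e@submissionComment,
               moderation = .modToList(e@moderation))
  c(.dropNA(base), .sortKeys(.jsonSanitize(e@extras)))
}
.eidFromList <- function(l) {
  extras <- l[setdiff(names(l), .eidCanonical)]
  disease <- if (is.null(l$disease)) NA_character_
             else as.character(unlist(l$disease))
  EvidenceItem(.asChrOne(l$eid), .asChrOne(l$gene_symbol),
               .asChrOne(l$variant_name), .srcFromList(l$source),
               .asChrOne(l$variant_origin), disease,
               isTRUE(l$could_not_find_disease),
               .asChrOne(l$evidence_statement),
               .asChrOne(l$evidence_type), .asChrOne(l$evidence_level),
               .asChrOne(l$evidence_direction),
               .asChrOne(l$clinical_significance),
               .asNumOne(l$evidence_rating), .asChrVec(l$drugs),
               .asChrOne(l$drug_interaction_type),
               .asChrVec(l$phenotypes), .asChrOne(l$submission_comment),
               .modFromList(l$moderation), extras = extras)
}

.assertionCanonical <- c("aid", "gene_symbol", "variant_name",
                         "variant_origin", "disease", "assertion_type",
                         "assertion_direction", "clinical_significance",
                         "drugs", "drug_interaction_type", "phenotypes",
                         "amp_tier", "amp_level", "acmg_codes",
                         "acmg_classification", "nccn_guideline",
                         "nccn_version", "fda_regulatory_approval",
                         "fda_companion_test", "summary", "description",
                         "supporting_eids", "moderation")
.assertionToList <- function(a) {
  base <- list(aid = a@aid, gene_symbol = a@geneSymbol,
               variant_name = a@variantName,
               variant_origin = a@variantOrigin,
               disease = if (length(a@diseaseDoid) == 1L) a@diseaseDoid
                         else as.list(a@diseaseDoid),
               assertion_type = a@assertionType,
               assertion_direction = a@assertionDirection,
               clinical_significance = a@clinicalSignificance,
               drugs = as.list(a@drugs),
               drug_interaction_type = a@drugInteractionType,
               phenotypes = as.list(a@phenotypes),
               amp_tier = a@ampTier, amp_level = a@ampLevel,
               acmg_codes = as.list(a@acmgCodes),
               acmg_classification = a@acmgClassification,
               nccn_guideline = a@nccnGuideline,
               nccn_version = a@nccnVersion,
               fda_regulatory_approval = a@fdaRegulatoryApproval,
               fda_companion_test = a@fdaCompanionTest,
               summary = a@summary, description = a@description,
               supporting_eids = as.list(a@supportingEids),
               moderation = .modToList(a@moderation))
  c(.dropNA(base), .sortKeys(.jsonSanitize(a@extras)))
}
.assertionFromList <- function(l) {
  extras <- l[setdiff(names(l), .assertionCanonical)]
  disease <- if (is.null(l$disease)) NA_character_
             else as.character(unlist(l$disease))
  Assertion(.asChrOne(l$aid), .asChrOne(l$gene_symbol),
            .asChrOne(l$variant_name), .asChrOne(l$variant_origin),
            disease, .asChrOne(l$assertion_type),
            .asChrOne(l$assertion_direction),
            .asChrOne(l$clinical_significance), .asChrVec(l$drugs),
            .asChrOne(l$drug_interaction_type), .asChrVec(l$phenotypes),
            .asChrOne(l$amp_tier), .asChrOne(l$amp_level),
            .asChrVec(l$acmg_codes), .asChrOne(l$acmg_classification),
            .asChrOne(l$nccn_guideline), .asChrOne(l$nccn_version),
            isTRUE(l$fda_regulatory_approval),
            isTRUE(l$fda_companion_test), .asChrOne(l$summary),
            .asChrOne(l$description), .asChrVec(l$supporting_eids),
            .modFromList(l$moderation), extras = extras)
}

## ---- JSON corpus ---------------------------------------------------------

.corpusToList <- function(corpus) {
  extras <- corpus@extras
  extras$integrity_report <- NULL
  list(format_version = 1L,
       clock = as.character(corpus@clock),
       genes = lapply(.sortKeys(corpus@genes), .geneToList),
       variants = lapply(.sortKeys(corpus@variants), .variantToList),
       evidence_items = lapply(.sortKeys(corpus@evidenceItems),
                               .eidToList),
       assertions = lapply(.sortKeys(corpus@assertions),
                           .assertionToList),
       actors = .sortKeys(.jsonSanitize(corpus@actors)),
       event_log = .jsonSanitize(corpus@eventLog),
       extras = .sortKeys(.jsonSanitize(extras)))
}

.corpusFromList <- function(l, registries = bundledRegistries()) {
  corpus <- emptyCorpus(registries = registries,
                        clock = if (is.null(l$clock))
                          as.Date("2020-01-01") else as.Date(l$clock))
  corpus@genes <- lapply(l$genes, .geneFromList)
  corpus@variants <- lapply(l$variants, .variantFromList)
  corpus@evidenceItems <- lapply(l$evidence_items, .eidFromList)
  corpus@assertions <- lapply(l$assertions, .assertionFromList)
  corpus@actors <- if (is.null(l$actors)) list() else l$actors
  corpus@eventLog <- if (is.null(l$event_log)) list() else l$event_log
  corpus@extras <- if (is.null(l$extras)) list() else l$extras
  corpus
}

.atomicWrite <- function(text, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  con <- file(tmp, open = "wb")
  writeBin(charToRaw(text), con)
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

#' Write a corpus to disk
#'
#' Serializes a corpus to the canonical JSON dialect or the flat TSV
#' dialect.  Output is deterministic: keys sorted in the C locale, fixed
#' field order, atomic write (temp file + rename), so the same corpus
#' always produces byte-identical files.  The TSV dialect is one row per
#' record with a \code{record_type} column, multi-valued cells
#' comma-joined (backslash-escaped); it carries the canonical flat fields
#' only — comment threads, revisions, the event log and extras are
#' JSON-only.
#'
#' @param corpus A \linkS4class{Corpus}.
#' @param path Output path.
#' @param format \code{"json"} or \code{"tsv"}.
#' @param withScores Add a \code{variant_evidence_score} column to variant
#'   rows of the TSV export (computed; ignored on read).
#' @return The path, invisibly.
#' @export
writeCorpus <- function(corpus, path, format = c("json", "tsv"),
                        withScores = FALSE) {
  format <- match.arg(format)
  if (format == "json") {
    txt <- as.character(jsonlite::toJSON(.corpusToList(corpus),
                                         auto_unbox = TRUE, null = "null",
                                         na = "null", digits = NA,
                                         pretty = TRUE))
    return(.atomicWrite(paste0(txt, "\n"), path))
  }
  .writeCorpusTsv(corpus, path, withScores)
}

#' Read a corpus from disk
#'
#' Parses the canonical JSON or flat TSV dialect back into a
#' \linkS4class{Corpus}.  Unknown record fields are preserved in each
#' record's extras map and survive a re-write.  A referential-integrity
#' report (dangling gene/variant/evidence references) is computed on load
#' and stored under \code{corpusExtras(corpus)$integrity_report}; it is
#' not serialized back out.
#'
#' @param path Input path.
#' @param format \code{"json"} or \code{"tsv"}.
#' @param registries Ontology registries to attach (bundled subsets by
#'   default; registries are not part of the serialized corpus).
#' @return A \linkS4class{Corpus}.
#' @export
readCorpus <- function(path, format = c("json", "tsv"),
                       registries = bundledRegistries()) {
  format <- match.arg(format)
  corpus <- if (format == "json") {
    l <- tryCatch(
      jsonlite::fromJSON(path, simplifyVector = TRUE,
                         simplifyDataFrame = FALSE,
                         simplifyMatrix = FALSE),
      error = function(e) stop("parse error in ", path, ": ",
                               conditionMessage(e)))
    .corpusFromList(l, registries)
  } else {
    .readCorpusTsv(path, registries)
  }
  report <- .integrityReport(corpus)
  if (nrow(report)) corpus@extras$integrity_report <- report
  corpus
}

#' Extras map of a corpus
#' @param x A \linkS4class{Corpus}.
#' @return Named list.
#' @export
corpusExtras <- function(x) x@extras

.integrityReport <- function(corpus) {
  rows <- list()
  for (e in corpus@evidenceItems) {
    if (!is.na(e@geneSymbol) && !e@geneSymbol %in% names(corpus@genes))
      rows[[length(rows) + 1L]] <-
        .violationRow("CORPUS_DANGLING_REF", "error", e@eid, "gene_symbol",
                      e@geneSymbol)
    vk <- variantKey(e@geneSymbol, e@variantName)
    if (!is.na(e@variantName) && !vk %in% names(corpus@variants))
      rows[[length(rows) + 1L]] <-
        .violationRow("CORPUS_DANGLING_REF", "error", e@eid,
                      "variant_name", vk)
  }
  for (a in corpus@assertions)
    for (e in a@supportingEids)
      if (!e %in% names(corpus@evidenceItems))
        rows[[length(rows) + 1L]] <-
          .violationRow("ASRT_EID_DANGLING", "error", a@aid,
                        "supporting_eids", e)
  .bindViolations(rows)
}

## ---- TSV corpus ----------------------------------------------------------

.tsvEscape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub(",", "\\,", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  gsub("\n", "\\n", x, fixed = TRUE)
}
.tsvUnescapeOne <- function(x) {
  out <- character(0); buf <- ""
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "\\" && i < length(chars)) {
      nxt <- chars[i + 1L]
      buf <- paste0(buf, switch(nxt, t = "\t", n = "\n", nxt))
      i <- i + 2L
    } else if (ch == ",") {
      out <- c(out, buf); buf <- ""
      i <- i + 1L
    } else {
      buf <- paste0(buf, ch)
      i <- i + 1L
    }
  }
  c(out, buf)
}
.joinMulti <- function(x) {
  if (!length(x)) "" else paste(.tsvEscape(x), collapse = ",")
}
.splitMulti <- function(x) {
  if (is.na(x) || x == "") character() else .tsvUnescapeOne(x)
}
.cell <- function(x) {
  if (length(x) != 1L || is.na(x)) "" else .tsvEscape(as.character(x))
}
.cellVal <- function(x) {
  if (is.na(x) || x == "") NA_character_ else .tsvUnescapeOne(x)[1L]
}

.tsvColumns <- function() c(
  "record_type", "id", "gene_symbol", "variant_name", "entrez_id",
  "aliases", "summary", "variant_types", "hgvs_expressions",
  "clinvar_ids", "chromosome", "start", "stop", "reference_base",
  "variant_base", "reference_build", "representative_transcript",
  "chromosome_2", "start_2", "stop_2", "reference_base_2",
  "variant_base_2", "representative_transcript_2", "allele_registry_key",
  "variant_group_ids", "source_type", "source_id", "citation",
  "clinical_trial_ids", "variant_origin", "disease",
  "could_not_find_disease", "evidence_statement", "evidence_type",
  "evidence_level", "evidence_direction", "clinical_significance",
  "evidence_rating", "drugs", "drug_interaction_type", "phenotypes",
  "submission_comment", "assertion_type", "assertion_direction",
  "amp_tier", "amp_level", "acmg_codes", "acmg_classification",
  "nccn_guideline", "nccn_version", "fda_regulatory_approval",
  "fda_companion_test", "description", "supporting_eids", "state",
  "flagged", "submitter_id", "decided_by", "variant_evidence_score")

.blankRow <- function() {
  row <- as.list(rep("", length(.tsvColumns())))
  names(row) <- .tsvColumns()
  row
}

.writeCorpusTsv <- function(corpus, path, withScores = FALSE) {
  cols <- .tsvColumns()
  if (!withScores) cols <- setdiff(cols, "variant_evidence_score")
  rows <- list()
  addRow <- function(row) rows[[length(rows) + 1L]] <<- row

  for (g in .sortKeys(corpus@genes)) {
    row <- .blankRow()
    row$record_type <- "gene"; row$id <- .cell(g@geneSymbol)
    row$gene_symbol <- .cell(g@geneSymbol)
    row$entrez_id <- .cell(g@entrezId)
    row$aliases <- .joinMulti(g@aliases)
    row$summary <- .cell(g@summary)
    addRow(row)
  }
  for (key in sort(names(corpus@variants), method = "radix")) {
    v <- corpus@variants[[key]]
    row <- .blankRow()
    row$record_type <- "variant"; row$id <- .cell(key)
    row$gene_symbol <- .cell(v@geneSymbol)
    row$variant_name <- .cell(v@variantName)
    row$aliases <- .joinMulti(v@aliases)
    row$summary <- .cell(v@summary)
    row$variant_types <- .joinMulti(v@variantTypes)
    row$hgvs_expressions <- .joinMulti(v@hgvsExpressions)
    row$clinvar_ids <- .joinMulti(v@clinvarIds)
    pc <- v@primaryCoordinates
    row$chromosome <- .cell(pc@chromosome)
    row$start <- .cell(pc@start); row$stop <- .cell(pc@stop)
    row$reference_base <- .cell(pc@referenceBase)
    row$variant_base <- .cell(pc@variantBase)
    row$reference_build <- .cell(pc@referenceBuild)
    row$representative_transcript <- .cell(pc@representativeTranscript)
    sc <- v@secondaryCoordinates
    row$chromosome_2 <- .cell(sc@chromosome)
    row$start_2 <- .cell(sc@start); row$stop_2 <- .cell(sc@stop)
    row$reference_base_2 <- .cell(sc@referenceBase)
    row$variant_base_2 <- .cell(sc@variantBase)
    row$representative_transcript_2 <- .cell(sc@representativeTranscript)
    row$allele_registry_key <- .cell(v@alleleRegistryKey)
    row$variant_group_ids <- .joinMulti(v@variantGroupIds)
    row$state <- .cell(v@moderation@state)
    row$flagged <- .cell(tolower(as.character(v@moderation@flagged)))
    row$submitter_id <- .cell(v@moderation@submitterId)
    row$decided_by <- .cell(v@moderation@decidedBy)
    if (withScores)
      row$variant_evidence_score <-
        .cell(variantEvidenceScore(key, corpus)@variantScore)
    addRow(row)
  }
  for (e in .sortKeys(corpus@evidenceItems)) {
    row <- .blankRow()
    row$record_type <- "evidence"; row$id <- .cell(e@eid)
    row$gene_symbol <- .cell(e@geneSymbol)
    row$variant_name <- .cell(e@variantName)
    row$source_type <- .cell(e@source@sourceType)
    row$source_id <- .cell(e@source@sourceId)
    row$citation <- .cell(e@source@citation)
    row$clinical_trial_ids <- .joinMulti(e@source@clinicalTrialIds)
    row$variant_origin <- .cell(e@variantOrigin)
    row$disease <- .joinMulti(e@diseaseDoid[!is.na(e@diseaseDoid)])
    row$could_not_find_disease <-
      .cell(tolower(as.character(e@couldNotFindDisease)))
    row$evidence_statement <- .cell(e@evidenceStatement)
    row$evidence_type <- .cell(e@evidenceType)
    row$evidence_level <- .cell(e@evidenceLevel)
    row$evidence_direction <- .cell(e@evidenceDirection)
    row$clinical_significance <- .cell(e@clinicalSignificance)
    row$evidence_rating <- .cell(e@evidenceRating)
    row$drugs <- .joinMulti(e@drugs)
    row$drug_interaction_type <- .cell(e@drugInteractionType)
    row$phenotypes <- .joinMulti(e@phenotypes)
    row$submission_comment <- .cell(e@submissionComment)
    row$state <- .cell(e@moderation@state)
    row$flagged <- .cell(tolower(as.character(e@moderation@flagged)))
    row$submitter_id <- .cell(e@moderation@submitterId)
    row$decided_by <- .cell(e@moderation@decidedBy)
    addRow(row)
  }
  for (a in .sortKeys(corpus@assertions)) {
    row <- .blankRow()
    row$record_type <- "assertion"; row$id <- .cell(a@aid)
    row$gene_symbol <- .cell(a@geneSymbol)
    row$variant_name <- .cell(a@variantName)
    row$variant_origin <- .cell(a@variantOrigin)
    row$disease <- .joinMulti(a@diseaseDoid[!is.na(a@diseaseDoid)])
    row$assertion_type <- .cell(a@assertionType)
    row$assertion_direction <- .cell(a@assertionDirection)
    row$clinical_significance <- .cell(a@clinicalSignificance)
    row$drugs <- .joinMulti(a@drugs)
    row$drug_interaction_type <- .cell(a@drugInteractionType)
    row$phenotypes <- .joinMulti(a@phenotypes)
    row$amp_tier <- .cell(a@ampTier)
    row$amp_level <- .cell(a@ampLevel)
    row$acmg_codes <- .joinMulti(a@acmgCodes)
    row$acmg_classification <- .cell(a@acmgClassification)
    row$nccn_guideline <- .cell(a@nccnGuideline)
    row$nccn_version <- .cell(a@nccnVersion)
    row$fda_regulatory_approval <-
      .cell(tolower(as.character(a@fdaRegulatoryApproval)))
    row$fda_companion_test <-
      .cell(tolower(as.character(a@fdaCompanionTest)))
    row$summary <- .cell(a@summary)
    row$description <- .cell(a@description)
    row$supporting_eids <- .joinMulti(a@supportingEids)
    row$state <- .cell(a@moderation@state)
    row$flagged <- .cell(tolower(as.character(a@moderation@flagged)))
    row$submitter_id <- .cell(a@moderation@submitterId)
    row$decided_by <- .cell(a@moderation@decidedBy)
    addRow(row)
  }

  lines <- c(paste(cols, collapse = "\t"),
             vapply(rows, function(r)
               paste(unlist(r[cols]), collapse = "\t"), character(1)))
  .atomicWrite(paste0(paste(lines, collapse = "\n"), "\n"), path)
}

.readCorpusTsv <- function(path, registries = bundledRegistries()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL,
                          check.names = FALSE, quote = "")
  corpus <- emptyCorpus(registries = registries)
  modOf <- function(r)
    ModerationRecord(state = if (r[["state"]] == "") "submitted"
                             else r[["state"]],
                     flagged = identical(r[["flagged"]], "true"),
                     submitterId = .cellVal(r[["submitter_id"]]),
                     decidedBy = .cellVal(r[["decided_by"]]))
  for (i in seq_len(nrow(df))) {
    r <- as.list(df[i, , drop = FALSE])
    r <- lapply(r, as.character)
    kind <- r[["record_type"]]
    if (kind == "gene") {
      corpus@genes[[.cellVal(r[["id"]])]] <- GeneRecord(
        .cellVal(r[["gene_symbol"]]),
        as.numeric(.cellVal(r[["entrez_id"]])),
        .cellVal(r[["summary"]]), aliases = .splitMulti(r[["aliases"]]))
    } else if (kind == "variant") {
      pc <- GenomicCoordinates(.cellVal(r[["chromosome"]]),
                               as.numeric(.cellVal(r[["start"]])),
                               as.numeric(.cellVal(r[["stop"]])),
                               .cellVal(r[["reference_base"]]),
                               .cellVal(r[["variant_base"]]),
                               if (is.na(.cellVal(r[["reference_build"]])))
                                 "GRCh37"
                               else .cellVal(r[["reference_build"]]),
                               .cellVal(r[["representative_transcript"]]))
      sc <- GenomicCoordinates(.cellVal(r[["chromosome_2"]]),
                               as.numeric(.cellVal(r[["start_2"]])),
                               as.numeric(.cellVal(r[["stop_2"]])),
                               .cellVal(r[["reference_base_2"]]),
                               .cellVal(r[["variant_base_2"]]),
                               "GRCh37",
                               .cellVal(r[["representative_transcript_2"]]))
      corpus@variants[[.cellVal(r[["id"]])]] <- VariantRecord(
        .cellVal(r[["gene_symbol"]]), .cellVal(r[["variant_name"]]),
        .splitMulti(r[["aliases"]]), .cellVal(r[["summary"]]),
        variantTypes = .splitMulti(r[["variant_types"]]),
        hgvsExpressions = .splitMulti(r[["hgvs_expressions"]]),
        clinvarIds = .splitMulti(r[["clinvar_ids"]]),
        primaryCoordinates = pc, secondaryCoordinates = sc,
        variantGroupIds = .splitMulti(r[["variant_group_ids"]]),
        alleleRegistryKey = .cellVal(r[["allele_registry_key"]]),
        moderation = modOf(r))
    } else if (kind == "evidence") {
      corpus@evidenceItems[[.cellVal(r[["id"]])]] <- EvidenceItem(
        .cellVal(r[["id"]]), .cellVal(r[["gene_symbol"]]),
        .cellVal(r[["variant_name"]]),
        SourceRef(.cellVal(r[["source_type"]]),
                  .cellVal(r[["source_id"]]),
                  .cellVal(r[["citation"]]),
                  .splitMulti(r[["clinical_trial_ids"]])),
        .cellVal(r[["variant_origin"]]),
        { d <- .splitMulti(r[["disease"]])
          if (!length(d)) NA_character_ else d },
        identical(r[["could_not_find_disease"]], "true"),
        .cellVal(r[["evidence_statement"]]),
        .cellVal(r[["evidence_type"]]), .cellVal(r[["evidence_level"]]),
        .cellVal(r[["evidence_direction"]]),
        .cellVal(r[["clinical_significance"]]),
        as.numeric(.cellVal(r[["evidence_rating"]])),
        .splitMulti(r[["drugs"]]),
        .cellVal(r[["drug_interaction_type"]]),
        .splitMulti(r[["phenotypes"]]),
        .cellVal(r[["submission_comment"]]), modOf(r))
    } else if (kind == "assertion") {
      corpus@assertions[[.cellVal(r[["id"]])]] <- Assertion(
        .cellVal(r[["id"]]), .cellVal(r[["gene_symbol"]]),
        .cellVal(r[["variant_name"]]), .cellVal(r[["variant_origin"]]),
        { d <- .splitMulti(r[["disease"]])
          if (!length(d)) NA_character_ else d },
        .cellVal(r[["assertion_type"]]),
        .cellVal(r[["assertion_direction"]]),
        .cellVal(r[["clinical_significance"]]),
        .splitMulti(r[["drugs"]]),
        .cellVal(r[["drug_interaction_type"]]),
        .splitMulti(r[["phenotypes"]]), .cellVal(r[["amp_tier"]]),
        .cellVal(r[["amp_level"]]), .splitMulti(r[["acmg_codes"]]),
        .cellVal(r[["acmg_classification"]]),
        .cellVal(r[["nccn_guideline"]]), .cellVal(r[["nccn_version"]]),
        identical(r[["fda_regulatory_approval"]], "true"),
        identical(r[["fda_companion_test"]], "true"),
        .cellVal(r[["summary"]]), .cellVal(r[["description"]]),
        .splitMulti(r[["supporting_eids"]]), modOf(r))
    } else {
      stop("parse error at record ", i, ": unknown record_type '",
           kind, "'")
    }
  }
  corpus
}
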