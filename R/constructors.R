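## User-facing constructors.  All of them are deliberately permissive about
## missing SOP-required fields: an incomplete record is representable and
## the rule engine reports what is wrong, mirroring how a submission form
## can be saved in an invalid state and then reviewed.

.chr1 <- function(x) {
  if (is.null(x) || length(x) == 0L) return(NA_character_)
  as.character(x)[1L]
}

#' @rdname GenomicCoordinates-class
#' @param chromosome,start,stop,referenceBase,variantBase,referenceBuild,representativeTranscript
#'   See the corresponding slots.
#' @return A \linkS4class{GenomicCoordinates} object.
#' @examples
#' GenomicCoordinates("7", 55242465, 55242479, "GGAATTAAGAGAAGC", "-")
#' @export
GenomicCoordinates <- function(chromosome = NA, start = NA, stop = NA,
                               referenceBase = NA, variantBase = NA,
                               referenceBuild = "GRCh37",
                               representativeTranscript = NA) {
  new("GenomicCoordinates",
      chromosome = .chr1(chromosome),
      start = as.numeric(start)[1L], stop = as.numeric(stop)[1L],
      referenceBase = .chr1(referenceBase),
      variantBase = .chr1(variantBase),
      referenceBuild = .chr1(referenceBuild),
      representativeTranscript = .chr1(representativeTranscript))
}

#' @rdname SourceRef-class
#' @param sourceType,sourceId,citation,clinicalTrialIds See the
#'   corresponding slots.
#' @return A \linkS4class{SourceRef} object.
#' @examples
#' SourceRef("PubMed", "23982599")
#' @export
SourceRef <- function(sourceType = NA, sourceId = NA, citation = NA,
                      clinicalTrialIds = character()) {
  new("SourceRef", sourceType = .chr1(sourceType), sourceId = .chr1(sourceId),
      citation = .chr1(citation),
      clinicalTrialIds = as.character(clinicalTrialIds))
}

#' @rdname ModerationRecord-class
#' @param state,flagged,submitterId,decidedBy,comments,revisions See the
#'   corresponding slots.
#' @return A \linkS4class{ModerationRecord} object.
#' @export
ModerationRecord <- function(state = "submitted", flagged = FALSE,
                             submitterId = NA, decidedBy = NA,
                             comments = NULL, revisions = list()) {
  if (is.null(comments))
    comments <- data.frame(actor_id = character(), text = character(),
                           timestamp = integer(), stringsAsFactors = FALSE)
  new("ModerationRecord", state = .chr1(state), flagged = isTRUE(flagged),
      submitterId = .chr1(submitterId), decidedBy = .chr1(decidedBy),
      comments = comments, revisions = revisions)
}

#' @rdname GeneRecord-class
#' @param geneSymbol,entrezId,summary,summarySources,aliases,linkouts,extras
#'   See the corresponding slots.
#' @return A \linkS4class{GeneRecord} object.
#' @export
GeneRecord <- function(geneSymbol = NA, entrezId = NA, summary = NA,
                       summarySources = list(), aliases = character(),
                       linkouts = character(), extras = list()) {
  new("GeneRecord", geneSymbol = .chr1(geneSymbol),
      entrezId = as.numeric(entrezId)[1L], summary = .chr1(summary),
      summarySources = summarySources, aliases = as.character(aliases),
      linkouts = as.character(linkouts), extras = extras)
}

#' @rdname VariantRecord-class
#' @param geneSymbol,variantName,aliases,summary,summarySources,variantTypes,hgvsExpressions,clinvarIds,primaryCoordinates,secondaryCoordinates,variantGroupIds,alleleRegistryKey,moderation,extras
#'   See the corresponding slots.
#' @return A \linkS4class{VariantRecord} object.
#' @examples
#' VariantRecord("BRAF", "V600E", variantTypes = "SO:0001583")
#' @export
VariantRecord <- function(geneSymbol = NA, variantName = NA,
                          aliases = character(), summary = NA,
                          summarySources = list(),
                          variantTypes = character(),
                          hgvsExpressions = character(),
                          clinvarIds = character(),
                          primaryCoordinates = GenomicCoordinates(),
                          secondaryCoordinates = GenomicCoordinates(),
                          variantGroupIds = character(),
                          alleleRegistryKey = NA,
                          moderation = ModerationRecord(),
                          extras = list()) {
  new("VariantRecord", geneSymbol = .chr1(geneSymbol),
      variantName = .chr1(variantName), aliases = as.character(aliases),
      summary = .chr1(summary), summarySources = summarySources,
      variantTypes = as.character(variantTypes),
      hgvsExpressions = as.character(hgvsExpressions),
      clinvarIds = as.character(clinvarIds),
      primaryCoordinates = primaryCoordinates,
      secondaryCoordinates = secondaryCoordinates,
      variantGroupIds = as.character(variantGroupIds),
      alleleRegistryKey = .chr1(alleleRegistryKey),
      moderation = moderation, extras = extras)
}

#' @rdname EvidenceItem-class
#' @param eid,geneSymbol,variantName,source,variantOrigin,diseaseDoid,couldNotFindDisease,evidenceStatement,evidenceType,evidenceLevel,evidenceDirection,clinicalSignificance,evidenceRating,drugs,drugInteractionType,phenotypes,submissionComment,moderation,extras
#'   See the corresponding slots.
#' @return An \linkS4class{EvidenceItem} object.
#' @examples
#' EvidenceItem("EID1", "EGFR", "L858R",
#'   source = SourceRef("PubMed", "15118073"),
#'   variantOrigin = "Somatic", diseaseDoid = "DOID:3908",
#'   evidenceStatement = "Patients with L858R respond to gefitinib.",
#'   evidenceType = "Predictive", evidenceLevel = "B",
#'   evidenceDirection = "Supports",
#'   clinicalSignificance = "Sensitivity/Response",
#'   evidenceRating = 4L, drugs = "Gefitinib")
#' @export
EvidenceItem <- function(eid = NA, geneSymbol = NA, variantName = NA,
                         source = SourceRef(), variantOrigin = NA,
                         diseaseDoid = NA, couldNotFindDisease = FALSE,
                         evidenceStatement = NA, evidenceType = NA,
                         evidenceLevel = NA, evidenceDirection = NA,
                         clinicalSignificance = NA, evidenceRating = NA,
                         drugs = character(), drugInteractionType = NA,
                         phenotypes = character(), submissionComment = NA,
                         moderation = ModerationRecord(), extras = list()) {
  new("EvidenceItem", eid = .chr1(eid), geneSymbol = .chr1(geneSymbol),
      variantName = .chr1(variantName), source = source,
      variantOrigin = .chr1(variantOrigin),
      diseaseDoid = if (length(diseaseDoid) > 1L) as.character(diseaseDoid)
                    else .chr1(diseaseDoid),
      couldNotFindDisease = isTRUE(couldNotFindDisease),
      evidenceStatement = .chr1(evidenceStatement),
      evidenceType = .chr1(evidenceType),
      evidenceLevel = .chr1(evidenceLevel),
      evidenceDirection = .chr1(evidenceDirection),
      clinicalSignificance = .chr1(clinicalSignificance),
      evidenceRating = if (length(evidenceRating) == 0L ||
                           is.na(evidenceRating[1L])) NA_integer_
                       else as.integer(evidenceRating[1L]),
      drugs = as.character(drugs),
      drugInteractionType = .chr1(drugInteractionType),
      phenotypes = as.character(phenotypes),
      submissionComment = .chr1(submissionComment),
      moderation = moderation, extras = extras)
}

#' @rdname Assertion-class
#' @param aid,geneSymbol,variantName,variantOrigin,diseaseDoid,assertionType,assertionDirection,clinicalSignificance,drugs,drugInteractionType,phenotypes,ampTier,ampLevel,acmgCodes,acmgClassification,nccnGuideline,nccnVersion,fdaRegulatoryApproval,fdaCompanionTest,summary,description,supportingEids,moderation,extras
#'   See the corresponding slots.
#' @return An \linkS4class{Assertion} object.
#' @export
Assertion <- function(aid = NA, geneSymbol = NA, variantName = NA,
                      variantOrigin = NA, diseaseDoid = NA,
                      assertionType = NA, assertionDirection = NA,
                      clinicalSignificance = NA, drugs = character(),
                      drugInteractionType = NA, phenotypes = character(),
                      ampTier = NA, ampLevel = NA, acmgCodes = character(),
                      acmgClassification = NA, nccnGuideline = NA,
                      nccnVersion = NA, fdaRegulatoryApproval = FALSE,
                      fdaCompanionTest = FALSE, summary = NA,
                      description = NA, supportingEids = character(),
                      moderation = ModerationRecord(), extras = list()) {
  new("Assertion", aid = .chr1(aid), geneSymbol = .chr1(geneSymbol),
      variantName = .chr1(variantName), variantOrigin = .chr1(variantOrigin),
      diseaseDoid = if (length(diseaseDoid) > 1L) as.character(diseaseDoid)
                    else .chr1(diseaseDoid),
      assertionType = .chr1(assertionType),
      assertionDirection = .chr1(assertionDirection),
      clinicalSignificance = .chr1(clinicalSignificance),
      drugs = as.character(drugs),
      drugInteractionType = .chr1(drugInteractionType),
      phenotypes = as.character(phenotypes), ampTier = .chr1(ampTier),
      ampLevel = .chr1(ampLevel), acmgCodes = as.character(acmgCodes),
      acmgClassification = .chr1(acmgClassification),
      nccnGuideline = .chr1(nccnGuideline), nccnVersion = .chr1(nccnVersion),
      fdaRegulatoryApproval = isTRUE(fdaRegulatoryApproval),
      fdaCompanionTest = isTRUE(fdaCompanionTest), summary = .chr1(summary),
      description = .chr1(description),
      supportingEids = as.character(supportingEids),
      moderation = moderation, extras = extras)
}

#' Create an empty corpus
#'
#' @param registries Named list of \linkS4class{OntologyRegistry} objects;
#'   defaults to the bundled mini-subsets.
#' @param clock Corpus date used for conflict-of-interest checks.
#' @return An empty \linkS4class{Corpus}.
#' @examples
#' emptyCorpus()
#' @export
emptyCorpus <- function(registries = bundledRegistries(),
                        clock = as.Date("2020-01-01")) {
  new("Corpus", registries = registries, clock = clock)
}

#' Key of a variant within a corpus
#'
#' Variants are keyed by \code{"SYMBOL::Variant Name"} in the corpus
#' collections.
#'
#' @param geneSymbol,variantName Gene symbol and variant name.
#' @return Character key.
#' @export
variantKey <- function(geneSymbol, variantName) {
  paste0(geneSymbol, "::", variantName)
}
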