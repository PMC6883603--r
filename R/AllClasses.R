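#' @import methods
NULL

.scalarOrNA <- function(x) length(x) == 1L

#' Genomic coordinates for a representative variant
#'
#' One-based, fully closed coordinates of a representative alteration on a
#' named reference build, in the trimmed-allele dialect: shared bases between
#' the reference and variant alleles are removed and an absent allele is
#' written \code{"-"}.  Insertions occupy the two flanking bases
#' (\code{stop == start + 1}).
#'
#' @slot chromosome Chromosome or contig name.
#' @slot start,stop 1-based inclusive coordinates, \code{start <= stop}.
#' @slot referenceBase,variantBase Allele strings over A/C/G/T, or \code{"-"}
#'   for the empty allele; never both \code{"-"}.
#' @slot referenceBuild Assembly tag; defaults to \code{"GRCh37"}.
#' @slot representativeTranscript Versioned transcript accession
#'   (e.g. \code{"ENST00000078429.1"}), or \code{NA}.
#' @exportClass GenomicCoordinates
setClass("GenomicCoordinates",
  representation(
    chromosome = "character",
    start = "numeric",
    stop = "numeric",
    referenceBase = "character",
    variantBase = "character",
    referenceBuild = "character",
    representativeTranscript = "character"
  ),
  prototype(
    chromosome = NA_character_, start = NA_real_, stop = NA_real_,
    referenceBase = NA_character_, variantBase = NA_character_,
    referenceBuild = "GRCh37", representativeTranscript = NA_character_
  ),
  validity = function(object) {
    msg <- character()
    for (s in c("chromosome", "referenceBase", "variantBase",
                "referenceBuild", "representativeTranscript"))
      if (!.scalarOrNA(slot(object, s)))
        msg <- c(msg, sprintf("slot '%s' must be length 1", s))
    if (length(object@start) != 1L || length(object@stop) != 1L)
      msg <- c(msg, "start and stop must be length 1")
    if (length(msg)) msg else TRUE
  }
)

#' Literature source reference
#'
#' @slot sourceType \code{"PubMed"} or \code{"ASCO"}.
#' @slot sourceId Identifier within the source database (PubMed ID or ASCO
#'   Web ID).
#' @slot citation Stored abbreviated citation text.
#' @slot clinicalTrialIds Clinical-trial registry numbers linked to the
#'   source.
#' @exportClass SourceRef
setClass("SourceRef",
  representation(
    sourceType = "character",
    sourceId = "character",
    citation = "character",
    clinicalTrialIds = "character"
  ),
  prototype(
    sourceType = NA_character_, sourceId = NA_character_,
    citation = NA_character_, clinicalTrialIds = character()
  )
)

#' Moderation state of a curatable entity
#'
#' Every curatable record carries its position in the curation/moderation
#' cycle: it is \code{submitted} on creation and moves to \code{accepted} or
#' \code{rejected} through editor review.  Flags mark records needing
#' attention; comments and pending/decided revisions are kept with the
#' record.
#'
#' @slot state One of \code{"submitted"}, \code{"accepted"},
#'   \code{"rejected"}.
#' @slot flagged Logical flag raised by any curator, cleared by an editor.
#' @slot submitterId Actor id of the submitter.
#' @slot decidedBy Actor id of the editor who accepted/rejected, or
#'   \code{NA}.
#' @slot comments data.frame with columns \code{actor_id}, \code{text},
#'   \code{timestamp} (logical sequence number).
#' @slot revisions List of revision records (see
#'   \code{\link{proposeRevision}}).
#' @exportClass ModerationRecord
setClass("ModerationRecord",
  representation(
    state = "character",
    flagged = "logical",
    submitterId = "character",
    decidedBy = "character",
    comments = "data.frame",
    revisions = "list"
  ),
  prototype(
    state = "submitted", flagged = FALSE,
    submitterId = NA_character_, decidedBy = NA_character_,
    comments = data.frame(actor_id = character(), text = character(),
                          timestamp = integer(),
                          stringsAsFactors = FALSE),
    revisions = list()
  ),
  validity = function(object) {
    if (!object@state %in% c("submitted", "accepted", "rejected"))
      return("state must be submitted/accepted/rejected")
    TRUE
  }
)

#' Gene record
#'
#' Gene-level container: summary with sources, aliases and opaque link-outs.
#' A gene is only persisted in a corpus while at least one variant record
#' references it; the rule engine reports orphans.
#'
#' @slot geneSymbol HGNC/Entrez symbol.
#' @slot entrezId Entrez gene id (NA when unknown).
#' @slot summary,summarySources Free-text gene summary and its sources
#'   (list of \linkS4class{SourceRef}).
#' @slot aliases Alternative symbols.
#' @slot linkouts Opaque URLs to external gene resources.
#' @slot extras Unrecognised fields preserved on round trip.
#' @exportClass GeneRecord
setClass("GeneRecord",
  representation(
    geneSymbol = "character",
    entrezId = "numeric",
    summary = "character",
    summarySources = "list",
    aliases = "character",
    linkouts = "character",
    extras = "list"
  ),
  prototype(
    geneSymbol = NA_character_, entrezId = NA_real_,
    summary = NA_character_, summarySources = list(),
    aliases = character(), linkouts = character(), extras = list()
  )
)

#' Variant record
#'
#' A broadly-defined variant: a specific alteration (SNV, indel, fusion) or
#' a named categorical collection (e.g. "Exon 20 Insertion", "Mutation").
#' Carries Sequence Ontology variant types, HGVS expressions, ClinVar ids,
#' representative coordinates and a moderation record.
#'
#' @slot geneSymbol Owning gene symbol.
#' @slot variantName Specific or categorical variant name.
#' @slot aliases Alternative names/identifiers (dbSNP, COSMIC, ...).
#' @slot summary,summarySources Variant-level clinical summary and sources.
#' @slot variantTypes Sequence Ontology term ids (\code{SO:#######}).
#' @slot hgvsExpressions HGVS strings (well-formedness checked only).
#' @slot clinvarIds ClinVar ids as strings, or the sentinel
#'   \code{"NONE_FOUND"}.
#' @slot primaryCoordinates,secondaryCoordinates
#'   \linkS4class{GenomicCoordinates}; secondary coordinates are reserved
#'   for two-locus structural variants (fusions).
#' @slot variantGroupIds Ids of variant groups this variant belongs to.
#' @slot alleleRegistryKey Opaque allele-registry identifier.
#' @slot moderation \linkS4class{ModerationRecord}.
#' @slot extras Unrecognised fields preserved on round trip.
#' @exportClass VariantRecord
setClass("VariantRecord",
  representation(
    geneSymbol = "character",
    variantName = "character",
    aliases = "character",
    summary = "character",
    summarySources = "list",
    variantTypes = "character",
    hgvsExpressions = "character",
    clinvarIds = "character",
    primaryCoordinates = "GenomicCoordinates",
    secondaryCoordinates = "GenomicCoordinates",
    variantGroupIds = "character",
    alleleRegistryKey = "character",
    moderation = "ModerationRecord",
    extras = "list"
  ),
  prototype(
    geneSymbol = NA_character_, variantName = NA_character_,
    aliases = character(), summary = NA_character_, summarySources = list(),
    variantTypes = character(), hgvsExpressions = character(),
    clinvarIds = character(),
    variantGroupIds = character(), alleleRegistryKey = NA_character_,
    extras = list()
  )
)

#' Evidence item
#'
#' The core record: one literature- or abstract-derived clinical claim about
#' a variant.  Twelve universally required fields (gene, variant, source
#' type and id, variant origin, disease, statement, evidence type, level,
#' direction, clinical significance, star rating) plus conditional fields
#' (drugs and drug interaction type for Predictive items) and optional
#' phenotypes.  Structural looseness is deliberate: incomplete items are
#' representable and the rule engine (\code{\link{validateEvidenceItem}})
#' reports what is wrong.
#'
#' @slot eid Evidence item identifier.
#' @slot geneSymbol,variantName Gene and variant the claim is about.
#' @slot source \linkS4class{SourceRef}.
#' @slot variantOrigin Somatic / Rare Germline / Common Germline / Unknown /
#'   N/A.
#' @slot diseaseDoid Disease Ontology CURIE (\code{DOID:####}), or free text
#'   when \code{couldNotFindDisease} is set.  Exactly one disease per item.
#' @slot couldNotFindDisease Free-text disease escape hatch.
#' @slot evidenceStatement Brief summary of the claim (1-3 sentences).
#' @slot evidenceType Predictive / Diagnostic / Prognostic / Predisposing /
#'   Functional.
#' @slot evidenceLevel A (validated) through E (inferential).
#' @slot evidenceDirection Supports / Does not support.
#' @slot clinicalSignificance Member of the per-type significance
#'   vocabulary.
#' @slot evidenceRating Integer star rating 1-5.
#' @slot drugs Drug names (Predictive only), generic NCIt names.
#' @slot drugInteractionType Combination / Sequential / Substitutes,
#'   required with more than one drug.
#' @slot phenotypes HPO term ids.
#' @slot submissionComment Free-form comment shown to the reviewing editor.
#' @slot moderation \linkS4class{ModerationRecord}.
#' @slot extras Unrecognised fields preserved on round trip.
#' @exportClass EvidenceItem
setClass("EvidenceItem",
  representation(
    eid = "character",
    geneSymbol = "character",
    variantName = "character",
    source = "SourceRef",
    variantOrigin = "character",
    diseaseDoid = "character",
    couldNotFindDisease = "logical",
    evidenceStatement = "character",
    evidenceType = "character",
    evidenceLevel = "character",
    evidenceDirection = "character",
    clinicalSignificance = "character",
    evidenceRating = "integer",
    drugs = "character",
    drugInteractionType = "character",
    phenotypes = "character",
    submissionComment = "character",
    moderation = "ModerationRecord",
    extras = "list"
  ),
  prototype(
    eid = NA_character_, geneSymbol = NA_character_,
    variantName = NA_character_,
    variantOrigin = NA_character_, diseaseDoid = NA_character_,
    couldNotFindDisease = FALSE, evidenceStatement = NA_character_,
    evidenceType = NA_character_, evidenceLevel = NA_character_,
    evidenceDirection = NA_character_, clinicalSignificance = NA_character_,
    evidenceRating = NA_integer_, drugs = character(),
    drugInteractionType = NA_character_, phenotypes = character(),
    submissionComment = NA_character_, extras = list()
  )
)

#' Assertion
#'
#' A disease-specific synthesis of evidence items carrying a formal
#' classification: AMP-ASCO-CAP Tier (I-IV) and Level (A-D) for Predictive,
#' Prognostic and Diagnostic assertions, or an ACMG-AMP five-tier germline
#' classification for Predisposing assertions.
#'
#' @slot aid Assertion identifier.
#' @slot geneSymbol,variantName Gene/variant asserted about.
#' @slot variantOrigin As for evidence items.
#' @slot diseaseDoid Single Disease Ontology CURIE.
#' @slot assertionType Predictive / Diagnostic / Prognostic / Predisposing.
#' @slot assertionDirection Supports / Does not support.
#' @slot clinicalSignificance Per-type vocabulary member (assertions of
#'   somatic types additionally admit Benign / Likely Benign to express
#'   Tier IV conclusions).
#' @slot drugs,drugInteractionType Predictive assertions only.
#' @slot phenotypes HPO term ids.
#' @slot ampTier,ampLevel AMP-ASCO-CAP tier \code{"I".."IV"} and level
#'   \code{"A".."D"} (somatic types only).
#' @slot acmgCodes ACMG-AMP criterion tokens, optionally with a strength
#'   override suffix, e.g. \code{"PVS1"}, \code{"PS1@moderate"}.
#' @slot acmgClassification Pathogenic / Likely Pathogenic / VUS /
#'   Likely Benign / Benign (Predisposing only).
#' @slot nccnGuideline,nccnVersion Free-text practice-guideline annotation.
#' @slot fdaRegulatoryApproval,fdaCompanionTest Regulatory flags.
#' @slot summary One-sentence summary.
#' @slot description Longer description of the synthesis.
#' @slot supportingEids Identifiers of supporting evidence items.
#' @slot moderation \linkS4class{ModerationRecord}.
#' @slot extras Unrecognised fields preserved on round trip.
#' @exportClass Assertion
setClass("Assertion",
  representation(
    aid = "character",
    geneSymbol = "character",
    variantName = "character",
    variantOrigin = "character",
    diseaseDoid = "character",
    assertionType = "character",
    assertionDirection = "character",
    clinicalSignificance = "character",
    drugs = "character",
    drugInteractionType = "character",
    phenotypes = "character",
    ampTier = "character",
    ampLevel = "character",
    acmgCodes = "character",
    acmgClassification = "character",
    nccnGuideline = "character",
    nccnVersion = "character",
    fdaRegulatoryApproval = "logical",
    fdaCompanionTest = "logical",
    summary = "character",
    description = "character",
    supportingEids = "character",
    moderation = "ModerationRecord",
    extras = "list"
  ),
  prototype(
    aid = NA_character_, geneSymbol = NA_character_,
    variantName = NA_character_, variantOrigin = NA_character_,
    diseaseDoid = NA_character_, assertionType = NA_character_,
    assertionDirection = NA_character_, clinicalSignificance = NA_character_,
    drugs = character(), drugInteractionType = NA_character_,
    phenotypes = character(), ampTier = NA_character_,
    ampLevel = NA_character_, acmgCodes = character(),
    acmgClassification = NA_character_, nccnGuideline = NA_character_,
    nccnVersion = NA_character_, fdaRegulatoryApproval = FALSE,
    fdaCompanionTest = FALSE, summary = NA_character_,
    description = NA_character_, supportingEids = character(),
    extras = list()
  )
)

#' Ontology term registry
#'
#' In-memory registry for one ontology subset (disease, sequence, phenotype
#' or drug terms) supporting id/name lookup and ancestor queries over the
#' is-a DAG.  Built by \code{\link{loadOntology}}; cyclic or dangling
#' parentage is rejected at load time.
#'
#' @slot terms data.frame with columns \code{term_id}, \code{name},
#'   \code{ontology_key}.
#' @slot parents Named list: term id -> character vector of parent ids.
#' @slot ontologyKey One of \code{"disease"}, \code{"sequence"},
#'   \code{"phenotype"}, \code{"drug"}.
#' @exportClass OntologyRegistry
setClass("OntologyRegistry",
  representation(
    terms = "data.frame",
    parents = "list",
    ontologyKey = "character"
  ),
  prototype(
    terms = data.frame(term_id = character(), name = character(),
                       ontology_key = character(), stringsAsFactors = FALSE),
    parents = list(), ontologyKey = NA_character_
  )
)

#' Curation corpus
#'
#' The top-level container: identifier-keyed collections of genes, variants,
#' evidence items and assertions, the ontology registries they are validated
#' against, the registered actors, and the append-only event log that the
#' current state is a fold over (see \code{\link{replayEvents}}).
#'
#' @slot genes Named list of \linkS4class{GeneRecord} keyed by symbol.
#' @slot variants Named list of \linkS4class{VariantRecord} keyed by
#'   \code{"SYMBOL::Variant Name"}.
#' @slot evidenceItems Named list of \linkS4class{EvidenceItem} keyed by
#'   eid.
#' @slot assertions Named list of \linkS4class{Assertion} keyed by aid.
#' @slot registries Named list of \linkS4class{OntologyRegistry}.
#' @slot actors Named list of actor records (\code{list(actor_id, role,
#'   coi_statement_date)}).
#' @slot eventLog List of event records (append-only).
#' @slot clock Corpus date used for conflict-of-interest validity checks;
#'   fixed, never wall-clock.
#' @slot extras Generator ground truth, preserved unknown fields, etc.
#' @exportClass Corpus
setClass("Corpus",
  representation(
    genes = "list",
    variants = "list",
    evidenceItems = "list",
    assertions = "list",
    registries = "list",
    actors = "list",
    eventLog = "list",
    clock = "Date",
    extras = "list"
  ),
  prototype(
    genes = list(), variants = list(), evidenceItems = list(),
    assertions = list(), registries = list(), actors = list(),
    eventLog = list(), clock = as.Date("2020-01-01"), extras = list()
  )
)

#' Variant evidence score report
#'
#' @slot perItem data.frame with columns \code{eid}, \code{rating},
#'   \code{level}, \code{score}.
#' @slot variantScore Exact sum of the per-item scores.
#' @slot includedStatuses Moderation states that were counted.
#' @exportClass ScoreReport
setClass("ScoreReport",
  representation(
    perItem = "data.frame",
    variantScore = "numeric",
    includedStatuses = "character"
  )
)

#' ACMG-AMP combined classification
#'
#' @slot value Pathogenic / Likely Pathogenic / VUS / Likely Benign /
#'   Benign.
#' @slot firedRules Identifiers of the combining-table rows that fired.
#' @slot conflict TRUE when pathogenic-side and benign-side evidence
#'   contradict; forces \code{value == "VUS"}.
#' @exportClass AcmgClassification
setClass("AcmgClassification",
  representation(
    value = "character",
    firedRules = "character",
    conflict = "logical"
  ),
  validity = function(object) {
    if (isTRUE(object@conflict) && object@value != "VUS")
      return("conflicting evidence must classify as VUS")
    TRUE
  }
)

#' AMP-ASCO-CAP tier/level assignment
#'
#' @slot tier \code{"I".."IV"}.
#' @slot level \code{"A".."D"} for tiers I/II, \code{NA} otherwise.
#' @slot rationale Evidence references and flags used in the decision.
#' @exportClass AmpAssignment
setClass("AmpAssignment",
  representation(
    tier = "character",
    level = "character",
    rationale = "character"
  ),
  validity = function(object) {
    t <- object@tier; l <- object@level
    if (t %in% c("I", "II") && is.na(l))
      return("tiers I/II require a level")
    if (t %in% c("III", "IV") && !is.na(l))
      return("tiers III/IV carry no level")
    if (t == "I" && !is.na(l) && !l %in% c("A", "B"))
      return("tier I implies level A or B")
    if (t == "II" && !is.na(l) && !l %in% c("C", "D"))
      return("tier II implies level C or D")
    TRUE
  }
)

#' Left-shift normalization result
#'
#' @slot normalized \linkS4class{GenomicCoordinates} in leftmost trimmed
#'   form.
#' @slot shiftedBy Positions the start moved left.
#' @slot trimmed TRUE when shared prefix/suffix bases were removed from the
#'   input alleles.
#' @exportClass NormalizationResult
setClass("NormalizationResult",
  representation(
    normalized = "GenomicCoordinates",
    shiftedBy = "numeric",
    trimmed = "logical"
  )
)

## ---- show methods -------------------------------------------------------

setMethod("show", "GenomicCoordinates", function(object) {
  cat(sprintf("GenomicCoordinates %s:%s-%s %s>%s [%s%s]\n",
              object@chromosome, format(object@start), format(object@stop),
              object@referenceBase, object@variantBase,
              object@referenceBuild,
              if (is.na(object@representativeTranscript)) ""
              else paste0(", ", object@representativeTranscript)))
})

setMethod("show", "EvidenceItem", function(object) {
  cat(sprintf("EvidenceItem %s: %s %s [%s/%s/%s, %s]\n",
              object@eid, object@geneSymbol, object@variantName,
              object@evidenceType, object@evidenceLevel,
              object@evidenceDirection,
              if (is.na(object@evidenceRating)) "unrated"
              else paste0(object@evidenceRating, "-star")))
  cat(sprintf("  disease: %s | significance: %s | state: %s\n",
              object@diseaseDoid, object@clinicalSignificance,
              object@moderation@state))
})

setMethod("show", "Assertion", function(object) {
  cls <- if (!is.na(object@acmgClassification)) object@acmgClassification
         else if (!is.na(object@ampTier))
           paste0("Tier ", object@ampTier,
                  if (!is.na(object@ampLevel))
                    paste0(" Level ", object@ampLevel) else "")
         else "unclassified"
  cat(sprintf("Assertion %s: %s %s (%s) -> %s [state: %s]\n",
              object@aid, object@geneSymbol, object@variantName,
              object@assertionType, cls, object@moderation@state))
})

setMethod("show", "OntologyRegistry", function(object) {
  cat(sprintf("OntologyRegistry '%s': %d terms\n",
              object@ontologyKey, nrow(object@terms)))
})

setMethod("show", "Corpus", function(object) {
  cat("Corpus:\n")
  cat(sprintf("  genes: %d | variants: %d | evidence items: %d | assertions: %d\n",
              length(object@genes), length(object@variants),
              length(object@evidenceItems), length(object@assertions)))
  cat(sprintf("  registries: %s | actors: %d | events: %d\n",
              if (length(object@registries))
                paste(names(object@registries), collapse = ", ") else "none",
              length(object@actors), length(object@eventLog)))
})

setMethod("show", "AcmgClassification", function(object) {
  cat(sprintf("AcmgClassification: %s%s\n", object@value,
              if (isTRUE(object@conflict)) " (conflicting evidence)" else ""))
  if (length(object@firedRules))
    cat("  fired rules:", paste(object@firedRules, collapse = ", "), "\n")
})

setMethod("show", "AmpAssignment", function(object) {
  cat(sprintf("AmpAssignment: Tier %s%s\n", object@tier,
              if (!is.na(object@level)) paste0(", Level ", object@level)
              else ""))
  for (r in object@rationale) cat("  -", r, "\n")
})

setMethod("show", "ScoreReport", function(object) {
  cat(sprintf("ScoreReport: variant evidence score %s over %d item(s) [%s]\n",
              format(object@variantScore), nrow(object@perItem),
              paste(object@includedStatuses, collapse = "+")))
})

setMethod("show", "NormalizationResult", function(object) {
  cat("NormalizationResult (shifted by", object@shiftedBy,
      if (isTRUE(object@trimmed)) "positions, trimmed):"
      else "positions):", "\n  ")
  show(object@normalized)
})
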