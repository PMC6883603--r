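## Generics and accessors.  Slot access from user code should go through
## these rather than `@`.

#' @export
setGeneric("moderationState", function(x) standardGeneric("moderationState"))
#' Moderation state of a record
#' @param x An \linkS4class{EvidenceItem}, \linkS4class{VariantRecord} or
#'   \linkS4class{Assertion}.
#' @return \code{"submitted"}, \code{"accepted"} or \code{"rejected"}.
#' @aliases moderationState
#' @rdname moderationState
#' @export
setMethod("moderationState", "EvidenceItem", function(x) x@moderation@state)
#' @rdname moderationState
setMethod("moderationState", "Assertion", function(x) x@moderation@state)
#' @rdname moderationState
setMethod("moderationState", "VariantRecord", function(x) x@moderation@state)
#' @rdname moderationState
setMethod("moderationState", "ModerationRecord", function(x) x@state)

#' @export
setGeneric("isFlagged", function(x) standardGeneric("isFlagged"))
#' Is a record flagged for editor attention?
#' @param x A curatable record.
#' @aliases isFlagged
#' @rdname isFlagged
#' @export
setMethod("isFlagged", "EvidenceItem", function(x) x@moderation@flagged)
#' @rdname isFlagged
setMethod("isFlagged", "Assertion", function(x) x@moderation@flagged)
#' @rdname isFlagged
setMethod("isFlagged", "VariantRecord", function(x) x@moderation@flagged)

#' Collections of a corpus
#'
#' Accessors for the identifier-keyed collections and bookkeeping slots of a
#' \linkS4class{Corpus}.
#'
#' @param x A \linkS4class{Corpus}.
#' @return A named list (collections), or the event log / registry list.
#' @name corpus-accessors
NULL

#' @export
setGeneric("corpusGenes", function(x) standardGeneric("corpusGenes"))
#' @rdname corpus-accessors
#' @aliases corpusGenes
#' @export
setMethod("corpusGenes", "Corpus", function(x) x@genes)

#' @export
setGeneric("corpusVariants", function(x) standardGeneric("corpusVariants"))
#' @rdname corpus-accessors
#' @aliases corpusVariants
#' @export
setMethod("corpusVariants", "Corpus", function(x) x@variants)

#' @export
setGeneric("corpusEvidence", function(x) standardGeneric("corpusEvidence"))
#' @rdname corpus-accessors
#' @aliases corpusEvidence
#' @export
setMethod("corpusEvidence", "Corpus", function(x) x@evidenceItems)

#' @export
setGeneric("corpusAssertions", function(x) standardGeneric("corpusAssertions"))
#' @rdname corpus-accessors
#' @aliases corpusAssertions
#' @export
setMethod("corpusAssertions", "Corpus", function(x) x@assertions)

#' @export
setGeneric("corpusRegistries", function(x) standardGeneric("corpusRegistries"))
#' @rdname corpus-accessors
#' @aliases corpusRegistries
#' @export
setMethod("corpusRegistries", "Corpus", function(x) x@registries)

#' @export
setGeneric("eventLog", function(x) standardGeneric("eventLog"))
#' @rdname corpus-accessors
#' @aliases eventLog
#' @export
setMethod("eventLog", "Corpus", function(x) x@eventLog)

#' @export
setGeneric("variantScore", function(x) standardGeneric("variantScore"))
#' Total variant evidence score of a report
#' @param x A \linkS4class{ScoreReport}.
#' @aliases variantScore
#' @rdname variantScore
#' @export
setMethod("variantScore", "ScoreReport", function(x) x@variantScore)

#' @export
setGeneric("perItemScores", function(x) standardGeneric("perItemScores"))
#' Per-evidence-item score breakdown of a report
#' @param x A \linkS4class{ScoreReport}.
#' @aliases perItemScores
#' @rdname perItemScores
#' @export
setMethod("perItemScores", "ScoreReport", function(x) x@perItem)

#' @export
setGeneric("classificationValue",
           function(x) standardGeneric("classificationValue"))
#' Classification outcome accessors
#' @param x An \linkS4class{AcmgClassification} or
#'   \linkS4class{AmpAssignment}.
#' @aliases classificationValue firedRules hasConflict ampTier ampLevel
#' @name classification-accessors
#' @export
setMethod("classificationValue", "AcmgClassification", function(x) x@value)

#' @export
setGeneric("firedRules", function(x) standardGeneric("firedRules"))
#' @rdname classification-accessors
#' @export
setMethod("firedRules", "AcmgClassification", function(x) x@firedRules)

#' @export
setGeneric("hasConflict", function(x) standardGeneric("hasConflict"))
#' @rdname classification-accessors
#' @export
setMethod("hasConflict", "AcmgClassification", function(x) x@conflict)

#' @export
setGeneric("ampTier", function(x) standardGeneric("ampTier"))
#' @rdname classification-accessors
#' @export
setMethod("ampTier", "AmpAssignment", function(x) x@tier)

#' @export
setGeneric("ampLevel", function(x) standardGeneric("ampLevel"))
#' @rdname classification-accessors
#' @export
setMethod("ampLevel", "AmpAssignment", function(x) x@level)

#' @export
setGeneric("normalizedCoordinates",
           function(x) standardGeneric("normalizedCoordinates"))
#' Normalization result accessors
#' @param x A \linkS4class{NormalizationResult}.
#' @aliases normalizedCoordinates shiftedBy
#' @name normalization-accessors
#' @export
setMethod("normalizedCoordinates", "NormalizationResult",
          function(x) x@normalized)

#' @export
setGeneric("shiftedBy", function(x) standardGeneric("shiftedBy"))
#' @rdname normalization-accessors
#' @export
setMethod("shiftedBy", "NormalizationResult", function(x) x@shiftedBy)
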