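## Evidence scoring: one point per star times the evidence-level weight,
## summed per variant.  Direction and significance are deliberately not
## consulted: the variant evidence score measures the amount of curation,
## not a clinical verdict, and takes no account of conflicting evidence.
##
## Arithmetic is exact: default weights (10, 5, 3, 1, 0.5) are all integer
## multiples of one half, so scores are computed in integer half-points and
## divided by two at the end — no binary floating-point drift can
## accumulate in sums.

.halfPoints <- function(weights) {
  hp <- vapply(weights, function(w) {
    h <- w * 2
    if (abs(h - round(h)) > 1e-9)
      stop("domain error: level weights must be multiples of 0.5")
    round(h)
  }, numeric(1))
  hp
}

#' Evidence-level weights
#'
#' The default weighting of the five evidence levels: validated
#' association A = 10, clinical evidence B = 5, case study C = 3,
#' preclinical D = 1, inferential E = 0.5.  Alternative schemes can be
#' supplied to the scoring functions, but must cover all five levels with
#' positive weights.
#'
#' @param config Configuration list.
#' @return Named numeric vector over levels A-E.
#' @examples
#' defaultLevelWeights()
#' @export
defaultLevelWeights <- function(config = defaultConfig()) {
  w <- unlist(config$level_weights)
  .checkWeights(w, config)
  w
}

.checkWeights <- function(weights, config = defaultConfig()) {
  need <- config$evidence_levels
  if (!all(need %in% names(weights)))
    stop("domain error: weights must cover all five evidence levels")
  if (any(weights[need] <= 0))
    stop("domain error: level weights must be positive")
  invisible(TRUE)
}

#' Score a single evidence item
#'
#' The evidence item score is the star rating (one point per star, 1-5)
#' multiplied by the weight of its evidence level.
#'
#' @param rating Integer star rating in 1..5, or an
#'   \linkS4class{EvidenceItem} (in which case \code{level} is ignored).
#' @param level Evidence level \code{"A".."E"}.
#' @param weights Named weight vector (see
#'   \code{\link{defaultLevelWeights}}).
#' @return Numeric score, exact to the half point.
#' @examples
#' evidenceItemScore(1, "A")   # 10
#' evidenceItemScore(5, "E")   # 2.5
#' @export
evidenceItemScore <- function(rating, level,
                              weights = defaultLevelWeights()) {
  if (is(rating, "EvidenceItem")) {
    level <- rating@evidenceLevel
    rating <- rating@evidenceRating
  }
  if (length(rating) != 1L || is.na(rating) ||
      as.integer(rating) != rating || rating < 1L || rating > 5L)
    stop("domain error: rating must be an integer between 1 and 5")
  if (length(level) != 1L || is.na(level) || !level %in% names(weights))
    stop("domain error: unknown evidence level '", level, "'")
  .checkWeights(weights)
  hp <- .halfPoints(weights)
  (as.integer(rating) * hp[[level]]) / 2
}

#' Variant evidence score
#'
#' Sums the evidence item scores of all evidence items attached to a
#' variant whose moderation state is in \code{includedStatuses}
#' (by default only accepted items count).  Evidence direction and
#' clinical significance are ignored by design: opposing items add up,
#' they do not cancel.
#'
#' @param variant A \linkS4class{VariantRecord}, or a variant key string
#'   \code{"SYMBOL::Name"}.
#' @param corpus The \linkS4class{Corpus} holding the evidence items.
#' @param weights Level weight vector.
#' @param includedStatuses Moderation states to count; default
#'   \code{"accepted"}, configurable to
#'   \code{c("accepted", "submitted")}.
#' @return A \linkS4class{ScoreReport}; an empty evidence set scores 0.
#' @export
variantEvidenceScore <- function(variant, corpus,
                                 weights = defaultLevelWeights(),
                                 includedStatuses =
                                   defaultConfig()$included_statuses) {
  key <- if (is(variant, "VariantRecord"))
    variantKey(variant@geneSymbol, variant@variantName)
  else as.character(variant)
  .checkWeights(weights)
  hp <- .halfPoints(weights)

  items <- Filter(function(e)
    identical(variantKey(e@geneSymbol, e@variantName), key) &&
      e@moderation@state %in% includedStatuses,
    corpus@evidenceItems)

  if (length(items)) {
    eids <- vapply(items, function(e) e@eid, character(1))
    ratings <- vapply(items, function(e) e@evidenceRating, integer(1))
    levels <- vapply(items, function(e) e@evidenceLevel, character(1))
    scoresHp <- ratings * hp[levels]
    ord <- order(eids, method = "radix")
    per <- data.frame(eid = eids[ord], rating = ratings[ord],
                      level = levels[ord], score = scoresHp[ord] / 2,
                      stringsAsFactors = FALSE, row.names = NULL)
    total <- sum(scoresHp) / 2
  } else {
    per <- data.frame(eid = character(), rating = integer(),
                      level = character(), score = numeric(),
                      stringsAsFactors = FALSE)
    total <- 0
  }
  new("ScoreReport", perItem = per, variantScore = total,
      includedStatuses = includedStatuses)
}

#' Score every variant in a corpus
#'
#' @param corpus A \linkS4class{Corpus}.
#' @param weights Level weight vector.
#' @param includedStatuses Moderation states to count.
#' @return data.frame with one row per variant: \code{variant},
#'   \code{n_items}, \code{variant_evidence_score}, ordered by variant
#'   key.
#' @export
scoreCorpus <- function(corpus, weights = defaultLevelWeights(),
                        includedStatuses =
                          defaultConfig()$included_statuses) {
  keys <- sort(names(corpus@variants), method = "radix")
  rows <- lapply(keys, function(k) {
    rep <- variantEvidenceScore(k, corpus, weights, includedStatuses)
    data.frame(variant = k, n_items = nrow(rep@perItem),
               variant_evidence_score = rep@variantScore,
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(variant = character(), n_items = integer(),
                      variant_evidence_score = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
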