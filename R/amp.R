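## AMP-ASCO-CAP 2017 tier/level assignment for somatic assertions
## (Predictive, Prognostic, Diagnostic).  The level mapping is one data
## table so an alternative minimal-evidence scheme can be dropped in.
##
## Decision procedure (deterministic):
##   Tier IV  — the asserted significance is benign-side
##              (Benign / Likely Benign); no level.
##   Tier III — evidence exists but there is no significance consensus:
##              no accepted supporting items, all counted items carry
##              significance N/A, or accepted items contradict each other
##              on the asserted significance (both directions present);
##              no level.
##   Otherwise the level comes from the accepted, Supports-direction
##   evidence: A when a regulatory anchor (FDA approval, companion test or
##   an NCCN guideline) is corroborated by a Level A item; B when a
##   Level B (or uncorroborated Level A) item exists; C/D from the best
##   remaining item (D also covers Level E, inferential-only support).
##   Tier I <=> Level A/B, Tier II <=> Level C/D.

#' The AMP level mapping table
#'
#' The documented mapping from accepted supporting evidence to the
#' AMP-ASCO-CAP Level, evaluated top to bottom.
#'
#' @return data.frame with columns \code{level}, \code{tier},
#'   \code{condition} (human-readable description of each row).
#' @export
ampLevelTable <- function() {
  data.frame(
    level = c("A", "B", "C", "D"),
    tier = c("I", "I", "II", "II"),
    condition = c(
      "regulatory anchor (FDA approval/companion test/NCCN) + accepted Level A evidence",
      "accepted Level B (or uncorroborated Level A) Supports evidence",
      "best accepted Supports evidence is Level C",
      "best accepted Supports evidence is Level D or E"
    ),
    stringsAsFactors = FALSE
  )
}

.benignSideSignificance <- function(config = defaultConfig()) {
  config$assertion_extra_significance
}

#' Assign an AMP-ASCO-CAP tier and level to a somatic assertion
#'
#' Applies the deterministic mapping in \code{\link{ampLevelTable}} to the
#' assertion's accepted supporting evidence items.  Only Supports-direction
#' items count toward the level; Does-not-support items on the asserted
#' significance count toward contradiction detection (Tier III).
#' Predisposing assertions are routed to \code{\link{combineAcmg}} instead
#' and raise an error here.
#'
#' @param assertion An \linkS4class{Assertion} of type Predictive,
#'   Prognostic or Diagnostic.
#' @param corpus The \linkS4class{Corpus} resolving the supporting
#'   evidence ids.
#' @param config Configuration list.
#' @return An \linkS4class{AmpAssignment} with the tier, level (tiers I/II
#'   only) and the rationale trail.
#' @examples
#' ## see the package vignette for a worked corpus example
#' @export
assignAmp <- function(assertion, corpus, config = defaultConfig()) {
  if (identical(assertion@assertionType, "Predisposing"))
    stop("type error: Predisposing assertions are classified with ",
         "combineAcmg(), not the somatic tier system")
  if (!assertion@assertionType %in%
      c("Predictive", "Prognostic", "Diagnostic"))
    stop("type error: unknown assertion type '",
         assertion@assertionType, "'")

  rationale <- character()
  items <- lapply(assertion@supportingEids,
                  function(e) corpus@evidenceItems[[e]])
  missing <- assertion@supportingEids[vapply(items, is.null, logical(1))]
  if (length(missing))
    rationale <- c(rationale,
                   paste0("unresolved evidence ids ignored: ",
                          paste(missing, collapse = ", ")))
  items <- Filter(Negate(is.null), items)
  accepted <- Filter(function(e) e@moderation@state == "accepted", items)

  ## Tier IV: benign-side asserted significance
  if (!is.na(assertion@clinicalSignificance) &&
      assertion@clinicalSignificance %in%
        .benignSideSignificance(config)) {
    rationale <- c(rationale,
                   paste0("asserted significance '",
                          assertion@clinicalSignificance,
                          "' is benign-side"))
    return(new("AmpAssignment", tier = "IV", level = NA_character_,
               rationale = rationale))
  }

  supports <- Filter(function(e)
    identical(e@evidenceDirection, "Supports"), accepted)
  contra <- Filter(function(e)
    identical(e@evidenceDirection, "Does not support") &&
      identical(e@clinicalSignificance, assertion@clinicalSignificance),
    accepted)

  ## Tier III: evidence without significance consensus
  if (!length(accepted)) {
    rationale <- c(rationale, "no accepted supporting evidence")
    return(new("AmpAssignment", tier = "III", level = NA_character_,
               rationale = rationale))
  }
  allNA <- all(vapply(accepted, function(e)
    identical(e@clinicalSignificance, "N/A"), logical(1)))
  if (allNA) {
    rationale <- c(rationale,
                   "all counted evidence has significance N/A")
    return(new("AmpAssignment", tier = "III", level = NA_character_,
               rationale = rationale))
  }
  if (length(supports) && length(contra)) {
    rationale <- c(rationale,
                   "contradictory directions on the asserted significance")
    return(new("AmpAssignment", tier = "III", level = NA_character_,
               rationale = rationale))
  }
  if (!length(supports)) {
    rationale <- c(rationale,
                   "no Supports-direction accepted evidence")
    return(new("AmpAssignment", tier = "III", level = NA_character_,
               rationale = rationale))
  }

  levels <- vapply(supports, function(e) e@evidenceLevel, character(1))
  eids <- vapply(supports, function(e) e@eid, character(1))
  anchor <- isTRUE(assertion@fdaRegulatoryApproval) ||
    isTRUE(assertion@fdaCompanionTest) || !is.na(assertion@nccnGuideline)

  if (anchor && any(levels == "A")) {
    lvl <- "A"
    rationale <- c(rationale,
                   paste0("regulatory/guideline anchor corroborated by ",
                          "Level A evidence: ",
                          paste(eids[levels == "A"], collapse = ", ")))
  } else if (any(levels %in% c("A", "B"))) {
    lvl <- "B"
    rationale <- c(rationale,
                   paste0("clinical evidence: ",
                          paste(eids[levels %in% c("A", "B")],
                                collapse = ", ")))
  } else if (any(levels == "C")) {
    lvl <- "C"
    rationale <- c(rationale,
                   paste0("best accepted evidence is case-study Level C: ",
                          paste(eids[levels == "C"], collapse = ", ")))
  } else {
    lvl <- "D"
    rationale <- c(rationale,
                   paste0("best accepted evidence is preclinical/",
                          "inferential: ", paste(eids, collapse = ", ")))
  }
  tier <- if (lvl %in% c("A", "B")) "I" else "II"
  new("AmpAssignment", tier = tier, level = lvl, rationale = rationale)
}
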