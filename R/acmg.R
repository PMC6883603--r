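## ACMG-AMP 2015 criteria combination.  The 28 evidence-code tokens carry a
## default strength from their prefix; an explicit "@strength" suffix
## overrides it (the ClinGen-style refinements).  After overrides the
## strength counts are matched against the combining table, which is kept
## as data so updated rule sets can be layered in.

.acmgTokens <- c(
  "PVS1",
  paste0("PS", 1:4),
  paste0("PM", 1:6),
  paste0("PP", 1:5),
  "BA1",
  paste0("BS", 1:4),
  paste0("BP", 1:7)
)

#' The 28 ACMG evidence-code tokens
#'
#' Pathogenic side: PVS1 (very strong), PS1-PS4 (strong), PM1-PM6
#' (moderate), PP1-PP5 (supporting).  Benign side: BA1 (stand-alone),
#' BS1-BS4 (strong), BP1-BP7 (supporting).
#'
#' @return Character vector of the 28 tokens.
#' @export
acmgCodeTokens <- function() .acmgTokens

.acmgDefaultStrength <- function(token) {
  pre <- sub("[0-9]+$", "", token)
  switch(pre,
         PVS = "very_strong", PS = "strong", PM = "moderate",
         PP = "supporting",
         BA = "standalone", BS = "strong", BP = "supporting",
         stop("domain error: unknown ACMG token ", token))
}

.acmgSide <- function(token) {
  if (grepl("^(PVS|PS|PM|PP)", token)) "pathogenic" else "benign"
}

.acmgTokenValid <- function(code) {
  tok <- sub("@.*$", "", code)
  tok %in% .acmgTokens
}

#' Parse ACMG codes with optional strength overrides
#'
#' Codes are written \code{"TOKEN"} or \code{"TOKEN@strength"}, e.g.
#' \code{"PVS1"}, \code{"PS1@moderate"}.  Pathogenic-side strengths:
#' \code{very_strong}, \code{strong}, \code{moderate}, \code{supporting};
#' benign-side: \code{standalone}, \code{strong}, \code{supporting}.
#' Overrides never move a code across sides.
#'
#' @param codes Character vector of code strings.
#' @return data.frame with columns \code{token}, \code{side},
#'   \code{strength}.
#' @examples
#' parseAcmgCodes(c("PVS1", "PS1@moderate"))
#' @export
parseAcmgCodes <- function(codes) {
  toks <- sub("@.*$", "", codes)
  ovr <- ifelse(grepl("@", codes), sub("^[^@]*@", "", codes), NA)
  bad <- setdiff(toks, .acmgTokens)
  if (length(bad))
    stop("domain error: unknown ACMG token(s): ",
         paste(bad, collapse = ", "))
  if (anyDuplicated(toks))
    stop("domain error: duplicate ACMG token(s): ",
         paste(unique(toks[duplicated(toks)]), collapse = ", "))
  side <- vapply(toks, .acmgSide, character(1))
  strength <- vapply(seq_along(toks), function(i) {
    if (is.na(ovr[i])) return(.acmgDefaultStrength(toks[i]))
    allowed <- if (side[i] == "pathogenic")
      c("very_strong", "strong", "moderate", "supporting")
    else c("standalone", "strong", "supporting")
    if (!ovr[i] %in% allowed)
      stop("domain error: strength '", ovr[i], "' not allowed for ",
           toks[i])
    ovr[i]
  }, character(1))
  data.frame(token = toks, side = side, strength = strength,
             stringsAsFactors = FALSE, row.names = NULL)
}

## Combining table: each row is a minimum-count requirement over the
## strength tally (vs = very strong, s = strong, m = moderate,
## p = supporting, ba = stand-alone benign, bs = strong benign,
## bp = supporting benign).  Classification rows are tried strongest
## first; within a classification any row matching fires.
.acmgCombiningRows <- function() {
  r <- function(id, class, vs = 0, s = 0, m = 0, p = 0, ba = 0, bs = 0,
                bp = 0, description)
    data.frame(rule_id = id, class = class, vs = vs, s = s, m = m, p = p,
               ba = ba, bs = bs, bp = bp, description = description,
               stringsAsFactors = FALSE)
  rbind(
    r("P1a", "Pathogenic", vs = 1, s = 1,
      description = "1 very strong + >=1 strong"),
    r("P1b", "Pathogenic", vs = 1, m = 2,
      description = "1 very strong + >=2 moderate"),
    r("P1c", "Pathogenic", vs = 1, m = 1, p = 1,
      description = "1 very strong + 1 moderate + 1 supporting"),
    r("P1d", "Pathogenic", vs = 1, p = 2,
      description = "1 very strong + >=2 supporting"),
    r("P2",  "Pathogenic", s = 2, description = ">=2 strong"),
    r("P3a", "Pathogenic", s = 1, m = 3,
      description = "1 strong + >=3 moderate"),
    r("P3b", "Pathogenic", s = 1, m = 2, p = 2,
      description = "1 strong + 2 moderate + >=2 supporting"),
    r("P3c", "Pathogenic", s = 1, m = 1, p = 4,
      description = "1 strong + 1 moderate + >=4 supporting"),
    r("LP1", "Likely Pathogenic", vs = 1, m = 1,
      description = "1 very strong + 1 moderate"),
    r("LP2", "Likely Pathogenic", s = 1, m = 1,
      description = "1 strong + 1-2 moderate"),
    r("LP3", "Likely Pathogenic", s = 1, p = 2,
      description = "1 strong + >=2 supporting"),
    r("LP4", "Likely Pathogenic", m = 3, description = ">=3 moderate"),
    r("LP5", "Likely Pathogenic", m = 2, p = 2,
      description = "2 moderate + >=2 supporting"),
    r("LP6", "Likely Pathogenic", m = 1, p = 4,
      description = "1 moderate + >=4 supporting"),
    r("B1", "Benign", ba = 1, description = "1 stand-alone (BA1)"),
    r("B2", "Benign", bs = 2, description = ">=2 strong benign"),
    r("LB1", "Likely Benign", bs = 1, bp = 1,
      description = "1 strong benign + 1 supporting benign"),
    r("LB2", "Likely Benign", bp = 2,
      description = ">=2 supporting benign")
  )
}

#' The ACMG-AMP combining table
#'
#' The criteria-combination rules encoded as minimum strength counts.
#' Each row fires when the tally of (possibly overridden) code strengths
#' meets all of its minima; a set classifies at the strongest
#' classification with a firing row.
#'
#' @return data.frame of rule rows (rule_id, class, count minima,
#'   description).
#' @export
acmgCombiningTable <- function() .acmgCombiningRows()

#' Combine ACMG evidence codes into a five-tier classification
#'
#' Tallies the codes (after strength overrides) and evaluates the
#' combining table: pathogenic rows, then likely-pathogenic rows on the
#' pathogenic-side tally; benign and likely-benign rows on the benign-side
#' tally.  When one side reaches a classification while the set also
#' carries codes from the opposite side — or both sides classify — the
#' evidence is contradictory: the result is VUS with \code{conflict=TRUE}
#' and the firing rows of both sides retained.  A set firing nothing is
#' VUS.
#'
#' @param codes Character vector of ACMG code strings
#'   (\code{"TOKEN"} or \code{"TOKEN@strength"}); at most one occurrence
#'   of each token, unknown tokens are an error.
#' @param table Combining table (see \code{\link{acmgCombiningTable}}).
#' @return An \linkS4class{AcmgClassification}.
#' @examples
#' combineAcmg(c("PVS1", "PS1"))          # Pathogenic
#' combineAcmg(c("PS1", "PM1", "PM2"))    # Likely Pathogenic
#' combineAcmg(c("BA1", "PVS1"))          # VUS, conflicting
#' @export
combineAcmg <- function(codes = character(),
                        table = acmgCombiningTable()) {
  parsed <- parseAcmgCodes(codes)
  st <- parsed$strength
  pa <- parsed$side == "pathogenic"
  tally <- c(vs = sum(pa & st == "very_strong"),
             s = sum(pa & st == "strong"),
             m = sum(pa & st == "moderate"),
             p = sum(pa & st == "supporting"),
             ba = sum(!pa & st == "standalone"),
             bs = sum(!pa & st == "strong"),
             bp = sum(!pa & st == "supporting"))

  fires <- vapply(seq_len(nrow(table)), function(i) {
    row <- table[i, ]
    tally[["vs"]] >= row$vs && tally[["s"]] >= row$s &&
      tally[["m"]] >= row$m && tally[["p"]] >= row$p &&
      tally[["ba"]] >= row$ba && tally[["bs"]] >= row$bs &&
      tally[["bp"]] >= row$bp
  }, logical(1))
  fired <- table[fires, , drop = FALSE]

  pathClass <- if (any(fired$class == "Pathogenic")) "Pathogenic"
    else if (any(fired$class == "Likely Pathogenic")) "Likely Pathogenic"
    else NA_character_
  benignClass <- if (any(fired$class == "Benign")) "Benign"
    else if (any(fired$class == "Likely Benign")) "Likely Benign"
    else NA_character_

  firedIds <- fired$rule_id[fired$class %in%
    c(pathClass, benignClass)[!is.na(c(pathClass, benignClass))]]
  anyPath <- any(pa)
  anyBenign <- any(!pa)

  conflict <- (!is.na(pathClass) && !is.na(benignClass)) ||
    (!is.na(pathClass) && anyBenign) ||
    (!is.na(benignClass) && anyPath)

  value <- if (conflict) "VUS"
    else if (!is.na(pathClass)) pathClass
    else if (!is.na(benignClass)) benignClass
    else "VUS"

  new("AcmgClassification", value = value,
      firedRules = as.character(firedIds), conflict = conflict)
}
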