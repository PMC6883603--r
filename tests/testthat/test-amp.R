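# corpus with one variant and controllable accepted evidence levels
ampCorpus <- function(levels, directions = NULL, significances = NULL) {
  corpus <- emptyCorpus()
  corpus <- registerActor(corpus, "cur1", "Curator")
  corpus <- registerActor(corpus, "ed1", "Editor", "2019-06-01")
  for (i in seq_along(levels)) {
    it <- compliantEid(sprintf("EID%d", i))
    it@source@sourceId <- paste0("55", i)
    it@evidenceLevel <- levels[i]
    if (!is.null(directions)) it@evidenceDirection <- directions[i]
    if (!is.null(significances))
      it@clinicalSignificance <- significances[i]
    corpus <- submitEntity(corpus, it, "cur1")
    corpus <- acceptEntity(corpus, it@eid, "ed1")
  }
  corpus
}

ampAssertion <- function(corpus, type = "Predictive", fda = FALSE,
                         significance = "Sensitivity/Response") {
  Assertion("AID1", "EGFR", "L858R", "Somatic", "DOID:3910", type,
            "Supports", significance,
            drugs = if (type == "Predictive") "Gefitinib" else character(),
            fdaRegulatoryApproval = fda,
            supportingEids = names(corpusEvidence(corpus)))
}

test_that("regulatory-anchored Level A evidence gives Tier I Level A", {
  corpus <- ampCorpus("A")
  amp <- assignAmp(ampAssertion(corpus, fda = TRUE), corpus)
  expect_identical(ampTier(amp), "I")
  expect_identical(ampLevel(amp), "A")
})

test_that("case-study-only support gives Tier II Level C", {
  corpus <- ampCorpus(c("C", "C"))
  amp <- assignAmp(ampAssertion(corpus, type = "Prognostic",
                                significance = "Poor Outcome"), corpus)
  expect_identical(ampTier(amp), "II")
  expect_identical(ampLevel(amp), "C")
})

test_that("Predisposing assertions are routed to the ACMG engine", {
  corpus <- ampCorpus("B")
  a <- ampAssertion(corpus, type = "Predisposing", significance = "N/A")
  expect_error(assignAmp(a, corpus), "type error.*combineAcmg")
})

test_that("levels B and D/E map to their tiers; A without anchor drops to B", {
  corpus <- ampCorpus("B")
  amp <- assignAmp(ampAssertion(corpus), corpus)
  expect_identical(c(ampTier(amp), ampLevel(amp)), c("I", "B"))

  corpusDE <- ampCorpus(c("D", "E"))
  ampDE <- assignAmp(ampAssertion(corpusDE), corpusDE)
  expect_identical(c(ampTier(ampDE), ampLevel(ampDE)), c("II", "D"))

  corpusA <- ampCorpus("A")
  ampA <- assignAmp(ampAssertion(corpusA, fda = FALSE), corpusA)
  expect_identical(c(ampTier(ampA), ampLevel(ampA)), c("I", "B"))
})

test_that("no consensus yields Tier III without a level", {
  # all counted evidence N/A
  corpus <- ampCorpus(c("B", "B"), significances = c("N/A", "N/A"))
  amp <- assignAmp(ampAssertion(corpus), corpus)
  expect_identical(ampTier(amp), "III")
  expect_true(is.na(ampLevel(amp)))

  # contradictory directions on the asserted significance
  c2 <- ampCorpus(c("B", "B"), directions = c("Supports",
                                              "Does not support"))
  amp2 <- assignAmp(ampAssertion(c2), c2)
  expect_identical(ampTier(amp2), "III")

  # evidence exists but none of it accepted
  c3 <- emptyCorpus()
  c3 <- registerActor(c3, "cur1", "Curator")
  c3 <- submitEntity(c3, compliantEid("EID1"), "cur1")
  amp3 <- assignAmp(Assertion("AID1", "EGFR", "L858R", "Somatic",
                              "DOID:3910", "Predictive", "Supports",
                              "Sensitivity/Response", drugs = "Gefitinib",
                              supportingEids = "EID1"), c3)
  expect_identical(ampTier(amp3), "III")
})

test_that("benign-side asserted significance yields Tier IV", {
  corpus <- ampCorpus("B")
  amp <- assignAmp(ampAssertion(corpus, significance = "Likely Benign"),
                   corpus)
  expect_identical(ampTier(amp), "IV")
  expect_true(is.na(ampLevel(amp)))
})

test_that("a level is never emitted without tiers I/II, and upgrades never demote", {
  ord <- c(E = 1, D = 2, C = 3, B = 4, A = 5)
  tierRank <- c(III = 0, II = 1, I = 2)
  for (lvl in c("E", "D", "C", "B", "A")) {
    corpus <- ampCorpus(lvl)
    amp <- assignAmp(ampAssertion(corpus), corpus)
    if (ampTier(amp) %in% c("I", "II"))
      expect_false(is.na(ampLevel(amp)))
    else expect_true(is.na(ampLevel(amp)))
  }
  ranks <- vapply(c("E", "D", "C", "B", "A"), function(lvl) {
    corpus <- ampCorpus(lvl)
    tierRank[[ampTier(assignAmp(ampAssertion(corpus), corpus))]]
  }, numeric(1))
  expect_true(all(diff(ranks) >= 0))
})
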