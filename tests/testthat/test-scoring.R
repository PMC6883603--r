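test_that("evidence item scores follow stars times level weight", {
  expect_identical(evidenceItemScore(1, "A"), 10)
  expect_identical(evidenceItemScore(3, "B"), 15)
  expect_identical(evidenceItemScore(5, "E"), 2.5)
  expect_identical(evidenceItemScore(compliantEid()), 20)  # 4 stars x B=5
  expect_error(evidenceItemScore(0, "A"), "domain error")
  expect_error(evidenceItemScore(6, "A"), "domain error")
  expect_error(evidenceItemScore(3, "F"), "domain error")
  expect_error(evidenceItemScore(2, "A", c(A = 10)), "domain error")
})

test_that("weights are configuration with enforced ordering constraints", {
  w <- defaultLevelWeights()
  expect_identical(unname(w[c("A", "B", "C", "D", "E")]),
                   c(10, 5, 3, 1, 0.5))
  expect_true(all(diff(unname(w[c("A", "B", "C", "D", "E")])) < 0))
  alt <- c(A = 8, B = 4, C = 2, D = 1, E = 0.5)
  expect_identical(evidenceItemScore(2, "A", alt), 16)
})

test_that("variant scores sum accepted items and ignore direction", {
  corpus <- emptyCorpus()
  corpus <- registerActor(corpus, "cur1", "Curator")
  corpus <- registerActor(corpus, "ed1", "Editor", "2019-06-01")

  # empty evidence set scores zero
  corpus <- submitEntity(corpus,
                         VariantRecord("EGFR", "L858R",
                                       variantTypes = "SO:0001583"),
                         "cur1")
  rep0 <- variantEvidenceScore("EGFR::L858R", corpus)
  expect_identical(variantScore(rep0), 0)

  mk <- function(eid, rating, level, dir = "Supports") {
    it <- compliantEid(eid)
    it@source@sourceId <- paste0("90", eid)
    it@evidenceRating <- as.integer(rating)
    it@evidenceLevel <- level
    it@evidenceDirection <- dir
    it
  }
  corpus <- submitEntity(corpus, mk("EIDA", 1, "A"), "cur1")
  corpus <- submitEntity(corpus, mk("EIDB", 3, "B"), "cur1")
  corpus <- acceptEntity(corpus, "EIDA", "ed1")
  corpus <- acceptEntity(corpus, "EIDB", "ed1")
  rep <- variantEvidenceScore("EGFR::L858R", corpus)
  expect_identical(variantScore(rep), 25)   # 10 + 15
  expect_identical(sum(perItemScores(rep)$score), variantScore(rep))

  # opposing directions add up, they do not cancel
  c2 <- emptyCorpus()
  c2 <- registerActor(c2, "cur1", "Curator")
  c2 <- registerActor(c2, "ed1", "Editor", "2019-06-01")
  c2 <- submitEntity(c2, mk("EIDS", 2, "B", "Supports"), "cur1")
  c2 <- submitEntity(c2, mk("EIDN", 2, "B", "Does not support"), "cur1")
  c2 <- acceptEntity(c2, "EIDS", "ed1")
  c2 <- acceptEntity(c2, "EIDN", "ed1")
  expect_identical(variantScore(variantEvidenceScore("EGFR::L858R", c2)),
                   20)
})

test_that("only the configured moderation states count", {
  corpus <- miniCorpus()   # EID1 accepted (4xB=20), EID2 submitted (4xA=40)
  expect_identical(variantScore(variantEvidenceScore("EGFR::L858R",
                                                     corpus)), 20)
  both <- variantEvidenceScore("EGFR::L858R", corpus,
                               includedStatuses = c("accepted",
                                                    "submitted"))
  expect_identical(variantScore(both), 60)
})

test_that("appending an item raises the variant score by exactly its score", {
  set.seed(42)
  corpus <- miniCorpus()
  for (i in 1:10) {
    before <- variantScore(variantEvidenceScore("EGFR::L858R", corpus))
    rating <- sample(1:5, 1)
    level <- sample(c("A", "B", "C", "D", "E"), 1)
    it <- compliantEid(paste0("EIDX", i))
    it@source@sourceId <- paste0("7", i)
    it@evidenceRating <- as.integer(rating)
    it@evidenceLevel <- level
    corpus <- submitEntity(corpus, it, "cur1")
    corpus <- acceptEntity(corpus, it@eid, "ed1")
    after <- variantScore(variantEvidenceScore("EGFR::L858R", corpus))
    expect_identical(after - before, evidenceItemScore(rating, level))
  }
})

test_that("scores are monotone in rating and follow weight order in level", {
  w <- defaultLevelWeights()
  for (lvl in names(w))
    expect_true(all(diff(vapply(1:5, evidenceItemScore, numeric(1),
                                level = lvl)) > 0))
  for (r in 1:5) {
    byLevel <- vapply(c("A", "B", "C", "D", "E"), evidenceItemScore,
                      numeric(1), rating = r)
    expect_true(all(diff(byLevel) < 0))
  }
})

test_that("scores serialize with at most one decimal place under defaults", {
  corpus <- generateCorpus(generatorConfig(seed = 13, nEids = 30))
  tab <- scoreCorpus(corpus)
  expect_true(all(tab$variant_evidence_score * 2 ==
                    round(tab$variant_evidence_score * 2)))
  txt <- format(tab$variant_evidence_score, trim = TRUE)
  expect_true(all(!grepl("\\.[0-9]{2,}", txt)))
})
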