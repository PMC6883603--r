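test_that("submitting an evidence item auto-creates its gene and variant", {
  corpus <- emptyCorpus()
  corpus <- submitEntity(corpus, compliantEid("EID1"), "cur1")
  expect_true("EGFR" %in% names(corpusGenes(corpus)))
  expect_true("EGFR::L858R" %in% names(corpusVariants(corpus)))
  expect_identical(moderationState(corpusEvidence(corpus)$EID1),
                   "submitted")
  # unregistered submitters are treated as curators and cannot accept
  corpus <- registerActor(corpus, "ed1", "Editor", "2019-06-01")
  expect_error(acceptEntity(corpus, "EID1", "nobody"), "authorization")
})

test_that("identical pending resubmissions raise a duplicate warning", {
  corpus <- emptyCorpus()
  corpus <- submitEntity(corpus, compliantEid("EID1"), "cur1")
  dup <- compliantEid("EID2")
  expect_warning(submitEntity(corpus, dup, "cur2"), "duplicate")
  different <- compliantEid("EID3")
  different@source@sourceId <- "123456"
  expect_no_warning(submitEntity(corpus, different, "cur2"))
})

test_that("acceptance needs an editor with valid COI, never the submitter", {
  corpus <- miniCorpus()
  expect_identical(moderationState(corpusEvidence(corpus)$EID1),
                   "accepted")
  expect_identical(corpusEvidence(corpus)$EID1@moderation@decidedBy,
                   "ed1")

  # curators cannot accept
  expect_error(acceptEntity(corpus, "EID2", "cur1"), "authorization")

  # editors cannot accept their own submissions
  c2 <- emptyCorpus()
  c2 <- registerActor(c2, "ed1", "Editor", "2019-06-01")
  c2 <- submitEntity(c2, compliantEid("EID9"), "ed1")
  expect_error(acceptEntity(c2, "EID9", "ed1"), "self-acceptance")

  # expired or missing COI blocks acceptance
  c3 <- emptyCorpus()
  c3 <- registerActor(c3, "ed2", "Editor", "2018-01-01")  # stale
  c3 <- registerActor(c3, "ed3", "Editor")                # none
  c3 <- submitEntity(c3, compliantEid("EID8"), "cur1")
  expect_error(acceptEntity(c3, "EID8", "ed2"), "conflict-of-interest")
  expect_error(acceptEntity(c3, "EID8", "ed3"), "conflict-of-interest")
})

test_that("assertions cannot be accepted without an accepted evidence item", {
  corpus <- emptyCorpus()
  corpus <- registerActor(corpus, "ed1", "Editor", "2019-06-01")
  corpus <- submitEntity(corpus, compliantEid("EID1"), "cur1")
  a <- Assertion("AID1", "EGFR", "L858R", "Somatic", "DOID:3910",
                 "Predictive", "Supports", "Sensitivity/Response",
                 drugs = "Gefitinib", supportingEids = "EID1")
  corpus <- submitEntity(corpus, a, "cur1")
  expect_error(acceptEntity(corpus, "AID1", "ed1"), "gate error")
  corpus <- acceptEntity(corpus, "EID1", "ed1")
  corpus <- acceptEntity(corpus, "AID1", "ed1")
  expect_identical(moderationState(corpusAssertions(corpus)$AID1),
                   "accepted")
})

test_that("rejection permissions and the mandatory comment are enforced", {
  corpus <- miniCorpus()
  # submitter may reject their own pending item
  c2 <- rejectEntity(corpus, "EID2", "cur2", "withdrawn by submitter")
  expect_identical(moderationState(corpusEvidence(c2)$EID2), "rejected")
  # an unrelated curator may not
  expect_error(rejectEntity(corpus, "EID2", "cur1"), "comment-required")
  expect_error(rejectEntity(corpus, "EID2", "cur1", "nope"),
               "authorization")
  # a comment is mandatory even for editors
  expect_error(rejectEntity(corpus, "EID2", "ed1", "  "),
               "comment-required")
})

test_that("rejecting the last accepted evidence item demotes and flags the assertion", {
  corpus <- miniCorpus()
  a <- Assertion("AID1", "EGFR", "L858R", "Somatic", "DOID:3910",
                 "Predictive", "Supports", "Sensitivity/Response",
                 drugs = "Gefitinib", supportingEids = c("EID1", "EID2"))
  corpus <- submitEntity(corpus, a, "cur1")
  corpus <- acceptEntity(corpus, "AID1", "ed1")
  corpus <- rejectEntity(corpus, "EID1", "ed1", "retracted study")
  demoted <- corpusAssertions(corpus)$AID1
  expect_identical(moderationState(demoted), "submitted")
  expect_true(isFlagged(demoted))
  # the corpus-wide gate invariant holds afterwards
  for (x in corpusAssertions(corpus))
    if (moderationState(x) == "accepted")
      expect_true(any(vapply(x@supportingEids, function(e)
        moderationState(corpusEvidence(corpus)[[e]]) == "accepted",
        logical(1))))
})

test_that("revisions queue with a mandatory comment and apply on acceptance", {
  corpus <- miniCorpus()
  expect_error(proposeRevision(corpus, "EID1", "evidence_level", "B", "",
                               "cur2"), "comment-required")
  corpus <- proposeRevision(corpus, "EID1", "evidence_level", "C",
                            "level overstated for a case series", "cur2")
  # entity unchanged until an editor accepts
  expect_identical(corpusEvidence(corpus)$EID1@evidenceLevel, "B")
  expect_error(acceptRevision(corpus, "EID1", 1, "cur2"),
               "authorization")
  corpus <- acceptRevision(corpus, "EID1", 1, "ed1")
  expect_identical(corpusEvidence(corpus)$EID1@evidenceLevel, "C")

  # an accepted revision can leave the record in violation, which the
  # validator then reports
  corpus <- proposeRevision(corpus, "EID1", "drugs", character(),
                            "drug attribution unclear", "cur2")
  corpus <- acceptRevision(corpus, "EID1", 2, "ed1")
  v <- validateEvidenceItem(corpusEvidence(corpus)$EID1, REG)
  expect_true("EID_DRUGS_REQUIRED" %in% v$rule_id)
})

test_that("flags are idempotent and resolved by editors with a comment", {
  corpus <- miniCorpus()
  corpus <- flagEntity(corpus, "EID1", "cur2", "dose seems inconsistent")
  corpus <- flagEntity(corpus, "EID1", "cur1")   # double-flag: no change
  expect_true(isFlagged(corpusEvidence(corpus)$EID1))
  expect_error(resolveFlag(corpus, "EID1", "cur1", "fixed"),
               "authorization")
  corpus <- resolveFlag(corpus, "EID1", "ed1", "statement corrected")
  expect_false(isFlagged(corpusEvidence(corpus)$EID1))
})

test_that("replaying the event log reproduces the corpus exactly", {
  corpus <- generateCorpus(generatorConfig(seed = 17, nEids = 15,
                                           violationRate = 0.2))
  rebuilt <- replayEvents(eventLog(corpus))
  f1 <- tempfile(); f2 <- tempfile()
  # compare canonical serializations of records + log
  rebuilt@extras <- corpus@extras   # generator scratch is not event-sourced
  writeCorpus(corpus, f1)
  writeCorpus(rebuilt, f2)
  expect_identical(readLines(f1), readLines(f2))

  # ndjson round trip of the log itself
  logPath <- tempfile(fileext = ".ndjson")
  writeEventLog(corpus, logPath)
  events <- readEventLog(logPath)
  expect_length(events, length(eventLog(corpus)))
  rebuilt2 <- replayEvents(events)
  expect_identical(names(corpusEvidence(rebuilt2)),
                   names(corpusEvidence(corpus)))
  expect_identical(
    vapply(corpusEvidence(rebuilt2), moderationState, character(1)),
    vapply(corpusEvidence(corpus), moderationState, character(1)))
})

test_that("random action streams never self-accept nor break the assertion gate", {
  set.seed(101)
  for (rep in 1:40) {     # deeper sweep lives in the acceptance suite
    corpus <- emptyCorpus()
    corpus <- registerActor(corpus, "ed1", "Editor", "2019-06-01")
    corpus <- registerActor(corpus, "ed2", "Editor", "2019-06-01")
    ppl <- c("cur1", "cur2", "ed1", "ed2")
    for (step in 1:12) {
      corpus <- tryCatch(randomLifecycleAction(corpus, ppl),
                         error = function(e) corpus)
    }
    checkLifecycleInvariants(corpus)
  }
})
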