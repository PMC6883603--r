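test_that("identical seed and config reproduce the corpus byte for byte", {
  f1 <- tempfile(); f2 <- tempfile()
  writeCorpus(generateCorpus(generatorConfig(seed = 7, nEids = 20,
                                             violationRate = 0.2)), f1)
  writeCorpus(generateCorpus(generatorConfig(seed = 7, nEids = 20,
                                             violationRate = 0.2)), f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed produces a different corpus
  f3 <- tempfile()
  writeCorpus(generateCorpus(generatorConfig(seed = 8, nEids = 20,
                                             violationRate = 0.2)), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("generated corpora span the model space and stay replayable", {
  corpus <- generateCorpus(generatorConfig(seed = 11, nEids = 60,
                                           nAssertions = 8))
  items <- corpusEvidence(corpus)
  types <- vapply(items, function(e) e@evidenceType, character(1))
  expect_setequal(unique(types),
                  c("Predictive", "Diagnostic", "Prognostic",
                    "Predisposing", "Functional"))
  states <- vapply(items, moderationState, character(1))
  expect_true(all(c("accepted", "submitted") %in% states))
  pred <- items[types == "Predictive"]
  expect_true(all(vapply(pred, function(e) length(e@drugs) >= 1,
                         logical(1))))
  multi <- Filter(function(e) length(e@drugs) > 1, pred)
  expect_true(all(vapply(multi, function(e)
    e@drugInteractionType %in% c("Combination", "Sequential",
                                 "Substitutes"), logical(1))))

  asrt <- corpusAssertions(corpus)
  atypes <- vapply(asrt, function(a) a@assertionType, character(1))
  expect_true("Predisposing" %in% atypes)
  expect_true(any(atypes != "Predisposing"))
  for (a in asrt) {
    if (a@assertionType == "Predisposing")
      expect_true(a@acmgClassification %in%
                    c("Pathogenic", "Likely Pathogenic", "VUS",
                      "Likely Benign", "Benign"))
    else expect_true(a@ampTier %in% c("I", "II", "III", "IV"))
  }
  checkLifecycleInvariants(corpus)
})

test_that("injected defects are recovered perfectly by the validator", {
  corpus <- generateCorpus(generatorConfig(seed = 19, nEids = 50,
                                           violationRate = 0.25))
  gt <- corpusExtras(corpus)$injected_defects
  v <- validateCorpus(corpus)
  expect_identical(nrow(gt), as.integer(floor(0.25 * 50)))
  expect_identical(nrow(v), nrow(gt))                 # no false positives
  got <- v[order(v$entity_ref), c("entity_ref", "rule_id")]
  want <- gt[order(gt$entity_ref), ]
  expect_identical(got$entity_ref, want$entity_ref)
  expect_identical(got$rule_id, want$rule_id)
})

test_that("a degenerate level/rating distribution makes scores predictable", {
  corpus <- generateCorpus(generatorConfig(
    seed = 23, nEids = 20, nAssertions = 0,
    levelDistribution = c(A = 0, B = 0, C = 0, D = 0, E = 1),
    ratingDistribution = c(1, 0, 0, 0, 0)))
  tab <- scoreCorpus(corpus, includedStatuses = c("accepted", "submitted",
                                                  "rejected"))
  expect_identical(tab$variant_evidence_score, 0.5 * tab$n_items)
})

test_that("generated contigs and indel fixtures feed the normalizer", {
  corpus <- generateCorpus(generatorConfig(seed = 29, nEids = 5))
  contigs <- unlist(corpusExtras(corpus)$contigs)
  expect_length(contigs, 3L)
  expect_true(all(grepl("^[ACGT]+$", contigs)))
  fx <- corpusExtras(corpus)$coordinate_fixtures
  expect_gt(nrow(fx), 0L)
  for (i in seq_len(nrow(fx))) {
    co <- GenomicCoordinates(fx$contig[i], fx$start[i], fx$stop[i],
                             fx$ref[i], fx$var[i])
    expect_identical(nrow(checkReference(co, contigs)), 0L)
    res <- leftShiftNormalize(co, contigs)
    expect_gte(shiftedBy(res), 1)     # fixtures sit inside repeat runs
  }
})
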