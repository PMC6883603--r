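test_that("canonical code sets classify as expected", {
  expect_identical(classificationValue(combineAcmg(character())), "VUS")
  expect_identical(classificationValue(combineAcmg(c("PVS1", "PS1"))),
                   "Pathogenic")
  expect_identical(classificationValue(combineAcmg(c("PS1", "PM1",
                                                     "PM2"))),
                   "Likely Pathogenic")
  expect_identical(classificationValue(combineAcmg("BA1")), "Benign")
  mixed <- combineAcmg(c("BA1", "PVS1"))
  expect_identical(classificationValue(mixed), "VUS")
  expect_true(hasConflict(mixed))
  expect_identical(classificationValue(combineAcmg(c("BS1", "BP1"))),
                   "Likely Benign")
  expect_identical(classificationValue(combineAcmg(c("BP1", "BP4"))),
                   "Likely Benign")
  expect_identical(classificationValue(combineAcmg(c("PM1", "PP1"))),
                   "VUS")
})

test_that("token parsing enforces the vocabulary and strength overrides", {
  expect_length(acmgCodeTokens(), 28L)
  p <- parseAcmgCodes(c("PVS1", "PS1@moderate", "BS2@supporting"))
  expect_identical(p$strength, c("very_strong", "moderate", "supporting"))
  expect_error(combineAcmg(c("PVS1", "PVS1")), "duplicate")
  expect_error(combineAcmg("PX9"), "unknown")
  expect_error(parseAcmgCodes("PS1@standalone"), "not allowed")
})

test_that("strength overrides change the combining outcome", {
  # PVS1 downgraded to strong: {PVS1@strong, PS1} is two strongs
  res <- combineAcmg(c("PVS1@strong", "PS1"))
  expect_identical(classificationValue(res), "Pathogenic")
  expect_true("P2" %in% firedRules(res))
  # a lone strong + one moderate only reaches Likely Pathogenic
  expect_identical(classificationValue(combineAcmg(c("PS1@moderate",
                                                     "PM1", "PM2"))),
                   "Likely Pathogenic")
})

test_that("benign-only sets never classify pathogenic and vice versa", {
  ben <- c("BA1", "BS1", "BS2", "BP1", "BP2")
  path <- c("PVS1", "PS1", "PM1", "PM2", "PP1", "PP2")
  set.seed(21)
  for (i in 1:50) {
    b <- sample(ben, sample(1:4, 1))
    expect_false(classificationValue(combineAcmg(b)) %in%
                   c("Pathogenic", "Likely Pathogenic"))
    p <- sample(path, sample(1:5, 1))
    expect_false(classificationValue(combineAcmg(p)) %in%
                   c("Benign", "Likely Benign"))
  }
})

test_that("adding pathogenic codes never lowers a conflict-free classification", {
  rank <- c(VUS = 0, `Likely Pathogenic` = 1, Pathogenic = 2)
  pathCodes <- grep("^(PVS|PS|PM|PP)", acmgCodeTokens(), value = TRUE)
  set.seed(33)
  for (i in 1:100) {
    base <- sample(pathCodes, sample(0:4, 1))
    extra <- sample(setdiff(pathCodes, base), 1)
    r1 <- rank[[classificationValue(combineAcmg(base))]]
    r2 <- rank[[classificationValue(combineAcmg(c(base, extra)))]]
    expect_gte(r2, r1)
  }
})

test_that("the combiner agrees with the literal rule-table oracle on sampled sets", {
  # the exhaustive <=4-code sweep lives in the acceptance suite; here a
  # randomised cross-check including strength overrides
  toks <- acmgCodeTokens()
  set.seed(8)
  for (i in 1:300) {
    codes <- sample(toks, sample(0:6, 1))
    if (length(codes) && runif(1) < 0.3) {
      j <- sample(seq_along(codes), 1)
      side <- grepl("^(PVS|PS|PM|PP)", codes[j])
      codes[j] <- paste0(codes[j], "@",
                         if (side) sample(c("very_strong", "strong",
                                            "moderate", "supporting"), 1)
                         else sample(c("strong", "supporting"), 1))
    }
    got <- combineAcmg(codes)
    want <- oracleAcmg(codes)
    expect_identical(classificationValue(got), want$value,
                     info = paste(codes, collapse = ","))
    expect_identical(hasConflict(got), want$conflict,
                     info = paste(codes, collapse = ","))
  }
})
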