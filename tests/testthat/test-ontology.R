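test_that("a disease chain supports ancestor queries across levels", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("term_id\tname\tparent_ids\tontology_key",
               "DOID:162\tcancer\t\tdisease",
               "DOID:1324\tlung cancer\tDOID:162\tdisease",
               "DOID:3910\tlung adenocarcinoma\tDOID:1324\tdisease"), tsv)
  reg <- loadOntology(tsv, "disease")
  expect_true(isDescendant("DOID:3910", "DOID:162", reg))
  expect_true(isDescendant("DOID:3910", "DOID:1324", reg))
  expect_false(isDescendant("DOID:162", "DOID:3910", reg))
  expect_identical(termName(reg, "DOID:1324"), "lung cancer")
  expect_identical(termByName(reg, "lung adenocarcinoma"), "DOID:3910")
})

test_that("an empty term table yields an empty registry where all lookups miss", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines("term_id\tname\tparent_ids\tontology_key", tsv)
  reg <- loadOntology(tsv, "disease")
  expect_identical(nrow(reg@terms), 0L)
  expect_false(termExists(reg, "DOID:162"))
  expect_error(ancestorsOf("DOID:162", reg), "lookup error")
})

test_that("multi-parent terms report both ancestor paths", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("term_id\tname\tparent_ids\tontology_key",
               "X:1\troot\t\tsequence",
               "X:2\tleft\tX:1\tsequence",
               "X:3\tright\tX:1\tsequence",
               "X:4\tchild\tX:2|X:3\tsequence",
               "X:5\tleaf\tX:4\tsequence"), tsv)
  reg <- loadOntology(tsv, "sequence")
  expect_setequal(ancestorsOf("X:5", reg), c("X:1", "X:2", "X:3", "X:4"))
  expect_true(isDescendant("X:5", "X:2", reg))
  expect_true(isDescendant("X:5", "X:3", reg))
})

test_that("cyclic or malformed ontologies are rejected at load", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("term_id\tname\tparent_ids\tontology_key",
               "X:1\ta\tX:2\tsequence",
               "X:2\tb\tX:1\tsequence"), tsv)
  expect_error(loadOntology(tsv, "sequence"), "cyclic")

  dup <- tempfile(fileext = ".tsv")
  writeLines(c("term_id\tname\tparent_ids\tontology_key",
               "X:1\ta\t\tsequence",
               "X:1\tb\t\tsequence"), dup)
  expect_error(loadOntology(dup, "sequence"), "duplicate")

  dangling <- tempfile(fileext = ".tsv")
  writeLines(c("term_id\tname\tparent_ids\tontology_key",
               "X:1\ta\tX:9\tsequence"), dangling)
  expect_error(loadOntology(dangling, "sequence"), "not in registry")
})

test_that("descendant queries are irreflexive and match brute-force closure", {
  reg <- REG$sequence
  ids <- reg@terms$term_id
  for (a in ids) {
    expect_false(isDescendant(a, a, reg))
    expect_identical(ancestorsOf(a, reg), oracleAncestors(a, reg@parents))
  }
  # every ordered pair agrees with reachability in the closure
  for (a in ids) for (b in ids) {
    if (a == b) next
    expect_identical(isDescendant(a, b, reg),
                     b %in% oracleAncestors(a, reg@parents))
  }
  expect_true(isDescendant("SO:0001583", "SO:0001060", reg))
  expect_false(isDescendant("SO:0001060", "SO:0001583", reg))
})

test_that("minimal OBO files parse with is_a links and obsolete terms dropped", {
  obo <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: SO:0000001", "name: region", "",
               "[Term]", "id: SO:0000002",
               "name: child", "is_a: SO:0000001 ! region", "",
               "[Term]", "id: SO:0000003", "name: gone",
               "is_obsolete: true", "",
               "[Typedef]", "id: part_of"), obo)
  reg <- loadOntology(obo, "sequence")
  expect_setequal(reg@terms$term_id, c("SO:0000001", "SO:0000002"))
  expect_true(isDescendant("SO:0000002", "SO:0000001", reg))
  expect_false(termExists(reg, "SO:0000003"))
})
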