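FIX <- "GCATTTAC"

test_that("reference checking matches bases and insertion spans", {
  expect_identical(nrow(checkReference(
    GenomicCoordinates("c", 4, 4, "T", "A"), FIX)), 0L)
  v <- checkReference(GenomicCoordinates("c", 4, 4, "G", "A"), FIX)
  expect_identical(v$rule_id, "COORD_REF_MISMATCH")
  expect_error(checkReference(GenomicCoordinates("c", 99, 99, "A", "G"),
                              FIX), "range error")
  expect_identical(nrow(checkReference(
    GenomicCoordinates("c", 4, 5, "-", "GG"), FIX)), 0L)
  expect_identical(checkReference(
    GenomicCoordinates("c", 4, 6, "-", "GG"), FIX)$rule_id,
    "COORD_INSERTION_SPAN")
  expect_identical(checkReference(
    GenomicCoordinates("c", 4, 4, "-", "-"), FIX)$rule_id,
    "COORD_ALLELES_BLANK")
})

test_that("homopolymer deletions shift to the leftmost representation", {
  res <- leftShiftNormalize(GenomicCoordinates("c", 6, 6, "T", "-"), FIX)
  out <- normalizedCoordinates(res)
  expect_identical(c(out@start, out@stop), c(4, 4))
  expect_identical(c(out@referenceBase, out@variantBase), c("T", "-"))
  expect_identical(shiftedBy(res), 2)
})

test_that("SNVs pass through unchanged", {
  res <- leftShiftNormalize(GenomicCoordinates("c", 3, 3, "A", "G"), FIX)
  out <- normalizedCoordinates(res)
  expect_identical(c(out@start, out@stop, out@referenceBase,
                     out@variantBase), c("3", "3", "A", "G"))
  expect_identical(shiftedBy(res), 0)
  expect_false(res@trimmed)
})

test_that("untrimmed alleles are trimmed before shifting", {
  res <- leftShiftNormalize(GenomicCoordinates("c", 5, 6, "TT", "T"), FIX)
  out <- normalizedCoordinates(res)
  expect_identical(c(out@start, out@stop, out@referenceBase,
                     out@variantBase), c("4", "4", "T", "-"))
  expect_true(res@trimmed)
  # sequence-application oracle: both representations mean the same edit
  expect_identical(oracleApply(FIX, 5, 6, "TT", "T"),
                   oracleApply(FIX, 4, 4, "T", "-"))
})

test_that("no-op variants are a degenerate-variant error", {
  expect_error(leftShiftNormalize(GenomicCoordinates("c", 4, 4, "T", "T"),
                                  FIX), "degenerate")
})

test_that("normalization is idempotent and equivalence-preserving", {
  set.seed(99)
  for (i in 1:200) {
    case <- randomIndelCase()
    res <- leftShiftNormalize(case$coords, case$contig)
    out <- normalizedCoordinates(res)
    # idempotent
    res2 <- leftShiftNormalize(out, case$contig)
    out2 <- normalizedCoordinates(res2)
    expect_identical(
      c(out@start, out@stop, out@referenceBase, out@variantBase),
      c(out2@start, out2@stop, out2@referenceBase, out2@variantBase))
    expect_identical(shiftedBy(res2), 0)
    # equivalent under string application
    cin <- case$coords
    expect_identical(
      oracleApply(case$contig, cin@start, cin@stop, cin@referenceBase,
                  cin@variantBase),
      oracleApply(case$contig, out@start, out@stop, out@referenceBase,
                  out@variantBase))
  }
})

test_that("normalized indels are leftmost: shifting one base further breaks equivalence", {
  set.seed(7)
  for (i in 1:60) {
    case <- randomIndelCase()
    out <- normalizedCoordinates(leftShiftNormalize(case$coords,
                                                    case$contig))
    target <- oracleApply(case$contig, out@start, out@stop,
                          out@referenceBase, out@variantBase)
    if (out@start <= 1) next
    shifted <- GenomicCoordinates(out@chromosome, out@start - 1,
                                  out@stop - 1,
                                  if (out@referenceBase == "-") "-"
                                  else substr(case$contig, out@start - 1,
                                              out@stop - 1),
                                  out@variantBase)
    applied <- oracleApply(case$contig, shifted@start, shifted@stop,
                           shifted@referenceBase, shifted@variantBase)
    expect_false(identical(applied, target))
  }
})

test_that("repeat-region fixtures match the exhaustive leftmost oracle", {
  contigs <- c(hp = "AATTTTTTGC", di = "GACACACACATT", FIX = FIX)
  cases <- list(
    list(ctg = "hp", coords = GenomicCoordinates("hp", 7, 7, "T", "-")),
    list(ctg = "hp", coords = GenomicCoordinates("hp", 8, 9, "-", "T")),
    list(ctg = "di", coords = GenomicCoordinates("di", 7, 8, "CA", "-")),
    list(ctg = "di", coords = GenomicCoordinates("di", 9, 10, "-", "AC")),
    list(ctg = "FIX", coords = GenomicCoordinates("FIX", 6, 6, "T", "-")))
  for (case in cases) {
    ctg <- contigs[[case$ctg]]
    out <- normalizedCoordinates(leftShiftNormalize(case$coords, ctg))
    target <- oracleApply(ctg, case$coords@start, case$coords@stop,
                          case$coords@referenceBase,
                          case$coords@variantBase)
    lenDiff <- abs(nchar(target) - nchar(ctg))
    expect_identical(out@start,
                     as.numeric(oracleLeftmostStart(ctg, target,
                                                    maxLen = max(1, lenDiff))),
                     info = paste(case$ctg, case$coords@start))
  }
})

test_that("FASTA contigs load by name and feed the coordinate tools", {
  fa <- system.file("extdata", "example_ref.fa", package = "varcurate")
  contigs <- readReferenceFasta(fa)
  expect_identical(contigs[["toy1"]], "GCATTTAC")
  expect_identical(nrow(checkReference(
    GenomicCoordinates("TOY1", 4, 4, "T", "A"), contigs)), 0L)
  ## extending the AT repeat of toy2 left-shifts to before the first unit
  res <- leftShiftNormalize(GenomicCoordinates("toy2", 12, 13, "-", "AT"),
                            contigs)
  expect_identical(normalizedCoordinates(res)@start, 3)
})

test_that("padded output anchors indels VCF-style", {
  padded <- asPaddedAllele(GenomicCoordinates("c", 4, 4, "T", "-"), FIX)
  expect_identical(padded, list(chrom = "c", pos = 3, ref = "AT",
                                alt = "A"))
  snv <- asPaddedAllele(GenomicCoordinates("c", 3, 3, "A", "G"), FIX)
  expect_identical(snv$pos, 3)
  expect_identical(c(snv$ref, snv$alt), c("A", "G"))
})

test_that("coordinate strings parse into coordinate objects", {
  co <- parseCoordinateString("toy1:5-6:TT>T")
  expect_identical(c(co@chromosome, co@referenceBase, co@variantBase),
                   c("toy1", "TT", "T"))
  expect_identical(c(co@start, co@stop), c(5, 6))
  expect_error(parseCoordinateString("nonsense"), "cannot parse")
})
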