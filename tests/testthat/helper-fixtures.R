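# Shared fixtures, built in code.

REG <- bundledRegistries()

# fully SOP-compliant Predictive evidence item with one drug
compliantEid <- function(eid = "EID1") {
  EvidenceItem(
    eid = eid, geneSymbol = "EGFR", variantName = "L858R",
    source = SourceRef("PubMed", "15118073",
                       "Paez et al., 2004"),
    variantOrigin = "Somatic", diseaseDoid = "DOID:3910",
    evidenceStatement =
      "EGFR L858R tumours respond to gefitinib in lung adenocarcinoma.",
    evidenceType = "Predictive", evidenceLevel = "B",
    evidenceDirection = "Supports",
    clinicalSignificance = "Sensitivity/Response",
    evidenceRating = 4L, drugs = "Gefitinib")
}

# blank one required field of a compliant item
ablateField <- function(item, field) {
  switch(field,
    gene_symbol = { item@geneSymbol <- NA_character_ },
    variant_name = { item@variantName <- NA_character_ },
    source_type = { item@source@sourceType <- NA_character_ },
    source_id = { item@source@sourceId <- NA_character_ },
    variant_origin = { item@variantOrigin <- NA_character_ },
    disease = { item@diseaseDoid <- NA_character_ },
    evidence_statement = { item@evidenceStatement <- NA_character_ },
    evidence_type = { item@evidenceType <- NA_character_ },
    evidence_level = { item@evidenceLevel <- NA_character_ },
    evidence_direction = { item@evidenceDirection <- NA_character_ },
    clinical_significance = { item@clinicalSignificance <- NA_character_ },
    evidence_rating = { item@evidenceRating <- NA_integer_ },
    stop("unknown field ", field))
  item
}

# small corpus built through the lifecycle: one editor, two curators,
# a variant with accepted + submitted evidence
miniCorpus <- function() {
  corpus <- emptyCorpus()
  corpus <- registerActor(corpus, "cur1", "Curator")
  corpus <- registerActor(corpus, "cur2", "Curator")
  corpus <- registerActor(corpus, "ed1", "Editor", "2019-06-01")
  corpus <- submitEntity(corpus, compliantEid("EID1"), "cur1")
  e2 <- compliantEid("EID2")
  e2@source@sourceId <- "20979469"
  e2@evidenceLevel <- "A"
  corpus <- submitEntity(corpus, e2, "cur2")
  corpus <- acceptEntity(corpus, "EID1", "ed1")
  corpus
}

# one random moderation action against a corpus; guards are expected to
# throw for illegal moves, which callers swallow
randomLifecycleAction <- function(corpus, ppl) {
  actor <- sample(ppl, 1)
  eids <- names(corpusEvidence(corpus))
  aids <- names(corpusAssertions(corpus))
  action <- sample(c("submit_eid", "submit_assertion", "accept",
                     "reject", "flag"), 1,
                   prob = c(0.35, 0.15, 0.25, 0.15, 0.10))
  if (action == "submit_eid") {
    id <- paste0("E", length(eids) + 1, "_", sample.int(1e6, 1))
    it <- compliantEid(id)
    it@source@sourceId <- as.character(sample.int(1e7, 1))
    it@evidenceLevel <- sample(c("A", "B", "C", "D", "E"), 1)
    it@evidenceRating <- sample.int(5L, 1)
    return(suppressWarnings(submitEntity(corpus, it, actor)))
  }
  if (action == "submit_assertion") {
    if (!length(eids)) return(corpus)
    id <- paste0("A", length(aids) + 1, "_", sample.int(1e6, 1))
    a <- Assertion(id, "EGFR", "L858R", "Somatic", "DOID:3910",
                   "Predictive", "Supports", "Sensitivity/Response",
                   drugs = "Gefitinib",
                   supportingEids = sample(eids,
                                           min(length(eids),
                                               sample(1:3, 1))))
    return(submitEntity(corpus, a, actor))
  }
  refs <- c(eids, aids)
  if (!length(refs)) return(corpus)
  ref <- sample(refs, 1)
  switch(action,
         accept = acceptEntity(corpus, ref, actor),
         reject = rejectEntity(corpus, ref, actor, "random audit"),
         flag = flagEntity(corpus, ref, actor, "spot check"))
}

checkLifecycleInvariants <- function(corpus) {
  entities <- c(corpusEvidence(corpus), corpusAssertions(corpus))
  for (x in entities) {
    m <- x@moderation
    expect_true(m@state %in% c("submitted", "accepted", "rejected"))
    if (m@state == "accepted")
      expect_false(identical(m@decidedBy, m@submitterId))
  }
  for (a in corpusAssertions(corpus)) {
    if (moderationState(a) != "accepted") next
    expect_true(any(vapply(a@supportingEids, function(e) {
      it <- corpusEvidence(corpus)[[e]]
      !is.null(it) && moderationState(it) == "accepted"
    }, logical(1))))
  }
  invisible(TRUE)
}

randomIndelCase <- function() {
  n <- sample(20:60, 1)
  contig <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                         prob = c(0.4, 0.1, 0.1, 0.4)),
                  collapse = "")
  if (runif(1) < 0.5) {            # deletion
    len <- sample(1:4, 1)
    start <- sample(seq_len(n - len), 1)
    stop <- start + len - 1
    list(contig = contig,
         coords = GenomicCoordinates("c", start, stop,
                                     substr(contig, start, stop), "-"))
  } else {                          # insertion
    len <- sample(1:3, 1)
    start <- sample(seq_len(n - 1), 1)
    ins <- paste(sample(c("A", "T"), len, replace = TRUE), collapse = "")
    list(contig = contig,
         coords = GenomicCoordinates("c", start, start + 1, "-", ins))
  }
}
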