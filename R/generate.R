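## Seeded synthetic-corpus generator.  Builds a corpus through the same
## lifecycle operations a curator would use (so the event log is real and
## replayable), spanning all evidence types, levels, directions and
## significances, Predictive items with 1-3 drugs, Predisposing assertions
## covering every ACMG outcome, and somatic assertions across tiers.
## Optionally injects a labelled fraction of single-rule defects for
## validator recall testing, and emits small random contigs plus indel
## fixtures (homopolymer/dinucleotide repeats) for the normalization
## oracle.  Identical seed + config => identical corpus.

.genePool <- c("EGFR", "KRAS", "BRAF", "TP53", "PIK3CA", "ALK", "ERBB2",
               "BRCA1", "BRCA2", "KIT", "ABL1", "MET")

.defectKinds <- c("EID_REQUIRED_FIELD_MISSING", "EID_RATING_RANGE",
                  "EID_DRUG_INTERACTION_REQUIRED",
                  "EID_PREDISPOSING_SIGNIFICANCE_NA",
                  "EID_SIGNIFICANCE_VOCAB", "EID_DRUGS_ON_NONPREDICTIVE",
                  "EID_DISEASE_UNRESOLVED", "EID_DRUG_TRADE_NAME")

#' Generator configuration
#'
#' @param seed Integer seed driving all randomness.
#' @param nGenes,nVariants,nEids,nAssertions Record counts.
#' @param violationRate Fraction of evidence items submitted with one
#'   labelled, detectable defect (ground truth kept in
#'   \code{corpusExtras(corpus)$injected_defects}).
#' @param violationMix Named weights over the injectable rule ids
#'   (defaults to uniform over the eight kinds).
#' @param levelDistribution Named weights over evidence levels A-E.
#' @param ratingDistribution Weights over star ratings 1-5.
#' @return Config list for \code{\link{generateCorpus}}.
#' @export
generatorConfig <- function(seed = 7L, nGenes = 6L, nVariants = 12L,
                            nEids = 40L, nAssertions = 8L,
                            violationRate = 0,
                            violationMix = NULL,
                            levelDistribution = c(A = 0.05, B = 0.20,
                                                  C = 0.30, D = 0.30,
                                                  E = 0.15),
                            ratingDistribution = c(0.10, 0.20, 0.40,
                                                   0.20, 0.10)) {
  stopifnot(nGenes >= 0, nVariants >= 0, nEids >= 0, nAssertions >= 0,
            violationRate >= 0, violationRate <= 1)
  if (is.null(violationMix)) {
    violationMix <- rep(1, length(.defectKinds))
    names(violationMix) <- .defectKinds
  }
  list(seed = as.integer(seed), nGenes = as.integer(nGenes),
       nVariants = as.integer(nVariants), nEids = as.integer(nEids),
       nAssertions = as.integer(nAssertions),
       violationRate = violationRate, violationMix = violationMix,
       levelDistribution = levelDistribution,
       ratingDistribution = ratingDistribution)
}

.randomContig <- function(len) {
  base <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  ## plant a homopolymer and a dinucleotide repeat so left shifting has
  ## room to move
  runStart <- sample.int(max(1L, len - 12L), 1L)
  runBase <- sample(c("A", "C", "G", "T"), 1L)
  runLen <- sample(4:7, 1L)
  base[runStart:(runStart + runLen - 1L)] <- runBase
  diStart <- min(len - 9L, runStart + runLen + 2L)
  if (diStart >= 1L) {
    di <- sample(c("A", "C", "G", "T"), 2L)
    reps <- rep(di, length.out = 8L)
    base[diStart:(diStart + 7L)] <- reps
  }
  paste(base, collapse = "")
}

.coordinateFixtures <- function(contigs, n) {
  rows <- list()
  nms <- names(contigs)
  for (i in seq_len(n)) {
    nm <- nms[((i - 1L) %% length(nms)) + 1L]
    seq <- contigs[[nm]]
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    ## find a repeat run and delete/insert inside it, away from the left
    ## edge, so normalization has work to do
    runs <- rle(chars)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    long <- which(runs$lengths >= 3L & starts > 2L)
    if (!length(long)) next
    k <- long[sample.int(length(long), 1L)]
    posEnd <- ends[k]
    if (i %% 2L == 0L) {
      rows[[length(rows) + 1L]] <-
        data.frame(contig = nm, start = posEnd, stop = posEnd,
                   ref = chars[posEnd], var = "-",
                   stringsAsFactors = FALSE)
    } else if (posEnd < length(chars)) {
      rows[[length(rows) + 1L]] <-
        data.frame(contig = nm, start = posEnd, stop = posEnd + 1L,
                   ref = "-", var = runs$values[k],
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(contig = character(), start = numeric(),
                      stop = numeric(), ref = character(),
                      var = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

.sampleFrom <- function(x, weights = NULL) {
  if (is.null(weights)) x[sample.int(length(x), 1L)]
  else x[sample.int(length(x), 1L, prob = weights)]
}

.injectDefect <- function(item, kind, drugs) {
  sig <- function(t) significanceVocabulary(t)[1L]
  switch(kind,
    EID_REQUIRED_FIELD_MISSING = {
      item@evidenceStatement <- NA_character_
      item
    },
    EID_RATING_RANGE = {
      item@evidenceRating <- 6L
      item
    },
    EID_DRUG_INTERACTION_REQUIRED = {
      item@evidenceType <- "Predictive"
      item@clinicalSignificance <- sig("Predictive")
      item@drugs <- drugs[1:2]
      item@drugInteractionType <- NA_character_
      item
    },
    EID_PREDISPOSING_SIGNIFICANCE_NA = {
      item@evidenceType <- "Predisposing"
      item@clinicalSignificance <- "Positive"
      item@drugs <- character()
      item@drugInteractionType <- NA_character_
      item@evidenceStatement <-
        "Variant segregates with disease in the reported family."
      item
    },
    EID_SIGNIFICANCE_VOCAB = {
      item@evidenceType <- "Predictive"
      item@clinicalSignificance <- "Better Outcome"
      item@drugs <- drugs[1L]
      item@drugInteractionType <- NA_character_
      item
    },
    EID_DRUGS_ON_NONPREDICTIVE = {
      item@evidenceType <- "Prognostic"
      item@clinicalSignificance <- "Better Outcome"
      item@drugs <- drugs[1L]
      item@drugInteractionType <- NA_character_
      item
    },
    EID_DISEASE_UNRESOLVED = {
      item@diseaseDoid <- "DOID:9999999"
      item@couldNotFindDisease <- FALSE
      item
    },
    EID_DRUG_TRADE_NAME = {
      item@evidenceType <- "Predictive"
      item@clinicalSignificance <- sig("Predictive")
      item@drugs <- "Herceptin"
      item@drugInteractionType <- NA_character_
      item
    },
    stop("unknown defect kind ", kind))
}

#' Generate a synthetic curation corpus
#'
#' See \code{\link{generatorConfig}} for the dials.  The generated corpus
#' is built through \code{\link{submitEntity}} /
#' \code{\link{acceptEntity}} / \code{\link{rejectEntity}}, so its event
#' log replays to the same corpus.  Roughly 70\% of evidence items end up
#' accepted, 10\% rejected and 20\% pending.  With a non-zero
#' \code{violationRate}, the chosen fraction of evidence items each carry
#' exactly one labelled rule defect; the ground truth lands in
#' \code{corpusExtras(corpus)$injected_defects}.
#'
#' @param config From \code{\link{generatorConfig}}.
#' @return A \linkS4class{Corpus}.
#' @examples
#' corpus <- generateCorpus(generatorConfig(seed = 7, nEids = 10))
#' corpus
#' @export
generateCorpus <- function(config = generatorConfig()) {
  set.seed(config$seed)
  registries <- bundledRegistries()
  corpus <- emptyCorpus(registries = registries)

  ## actors: four curators, two editors with valid COI, one admin
  curators <- paste0("curator", 1:4)
  for (cu in curators) corpus <- registerActor(corpus, cu, "Curator")
  for (ed in c("editor1", "editor2"))
    corpus <- registerActor(corpus, ed, "Editor", "2019-06-01")
  corpus <- registerActor(corpus, "admin1", "Admin", "2019-06-01")

  genes <- .genePool[seq_len(min(config$nGenes, length(.genePool)))]
  doids <- registries$disease@terms$term_id
  drugs <- knownDrugs()$drug_name
  hpo <- setdiff(registries$phenotype@terms$term_id,
                 c("HP:0000001", "HP:0000118"))

  ## contigs + coordinate fixtures for the normalization oracle
  contigs <- vapply(1:3, function(i) .randomContig(60L), character(1))
  names(contigs) <- paste0("ctg", 1:3)
  corpus@extras$contigs <- as.list(contigs)
  fixtures <- .coordinateFixtures(contigs, 10L)
  corpus@extras$coordinate_fixtures <- fixtures

  ## variants, submitted by curators with coordinates on the contigs
  aa <- c("A", "R", "N", "D", "C", "E", "G", "H", "L", "K", "M", "F",
          "P", "S", "T", "W", "Y", "V")
  variantNames <- character(config$nVariants)
  variantGenes <- character(config$nVariants)
  if (config$nVariants > 0) for (i in seq_len(config$nVariants)) {
    g <- genes[((i - 1L) %% length(genes)) + 1L]
    cat3 <- i %% 6L
    nm <- if (cat3 == 0L) "Mutation"
          else paste0(.sampleFrom(aa), sample(60:900, 1L), .sampleFrom(aa))
    types <- if (cat3 == 0L) "SO:0001060" else "SO:0001583"
    ctgName <- names(contigs)[((i - 1L) %% length(contigs)) + 1L]
    ctg <- contigs[[ctgName]]
    pos <- sample.int(nchar(ctg), 1L)
    refBase <- substr(ctg, pos, pos)
    altBase <- .sampleFrom(setdiff(c("A", "C", "G", "T"), refBase))
    coords <- GenomicCoordinates(ctgName, pos, pos, refBase, altBase,
                                 "GRCh37",
                                 sprintf("ENST%011d.1", i))
    v <- VariantRecord(g, nm,
                       variantTypes = types,
                       hgvsExpressions =
                         sprintf("ENST%011d.1:c.%dC>G", i, pos),
                       clinvarIds = if (i %% 4L == 0L) "NONE_FOUND"
                                    else as.character(10000 + i),
                       primaryCoordinates = coords)
    corpus <- submitEntity(corpus, v, .sampleFrom(curators))
    variantNames[i] <- nm
    variantGenes[i] <- g
  }

  evTypes <- defaultConfig()$evidence_types
  levels <- names(config$levelDistribution)

  ## which evidence items get a defect, and which kind
  nBad <- floor(config$violationRate * config$nEids)
  badIdx <- if (nBad > 0) sort(sample.int(config$nEids, nBad)) else integer()
  injected <- list()

  for (i in seq_len(config$nEids)) {
    vi <- ((i - 1L) %% max(1L, config$nVariants)) + 1L
    g <- variantGenes[vi]; vn <- variantNames[vi]
    etype <- evTypes[((i - 1L) %% length(evTypes)) + 1L]
    lvl <- .sampleFrom(levels, config$levelDistribution)
    rating <- sample.int(5L, 1L, prob = config$ratingDistribution)
    dir <- if (stats::runif(1) < 0.8) "Supports" else "Does not support"
    doid <- .sampleFrom(doids)
    diseaseName <- termName(registries$disease, doid)
    sigPool <- significanceVocabulary(etype)
    sigv <- .sampleFrom(sigPool)
    itemDrugs <- character(); dit <- NA_character_
    if (etype == "Predictive") {
      nd <- sample.int(3L, 1L, prob = c(0.6, 0.3, 0.1))
      itemDrugs <- sample(drugs, nd)
      if (nd > 1L)
        dit <- .sampleFrom(defaultConfig()$drug_interaction_types)
    }
    statement <- if (etype == "Predisposing")
      sprintf("Case data in %s support codes PM2 and PP3 for %s %s.",
              diseaseName, g, vn)
    else
      sprintf("%s %s shows a %s %s association in %s.",
              g, vn, tolower(dir), tolower(etype), diseaseName)
    origin <- if (etype == "Predisposing") "Rare Germline" else "Somatic"
    phen <- if (i %% 5L == 0L) .sampleFrom(hpo) else character()

    item <- EvidenceItem(
      eid = sprintf("EID%04d", i), geneSymbol = g, variantName = vn,
      source = SourceRef(if (i %% 7L == 0L) "ASCO" else "PubMed",
                         as.character(20000000 + i),
                         sprintf("Author%d et al., 20%02d", i,
                                 10 + (i %% 10))),
      variantOrigin = origin, diseaseDoid = doid,
      evidenceStatement = statement, evidenceType = etype,
      evidenceLevel = lvl, evidenceDirection = dir,
      clinicalSignificance = sigv, evidenceRating = rating,
      drugs = itemDrugs, drugInteractionType = dit, phenotypes = phen)

    if (i %in% badIdx) {
      kind <- .sampleFrom(names(config$violationMix),
                          config$violationMix)
      item <- .injectDefect(item, kind, drugs)
      injected[[length(injected) + 1L]] <-
        data.frame(entity_ref = item@eid, rule_id = kind,
                   stringsAsFactors = FALSE)
    }

    submitter <- .sampleFrom(curators)
    corpus <- submitEntity(corpus, item, submitter)
    u <- stats::runif(1)
    editor <- .sampleFrom(c("editor1", "editor2"))
    if (u < 0.7) {
      corpus <- acceptEntity(corpus, item@eid, editor)
    } else if (u < 0.8) {
      corpus <- rejectEntity(corpus, item@eid, editor,
                             "insufficient study detail")
    }
  }

  if (length(injected))
    corpus@extras$injected_defects <- do.call(rbind, injected)

  ## assertions: somatic tiers + Predisposing ACMG outcomes
  acmgSets <- list(c("PVS1", "PS1"), c("PS1", "PM1", "PM2"), "BA1",
                   c("BS1", "BP1"), "PM1", c("BA1", "PVS1"))
  asrtTypes <- c("Predictive", "Prognostic", "Diagnostic", "Predisposing")
  madeAssertions <- 0L
  i <- 0L
  while (madeAssertions < config$nAssertions && i < config$nAssertions * 4L) {
    i <- i + 1L
    vi <- ((i - 1L) %% max(1L, config$nVariants)) + 1L
    g <- variantGenes[vi]; vn <- variantNames[vi]
    vkey <- variantKey(g, vn)
    eids <- Filter(function(e)
      identical(variantKey(e@geneSymbol, e@variantName), vkey),
      corpus@evidenceItems)
    accepted <- Filter(function(e) e@moderation@state == "accepted", eids)
    if (!length(accepted)) next
    atype <- asrtTypes[((madeAssertions) %% length(asrtTypes)) + 1L]
    aid <- sprintf("AID%03d", madeAssertions + 1L)
    support <- vapply(accepted[seq_len(min(3L, length(accepted)))],
                      function(e) e@eid, character(1))
    doid <- accepted[[1L]]@diseaseDoid

    if (atype == "Predisposing") {
      codes <- acmgSets[[((madeAssertions) %% length(acmgSets)) + 1L]]
      cls <- combineAcmg(codes)
      a <- Assertion(aid, g, vn, "Rare Germline", doid, atype,
                     "Supports", "N/A", acmgCodes = codes,
                     acmgClassification = cls@value,
                     summary = sprintf("Germline classification of %s %s.",
                                       g, vn),
                     description = "Codes combined from supporting items.",
                     supportingEids = support)
    } else {
      vocab <- significanceVocabulary(atype, assertion = TRUE)
      sigEid <- accepted[[1L]]@clinicalSignificance
      sigv <- if (sigEid %in% vocab) sigEid else vocab[1L]
      hasA <- any(vapply(accepted, function(e)
        identical(e@evidenceLevel, "A"), logical(1)))
      adrugs <- if (atype == "Predictive") accepted[[1L]]@drugs[1L]
                else character()
      adrugs <- adrugs[!is.na(adrugs)]
      a <- Assertion(aid, g, vn, "Somatic", doid, atype, "Supports",
                     sigv, drugs = adrugs,
                     fdaRegulatoryApproval = hasA,
                     summary = sprintf("%s interpretation of %s %s.",
                                       atype, g, vn),
                     description = "Synthesized from accepted items.",
                     supportingEids = support)
      amp <- assignAmp(a, corpus)
      a@ampTier <- amp@tier
      a@ampLevel <- amp@level
    }
    submitter <- .sampleFrom(curators)
    corpus <- submitEntity(corpus, a, submitter)
    corpus <- acceptEntity(corpus, aid, .sampleFrom(c("editor1",
                                                      "editor2")))
    madeAssertions <- madeAssertions + 1L
  }
  corpus
}
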