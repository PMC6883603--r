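# Independent oracles, deliberately written against the literature /
# first principles rather than the package's own code paths.

# --- ACMG combining: literal rule-by-rule evaluation ----------------------
# Counts each strength (honouring @overrides) and tests every combining
# rule as written, with literal ranges (e.g. "1 strong AND 1-2 moderate").
oracleAcmg <- function(codes) {
  toks <- sub("@.*$", "", codes)
  ovr <- ifelse(grepl("@", codes), sub("^[^@]*@", "", codes), NA)
  strengthOf <- function(tok, o) {
    if (!is.na(o)) return(o)
    if (grepl("^PVS", tok)) "very_strong"
    else if (grepl("^PS", tok)) "strong"
    else if (grepl("^PM", tok)) "moderate"
    else if (grepl("^PP", tok)) "supporting"
    else if (grepl("^BA", tok)) "standalone"
    else if (grepl("^BS", tok)) "strong"
    else "supporting"
  }
  isPath <- grepl("^(PVS|PS|PM|PP)", toks)
  s <- mapply(strengthOf, toks, ovr)
  nVS <- sum(isPath & s == "very_strong")
  nS  <- sum(isPath & s == "strong")
  nM  <- sum(isPath & s == "moderate")
  nP  <- sum(isPath & s == "supporting")
  nBA <- sum(!isPath & s == "standalone")
  nBS <- sum(!isPath & s == "strong")
  nBP <- sum(!isPath & s == "supporting")

  pathogenic <-
    (nVS >= 1 && nS >= 1) ||
    (nVS >= 1 && nM >= 2) ||
    (nVS >= 1 && nM == 1 && nP == 1) ||
    (nVS >= 1 && nP >= 2) ||
    (nS >= 2) ||
    (nS == 1 && nM >= 3) ||
    (nS == 1 && nM == 2 && nP >= 2) ||
    (nS == 1 && nM == 1 && nP >= 4)
  likelyPath <-
    (nVS == 1 && nM == 1) ||
    (nS == 1 && nM >= 1 && nM <= 2) ||
    (nS == 1 && nP >= 2) ||
    (nM >= 3) ||
    (nM == 2 && nP >= 2) ||
    (nM == 1 && nP >= 4)
  benign <- (nBA >= 1) || (nBS >= 2)
  likelyBenign <- (nBS == 1 && nBP == 1) || (nBP >= 2)

  pathClass <- if (pathogenic) "Pathogenic"
               else if (likelyPath) "Likely Pathogenic" else NA
  benClass <- if (benign) "Benign"
              else if (likelyBenign) "Likely Benign" else NA
  anyP <- any(isPath); anyB <- any(!isPath)
  conflict <- (!is.na(pathClass) && !is.na(benClass)) ||
    (!is.na(pathClass) && anyB) || (!is.na(benClass) && anyP)
  value <- if (conflict) "VUS"
           else if (!is.na(pathClass)) pathClass
           else if (!is.na(benClass)) benClass
           else "VUS"
  list(value = value, conflict = conflict)
}

# --- string-application oracle for coordinates ----------------------------
# Applies a trimmed-dialect representation to a contig by plain substring
# surgery; independent of the package's internal codec.
oracleApply <- function(contig, start, stop, ref, var) {
  if (identical(ref, "-")) {
    # insertion between start and stop
    paste0(substr(contig, 1, start), var,
           substr(contig, start + 1, nchar(contig)))
  } else if (identical(var, "-")) {
    paste0(substr(contig, 1, start - 1),
           substr(contig, stop + 1, nchar(contig)))
  } else {
    paste0(substr(contig, 1, start - 1), var,
           substr(contig, stop + 1, nchar(contig)))
  }
}

# Exhaustive leftmost oracle: enumerate every single-run deletion/insertion
# representation on the contig with allele length <= maxLen and return the
# smallest start whose application reproduces `target`.
oracleLeftmostStart <- function(contig, target, maxLen = 6) {
  n <- nchar(contig)
  best <- Inf
  for (start in 1:n) {
    for (len in 1:maxLen) {
      stop <- start + len - 1
      if (stop <= n) {                       # deletion candidates
        ref <- substr(contig, start, stop)
        if (identical(oracleApply(contig, start, stop, ref, "-"), target))
          best <- min(best, start)
      }
      if (start < n) {                        # insertion candidates
        combos <- .oracleKmers(len)
        for (ins in combos)
          if (identical(oracleApply(contig, start, start + 1, "-", ins),
                        target))
            best <- min(best, start)
      }
    }
  }
  best
}

.oracleKmersCache <- new.env(parent = emptyenv())
.oracleKmers <- function(len) {
  key <- as.character(len)
  if (!is.null(.oracleKmersCache[[key]])) return(.oracleKmersCache[[key]])
  out <- "";
  for (i in seq_len(len))
    out <- as.vector(outer(out, c("A", "C", "G", "T"), paste0))
  .oracleKmersCache[[key]] <- out
  out
}

# --- ontology transitive closure by brute force ---------------------------
oracleAncestors <- function(termId, parents) {
  out <- character()
  frontier <- parents[[termId]]
  while (length(frontier)) {
    new <- setdiff(frontier, out)
    out <- c(out, new)
    frontier <- unique(unlist(parents[new]))
  }
  sort(unique(out))
}
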