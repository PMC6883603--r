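## Representative-coordinate checking and 1-based left-shift normalization.
##
## Dialect: trimmed alleles, 1-based fully-closed coordinates.  SNV/MNV:
## start..stop covers the substituted bases.  Deletion: start..stop covers
## the deleted bases, variant allele "-".  Insertion: the inserted bases
## sit between start and stop with stop == start + 1, reference allele
## "-".  Internally the normalizer works on a (pos, ref, alt) allele pair
## (possibly empty strings) and converts at the boundary, so the trimmed
## dialect lives in one codec.

#' Read reference contigs from FASTA
#'
#' Whole-contig load (fixtures are small); contig names are the first
#' whitespace-delimited word of each header and lookups downstream are
#' case-insensitive.
#'
#' @param path FASTA file path.
#' @return Named character vector of upper-case sequences.
#' @examples
#' fa <- system.file("extdata", "example_ref.fa", package = "varcurate")
#' readReferenceFasta(fa)[["toy1"]]
#' @export
readReferenceFasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  out
}

.getContig <- function(contigs, name) {
  if (length(contigs) == 1L && is.null(names(contigs))) return(contigs)
  i <- match(tolower(name), tolower(names(contigs)))
  if (is.na(i))
    stop("range error: contig '", name, "' not found in reference")
  contigs[[i]]
}

.isDash <- function(x) is.na(x) || x == "-" || x == ""

#' Check representative coordinates against the reference sequence
#'
#' For SNV/MNV and deletions the reference allele must equal the contig
#' bases at \code{start..stop}; insertions (reference allele \code{"-"})
#' must span the two flanking bases (\code{stop == start + 1}).
#' Coordinates outside the contig are a hard range error; content
#' mismatches come back as violations.
#'
#' @param coords A \linkS4class{GenomicCoordinates}.
#' @param contig Reference sequence: a single string, or a named vector
#'   from \code{\link{readReferenceFasta}} (looked up by
#'   \code{coords@chromosome}, case-insensitive).
#' @return Violations data.frame.
#' @examples
#' checkReference(GenomicCoordinates("toy", 4, 4, "T", "A"), "GCATTTAC")
#' @export
checkReference <- function(coords, contig) {
  seqs <- if (length(contig) > 1L || !is.null(names(contig))) contig
          else contig
  seq <- .getContig(seqs, coords@chromosome)
  n <- nchar(seq)
  start <- coords@start; stop <- coords@stop
  if (is.na(start) || is.na(stop) || start < 1 || stop > n)
    stop("range error: coordinates ", start, "-", stop,
         " outside contig of length ", n)
  ref <- coords@referenceBase; var <- coords@variantBase
  entity <- paste0(coords@chromosome, ":", start, "-", stop)
  v <- list()
  if (start > stop) {
    v[[length(v) + 1L]] <- .violationRow(
      "COORD_START_GT_STOP", "error", entity, "start",
      paste0(start, " > ", stop))
    return(.bindViolations(v))
  }
  if (.isDash(ref) && .isDash(var)) {
    v[[length(v) + 1L]] <- .violationRow(
      "COORD_ALLELES_BLANK", "error", entity, "reference_base",
      "reference and variant bases cannot both be '-'")
    return(.bindViolations(v))
  }
  if (.isDash(ref)) {
    if (stop != start + 1)
      v[[length(v) + 1L]] <- .violationRow(
        "COORD_INSERTION_SPAN", "error", entity, "stop",
        "insertions must have stop == start + 1")
  } else {
    observed <- substr(seq, start, stop)
    if (!identical(observed, toupper(ref)))
      v[[length(v) + 1L]] <- .violationRow(
        "COORD_REF_MISMATCH", "error", entity, "reference_base",
        paste0("reference is '", observed, "', record says '", ref, "'"))
  }
  .bindViolations(v)
}

## trimmed dialect -> internal (pos, ref, alt); empty string = absent allele
.toInternal <- function(coords) {
  ref <- coords@referenceBase; alt <- coords@variantBase
  if (.isDash(ref)) {
    ## insertion between start and stop: internal pos = insertion point
    list(pos = coords@start + 1, ref = "", alt = toupper(alt))
  } else if (.isDash(alt)) {
    list(pos = coords@start, ref = toupper(ref), alt = "")
  } else {
    list(pos = coords@start, ref = toupper(ref), alt = toupper(alt))
  }
}

## internal -> trimmed dialect
.toTrimmed <- function(int, coords) {
  ref <- int$ref; alt <- int$alt; pos <- int$pos
  if (nchar(ref) == 0L) {
    GenomicCoordinates(coords@chromosome, pos - 1, pos, "-", alt,
                       coords@referenceBuild,
                       coords@representativeTranscript)
  } else if (nchar(alt) == 0L) {
    GenomicCoordinates(coords@chromosome, pos, pos + nchar(ref) - 1,
                       ref, "-", coords@referenceBuild,
                       coords@representativeTranscript)
  } else {
    GenomicCoordinates(coords@chromosome, pos, pos + nchar(ref) - 1,
                       ref, alt, coords@referenceBuild,
                       coords@representativeTranscript)
  }
}

#' Left-shift normalize an indel
#'
#' Produces the canonical leftmost trimmed representation of a variant:
#' the shared allele suffix is trimmed, then the shared prefix (advancing
#' start), and while one allele is empty the variant is shifted left by
#' prepending the preceding reference base to both alleles and re-trimming,
#' until no further shift preserves the alternate sequence.  The result is
#' idempotent and allele-equivalent to the input; SNVs pass through
#' unchanged.  A variant whose alleles cancel entirely (a no-op) is a
#' degenerate-variant error.
#'
#' @param coords A \linkS4class{GenomicCoordinates} that passes
#'   \code{\link{checkReference}}.
#' @param contig Reference sequence (string or named vector as in
#'   \code{\link{checkReference}}).
#' @return A \linkS4class{NormalizationResult}: the normalized
#'   coordinates, how far the start moved left, and whether shared bases
#'   were trimmed.
#' @examples
#' ## deletion of one T in a TTT homopolymer shifts to the leftmost T
#' leftShiftNormalize(GenomicCoordinates("toy", 6, 6, "T", "-"), "GCATTTAC")
#' @export
leftShiftNormalize <- function(coords, contig) {
  seq <- .getContig(contig, coords@chromosome)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  int <- .toInternal(coords)
  ref <- strsplit(int$ref, "", fixed = TRUE)[[1]]
  alt <- strsplit(int$alt, "", fixed = TRUE)[[1]]
  pos <- int$pos

  ## phase 1: trim shared bases of the *input* alleles (sets the flag)
  trimmed <- FALSE
  while (length(ref) > 0L && length(alt) > 0L &&
         ref[length(ref)] == alt[length(alt)]) {
    ref <- ref[-length(ref)]; alt <- alt[-length(alt)]
    trimmed <- TRUE
  }
  while (length(ref) > 0L && length(alt) > 0L && ref[1] == alt[1]) {
    ref <- ref[-1]; alt <- alt[-1]
    pos <- pos + 1
    trimmed <- TRUE
  }
  if (!length(ref) && !length(alt))
    stop("degenerate-variant error: alleles cancel entirely (no-op variant)")

  ## phase 2: left shift while one allele is empty; trimming here removes
  ## bases the shifter itself prepended, so the flag stays untouched
  repeat {
    nr <- length(ref); na <- length(alt)
    if (nr > 0L && na > 0L && ref[nr] == alt[na]) {
      ref <- ref[-nr]; alt <- alt[-na]
      next
    }
    if ((nr == 0L || na == 0L) && pos > 1) {
      b <- chars[pos - 1]
      ref <- c(b, ref); alt <- c(b, alt)
      pos <- pos - 1
      next
    }
    break
  }
  while (length(ref) > 0L && length(alt) > 0L && ref[1] == alt[1]) {
    ref <- ref[-1]; alt <- alt[-1]
    pos <- pos + 1
  }

  intOut <- list(pos = pos, ref = paste(ref, collapse = ""),
                 alt = paste(alt, collapse = ""))
  out <- .toTrimmed(intOut, coords)
  new("NormalizationResult", normalized = out,
      shiftedBy = max(0, coords@start - out@start), trimmed = trimmed)
}

#' Apply a variant to its contig
#'
#' Returns the full alternate sequence produced by applying the trimmed
#' representation to the reference contig; two representations of the
#' same variant yield identical strings.  Used for equivalence checking.
#'
#' @param coords A \linkS4class{GenomicCoordinates}.
#' @param contig Reference sequence.
#' @return Character scalar: the alternate contig sequence.
#' @export
applyCoordinates <- function(coords, contig) {
  seq <- .getContig(contig, coords@chromosome)
  int <- .toInternal(coords)
  pre <- substr(seq, 1, int$pos - 1)
  post <- substr(seq, int$pos + nchar(int$ref), nchar(seq))
  paste0(pre, int$alt, post)
}

#' Parse a coordinate string
#'
#' Accepts \code{"chr:start-stop:REF>ALT"} (as used by the CLI
#' \code{normalize} subcommand), e.g. \code{"toy1:5-6:TT>T"} or
#' \code{"7:140453136-140453136:A>T"}.
#'
#' @param spec Coordinate string.
#' @param referenceBuild Assembly tag to stamp on the result.
#' @return A \linkS4class{GenomicCoordinates}.
#' @export
parseCoordinateString <- function(spec, referenceBuild = "GRCh37") {
  m <- regmatches(spec,
    regexec("^([^:]+):([0-9]+)-([0-9]+):([ACGTN-]+)>([ACGTN-]+)$", spec))[[1]]
  if (!length(m))
    stop("cannot parse coordinate string '", spec,
         "' (expected chr:start-stop:REF>ALT)")
  GenomicCoordinates(m[2], as.numeric(m[3]), as.numeric(m[4]), m[5], m[6],
                     referenceBuild)
}

#' VCF-style padded representation
#'
#' Converts trimmed coordinates to the padded (anchor-base) convention
#' used by VCF: indels are written with the base preceding the event and
#' a 1-based position of that anchor base.
#'
#' @param coords A \linkS4class{GenomicCoordinates}.
#' @param contig Reference sequence.
#' @return List with \code{chrom}, \code{pos}, \code{ref}, \code{alt}.
#' @export
asPaddedAllele <- function(coords, contig) {
  seq <- .getContig(contig, coords@chromosome)
  int <- .toInternal(coords)
  if (nchar(int$ref) == 0L || nchar(int$alt) == 0L) {
    if (int$pos > 1) {
      anchor <- substr(seq, int$pos - 1, int$pos - 1)
      list(chrom = coords@chromosome, pos = int$pos - 1,
           ref = paste0(anchor, int$ref), alt = paste0(anchor, int$alt))
    } else {
      ## event at contig start: pad with the following base instead
      nxt <- substr(seq, int$pos + nchar(int$ref),
                    int$pos + nchar(int$ref))
      list(chrom = coords@chromosome, pos = 1,
           ref = paste0(int$ref, nxt), alt = paste0(int$alt, nxt))
    }
  } else {
    list(chrom = coords@chromosome, pos = int$pos, ref = int$ref,
         alt = int$alt)
  }
}
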