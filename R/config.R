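## Controlled vocabularies, level weights and the config override mechanism.
## Everything here is configuration: a YAML file handed to loadConfig() can
## replace any vocabulary or weight without a code change.

.vcDefaultConfig <- function() {
  list(
    level_weights = list(A = 10, B = 5, C = 3, D = 1, E = 0.5),
    evidence_levels = c("A", "B", "C", "D", "E"),
    evidence_types = c("Predictive", "Diagnostic", "Prognostic",
                       "Predisposing", "Functional"),
    assertion_types = c("Predictive", "Diagnostic", "Prognostic",
                        "Predisposing"),
    evidence_directions = c("Supports", "Does not support"),
    variant_origins = c("Somatic", "Rare Germline", "Common Germline",
                        "Unknown", "N/A"),
    drug_interaction_types = c("Combination", "Sequential", "Substitutes"),
    source_types = c("PubMed", "ASCO"),
    rating_range = c(1L, 5L),
    significance = list(
      Predictive = c("Sensitivity/Response", "Resistance",
                     "Reduced Sensitivity", "Adverse Response", "N/A"),
      Diagnostic = c("Positive", "Negative"),
      Prognostic = c("Better Outcome", "Poor Outcome", "N/A"),
      Predisposing = c("N/A"),
      Functional = c("Gain of Function", "Loss of Function",
                     "Unaltered Function", "Neomorphic", "Dominant Negative",
                     "Unknown")
    ),
    # assertions of somatic types can additionally conclude benign/likely
    # benign (the Tier IV outcome)
    assertion_extra_significance = c("Benign", "Likely Benign"),
    included_statuses = "accepted",
    coi_window_days = 365,
    statement_sentence_warning = 3
  )
}

#' Default toolkit configuration
#'
#' Returns the built-in configuration: evidence-level weights (A=10, B=5,
#' C=3, D=1, E=0.5), controlled vocabularies per field, per-evidence-type
#' clinical-significance vocabularies, the moderation states counted by the
#' variant evidence score, and the editor conflict-of-interest validity
#' window (365 days).
#'
#' @return A named list; see \code{\link{loadConfig}} to override entries
#'   from a YAML file.
#' @examples
#' defaultConfig()$level_weights$A
#' @export
defaultConfig <- function() .vcDefaultConfig()

#' Load a configuration file
#'
#' Reads a YAML file and merges it over \code{\link{defaultConfig}}: any
#' top-level entry present in the file replaces the default, everything else
#' is kept.  Vocabularies, level weights and moderation-state inclusion are
#' all overridable, so a corrected significance table can be dropped in
#' without touching code.
#'
#' @param path Path to a YAML file, or \code{NULL} for the defaults.
#' @return A configuration list.
#' @export
loadConfig <- function(path = NULL) {
  cfg <- .vcDefaultConfig()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  for (k in names(user)) {
    if (k == "significance" && is.list(user[[k]])) {
      for (t in names(user[[k]])) cfg$significance[[t]] <- unlist(user[[k]][[t]])
    } else if (k == "level_weights" && is.list(user[[k]])) {
      for (t in names(user[[k]])) cfg$level_weights[[t]] <- user[[k]][[t]]
    } else {
      cfg[[k]] <- if (is.list(user[[k]])) user[[k]] else unlist(user[[k]])
    }
  }
  cfg
}

#' The universally required evidence-item fields
#'
#' The twelve fields every evidence item must populate regardless of its
#' evidence type: gene symbol, variant name, source type, source id, variant
#' origin, disease, evidence statement, evidence type, evidence level,
#' evidence direction, clinical significance and evidence rating.
#' Conditional fields (drugs, drug interaction type) and optional fields
#' (phenotypes, comment) are not listed here.
#'
#' @return Character vector of twelve field names in canonical order.
#' @examples
#' length(requiredEvidenceFields())  # 12
#' @export
requiredEvidenceFields <- function() {
  c("gene_symbol", "variant_name", "source_type", "source_id",
    "variant_origin", "disease", "evidence_statement", "evidence_type",
    "evidence_level", "evidence_direction", "clinical_significance",
    "evidence_rating")
}

#' Clinical-significance vocabulary for an evidence or assertion type
#'
#' @param type Evidence/assertion type, e.g. \code{"Predictive"}.
#' @param assertion When TRUE, the assertion-level vocabulary is returned:
#'   for somatic types this adds \code{"Benign"} and
#'   \code{"Likely Benign"} (the Tier IV outcome).
#' @param config Configuration list (see \code{\link{loadConfig}}).
#' @return Character vector of allowed values.
#' @examples
#' significanceVocabulary("Prognostic")
#' @export
significanceVocabulary <- function(type, assertion = FALSE,
                                   config = defaultConfig()) {
  vocab <- config$significance[[type]]
  if (is.null(vocab)) return(character())
  if (assertion && type %in% c("Predictive", "Diagnostic", "Prognostic"))
    vocab <- c(vocab, config$assertion_extra_significance)
  vocab
}

## ---- bundled drug tables -------------------------------------------------

.vcExtdata <- function(file) {
  system.file("extdata", file, package = "varcurate", mustWork = TRUE)
}

#' Bundled drug name tables
#'
#' \code{knownDrugs} returns the bundled NCIt drug mini-table (generic
#' names with NCIt codes); \code{drugAliases} returns the trade-name /
#' old-name alias table mapping each alias to its generic name.  Both are
#' small curated subsets shipped with the package so that no download is
#' required; validation treats drugs absent from both tables as a warning,
#' not an error.
#'
#' @return A data.frame.
#' @rdname drug-tables
#' @export
knownDrugs <- function() {
  utils::read.delim(.vcExtdata("ncit_drugs.tsv"), stringsAsFactors = FALSE)
}

#' @rdname drug-tables
#' @export
drugAliases <- function() {
  utils::read.delim(.vcExtdata("drug_aliases.tsv"), stringsAsFactors = FALSE)
}

#' Load the bundled ontology subsets
#'
#' Convenience loader for the four mini-registries shipped with the package
#' (Disease Ontology cancer branch, Sequence Ontology sequence_variant
#' subtree, HPO phenotypic-abnormality subset, NCIt drug terms).
#'
#' @return Named list of \linkS4class{OntologyRegistry} objects with keys
#'   \code{disease}, \code{sequence}, \code{phenotype}, \code{drug}.
#' @export
bundledRegistries <- function() {
  list(
    disease = loadOntology(.vcExtdata("doid_subset.tsv"), "disease"),
    sequence = loadOntology(.vcExtdata("so_subset.tsv"), "sequence"),
    phenotype = loadOntology(.vcExtdata("hpo_subset.tsv"), "phenotype"),
    drug = loadOntology(.vcExtdata("ncit_drug_terms.tsv"), "drug")
  )
}
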