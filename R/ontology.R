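## Ontology registry: load a term subset from a 4-column TSV or a minimal
## OBO file, then answer id/name lookups and ancestor queries over the
## is-a DAG.  Registries are pluggable; the bundled mini-subsets (see
## bundledRegistries()) keep everything offline.

.parseOboFile <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  ids <- character(); nms <- character(); parents <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur) && !is.null(cur$id)) {
      ids[[length(ids) + 1L]] <<- cur$id
      nms[[length(nms) + 1L]] <<- if (is.null(cur$name)) NA_character_
                                  else cur$name
      parents[[cur$id]] <<- cur$isa
    }
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(); cur <- list(isa = character()); in_term <- TRUE; next }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || ln == "") next
    if (startsWith(ln, "id:")) cur$id <- trimws(sub("^id:", "", ln))
    else if (startsWith(ln, "name:")) cur$name <- trimws(sub("^name:", "", ln))
    else if (startsWith(ln, "is_a:")) {
      tgt <- trimws(sub("^is_a:", "", ln))
      tgt <- trimws(sub("!.*$", "", tgt))          # strip trailing label
      cur$isa <- c(cur$isa, tgt)
    } else if (startsWith(ln, "is_obsolete:") &&
               grepl("true", ln)) cur$id <- NULL   # drop obsolete terms
  }
  flush()
  list(ids = unlist(ids), names = unlist(nms), parents = parents)
}

.parseTermTsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("term_id", "name", "parent_ids")
  if (!all(need %in% names(df)))
    stop("ontology error: term table needs columns term_id, name, parent_ids")
  parents <- lapply(df$parent_ids, function(p) {
    if (is.na(p) || p == "") character()
    else trimws(strsplit(p, "|", fixed = TRUE)[[1]])
  })
  names(parents) <- df$term_id
  list(ids = df$term_id, names = df$name, parents = parents)
}

.checkAcyclic <- function(parents) {
  ## iterative colour DFS over parent links
  colour <- new.env(parent = emptyenv())
  for (root in names(parents)) {
    if (!is.null(colour[[root]])) next
    stack <- list(list(id = root, i = 0L))
    colour[[root]] <- "grey"
    while (length(stack)) {
      top <- stack[[length(stack)]]
      ps <- parents[[top$id]]
      if (top$i < length(ps)) {
        stack[[length(stack)]]$i <- top$i + 1L
        nxt <- ps[[top$i + 1L]]
        cn <- colour[[nxt]]
        if (is.null(cn)) {
          colour[[nxt]] <- "grey"
          stack[[length(stack) + 1L]] <- list(id = nxt, i = 0L)
        } else if (cn == "grey") {
          stop("ontology error: cyclic parentage involving ", nxt)
        }
      } else {
        colour[[top$id]] <- "black"
        stack[[length(stack)]] <- NULL
      }
    }
  }
  invisible(TRUE)
}

#' Load an ontology term subset
#'
#' Builds an \linkS4class{OntologyRegistry} from either a 4-column TSV term
#' table (\code{term_id}, \code{name}, \code{parent_ids} pipe-separated,
#' \code{ontology_key}) or an OBO-format file (\code{[Term]} stanzas with
#' \code{id}, \code{name}, \code{is_a}; obsolete terms dropped).  The
#' format is chosen by file extension (\code{.obo} vs anything else).
#'
#' Duplicate term ids, parents absent from the file and cyclic parentage
#' are rejected.
#'
#' @param path Path to the term table or OBO file.
#' @param ontologyKey One of \code{"disease"}, \code{"sequence"},
#'   \code{"phenotype"}, \code{"drug"}.
#' @return An \linkS4class{OntologyRegistry}.
#' @seealso \code{\link{isDescendant}}, \code{\link{ancestorsOf}}
#' @export
loadOntology <- function(path, ontologyKey) {
  parsed <- if (grepl("\\.obo$", path, ignore.case = TRUE))
    .parseOboFile(path) else .parseTermTsv(path)
  ids <- parsed$ids
  if (is.null(ids)) ids <- character()
  if (anyDuplicated(ids))
    stop("ontology error: duplicate term_id ",
         ids[duplicated(ids)][1L])
  bad <- setdiff(unlist(parsed$parents, use.names = FALSE), ids)
  if (length(bad))
    stop("ontology error: parent term(s) not in registry: ",
         paste(bad, collapse = ", "))
  .checkAcyclic(parsed$parents)
  terms <- data.frame(term_id = ids,
                      name = if (length(ids)) parsed$names else character(),
                      ontology_key = rep(ontologyKey, length(ids)),
                      stringsAsFactors = FALSE)
  new("OntologyRegistry", terms = terms, parents = parsed$parents,
      ontologyKey = ontologyKey)
}

#' Term lookups in a registry
#'
#' \code{termExists} tests membership; \code{termName} returns the label
#' for a term id (\code{NA} when absent); \code{termByName} returns the
#' term id(s) carrying a label.
#'
#' @param registry An \linkS4class{OntologyRegistry}.
#' @param termId,name Term CURIE / label.
#' @return Logical, character, or character vector respectively.
#' @rdname term-lookup
#' @export
termExists <- function(registry, termId) {
  termId %in% registry@terms$term_id
}

#' @rdname term-lookup
#' @export
termName <- function(registry, termId) {
  i <- match(termId, registry@terms$term_id)
  registry@terms$name[i]
}

#' @rdname term-lookup
#' @export
termByName <- function(registry, name) {
  registry@terms$term_id[registry@terms$name == name]
}

#' All ancestors of a term
#'
#' Transitive closure over parent links, excluding the term itself.
#'
#' @param termId Term CURIE.
#' @param registry An \linkS4class{OntologyRegistry}.
#' @return Character vector of ancestor term ids (possibly empty).
#' @export
ancestorsOf <- function(termId, registry) {
  if (!termExists(registry, termId))
    stop("lookup error: unknown term ", termId)
  seen <- character()
  frontier <- registry@parents[[termId]]
  while (length(frontier)) {
    nxt <- setdiff(frontier, seen)
    seen <- c(seen, nxt)
    frontier <- unique(unlist(registry@parents[nxt], use.names = FALSE))
  }
  sort(unique(seen))
}

#' Is one term a descendant of another?
#'
#' TRUE iff \code{termB} is reachable from \code{termA} via parent links.
#' Irreflexive: a term is not its own descendant.
#'
#' @param termA,termB Term CURIEs; both must resolve in the registry.
#' @param registry An \linkS4class{OntologyRegistry}.
#' @return Logical scalar.
#' @examples
#' reg <- bundledRegistries()$sequence
#' isDescendant("SO:0001583", "SO:0001060", reg)  # missense < sequence_variant
#' @export
isDescendant <- function(termA, termB, registry) {
  if (!termExists(registry, termA))
    stop("lookup error: unknown term ", termA)
  if (!termExists(registry, termB))
    stop("lookup error: unknown term ", termB)
  if (termA == termB) return(FALSE)
  termB %in% ancestorsOf(termA, registry)
}
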