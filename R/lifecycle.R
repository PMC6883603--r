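## Event-sourced curation/moderation state machine.  Every mutation goes
## through an operation that appends one event to the corpus log; the
## current state is a fold over the log (replayEvents), which is what makes
## corpus history deterministic.  Timestamps are logical sequence numbers —
## no wall clock anywhere.

.actorRole <- function(corpus, actorId) {
  a <- corpus@actors[[actorId]]
  if (is.null(a)) "Curator" else a$role      # unknown actors curate
}

.actorCoiValid <- function(corpus, actorId,
                           windowDays = defaultConfig()$coi_window_days) {
  a <- corpus@actors[[actorId]]
  if (is.null(a) || is.null(a$coi_statement_date) ||
      is.na(a$coi_statement_date)) return(FALSE)
  d <- as.Date(a$coi_statement_date)
  diff <- as.numeric(corpus@clock - d)
  diff >= 0 && diff <= windowDays
}

.appendEvent <- function(corpus, action, actorId, entityRef,
                         payload = list()) {
  ev <- list(seq = length(corpus@eventLog) + 1L, action = action,
             actor_id = actorId, entity_ref = entityRef,
             payload = payload)
  corpus@eventLog <- c(corpus@eventLog, list(ev))
  corpus
}

.findEntity <- function(corpus, ref) {
  if (ref %in% names(corpus@evidenceItems))
    return(list(kind = "evidence", entity = corpus@evidenceItems[[ref]]))
  if (ref %in% names(corpus@assertions))
    return(list(kind = "assertion", entity = corpus@assertions[[ref]]))
  if (ref %in% names(corpus@variants))
    return(list(kind = "variant", entity = corpus@variants[[ref]]))
  if (ref %in% names(corpus@genes))
    return(list(kind = "gene", entity = corpus@genes[[ref]]))
  stop("unknown entity '", ref, "'")
}

.storeEntity <- function(corpus, ref, found) {
  switch(found$kind,
         evidence = { corpus@evidenceItems[[ref]] <- found$entity },
         assertion = { corpus@assertions[[ref]] <- found$entity },
         variant = { corpus@variants[[ref]] <- found$entity },
         gene = { corpus@genes[[ref]] <- found$entity })
  corpus
}

.addComment <- function(mod, actorId, text, ts) {
  mod@comments <- rbind(mod@comments,
                        data.frame(actor_id = actorId, text = text,
                                   timestamp = as.integer(ts),
                                   stringsAsFactors = FALSE))
  mod
}

#' Register an actor
#'
#' Adds a curator/editor/admin to the corpus actor registry.  Editors need
#' a conflict-of-interest statement date to accept or reject; the
#' statement is valid for the configured window (365 days by default)
#' relative to the corpus clock.
#'
#' @param corpus A \linkS4class{Corpus}.
#' @param actorId Actor identifier.
#' @param role \code{"Curator"}, \code{"Editor"} or \code{"Admin"}.
#' @param coiStatementDate Date of the conflict-of-interest statement
#'   (Date or string), or \code{NA}.
#' @return The updated corpus.
#' @export
registerActor <- function(corpus, actorId, role = "Curator",
                          coiStatementDate = NA) {
  if (!role %in% c("Curator", "Editor", "Admin"))
    stop("unknown role '", role, "'")
  corpus@actors[[actorId]] <- list(actor_id = actorId, role = role,
                                   coi_statement_date =
                                     if (is.na(coiStatementDate)) NA
                                     else as.character(coiStatementDate))
  .appendEvent(corpus, "register_actor", actorId, actorId,
               list(role = role,
                    coi_statement_date =
                      if (is.na(coiStatementDate)) NA
                      else as.character(coiStatementDate)))
}

.eidIdentity <- function(item) {
  paste(item@geneSymbol, item@variantName, item@source@sourceId,
        item@evidenceType, paste(item@diseaseDoid, collapse = ","),
        paste(sort(item@drugs), collapse = ","), sep = "\r")
}

#' Submit a curatable entity
#'
#' Enters an evidence item, assertion or variant record into the corpus in
#' state \code{submitted}.  Submitting an evidence item auto-creates the
#' gene and variant records it references when they do not already exist.
#' Resubmitting an evidence item identical (gene, variant, source id,
#' type, disease, drugs) to a pending one raises a duplicate warning and
#' records it on the new item.
#'
#' @param corpus A \linkS4class{Corpus}.
#' @param entity \linkS4class{EvidenceItem}, \linkS4class{Assertion} or
#'   \linkS4class{VariantRecord}.
#' @param actor Submitting actor id (unregistered actors are treated as
#'   curators).
#' @return The updated corpus.
#' @export
submitEntity <- function(corpus, entity, actor) {
  ts <- length(corpus@eventLog) + 1L
  mod <- ModerationRecord(state = "submitted", submitterId = actor)

  if (is(entity, "EvidenceItem")) {
    ref <- entity@eid
    if (is.na(ref)) stop("evidence items need an eid before submission")
    dup <- any(vapply(corpus@evidenceItems, function(e)
      e@moderation@state == "submitted" &&
        identical(.eidIdentity(e), .eidIdentity(entity)), logical(1)))
    if (dup) {
      warning("duplicate of a pending evidence item: ", ref)
      mod <- .addComment(mod, actor,
                         "EID_DUPLICATE: identical pending submission", ts)
    }
    entity@moderation <- mod
    ## auto-create gene and variant records
    gs <- entity@geneSymbol
    if (!is.na(gs) && !gs %in% names(corpus@genes))
      corpus@genes[[gs]] <- GeneRecord(geneSymbol = gs)
    vk <- variantKey(gs, entity@variantName)
    if (!is.na(entity@variantName) && !vk %in% names(corpus@variants))
      corpus@variants[[vk]] <- VariantRecord(
        geneSymbol = gs, variantName = entity@variantName,
        moderation = ModerationRecord(state = "submitted",
                                      submitterId = actor))
    corpus@evidenceItems[[ref]] <- entity
    return(.appendEvent(corpus, "submit", actor, ref,
                        list(kind = "evidence",
                             entity = .eidToList(entity))))
  }
  if (is(entity, "Assertion")) {
    ref <- entity@aid
    if (is.na(ref)) stop("assertions need an aid before submission")
    entity@moderation <- mod
    corpus@assertions[[ref]] <- entity
    return(.appendEvent(corpus, "submit", actor, ref,
                        list(kind = "assertion",
                             entity = .assertionToList(entity))))
  }
  if (is(entity, "VariantRecord")) {
    ref <- variantKey(entity@geneSymbol, entity@variantName)
    entity@moderation <- mod
    if (!entity@geneSymbol %in% names(corpus@genes))
      corpus@genes[[entity@geneSymbol]] <-
        GeneRecord(geneSymbol = entity@geneSymbol)
    corpus@variants[[ref]] <- entity
    return(.appendEvent(corpus, "submit", actor, ref,
                        list(kind = "variant",
                             entity = .variantToList(entity))))
  }
  stop("cannot submit entities of class ", class(entity))
}

.requireEditor <- function(corpus, actor, what) {
  if (!.actorRole(corpus, actor) %in% c("Editor", "Admin"))
    stop("authorization error: only editors may ", what)
  if (!.actorCoiValid(corpus, actor))
    stop("authorization error: ", actor,
         " has no valid conflict-of-interest statement")
  invisible(TRUE)
}

#' Accept a submitted entity
#'
#' Moves an entity to state \code{accepted}.  Only editors/admins with a
#' valid conflict-of-interest statement may accept; nobody may accept
#' their own submission; an assertion cannot be accepted until at least
#' one of its supporting evidence items is itself accepted.
#'
#' @param corpus A \linkS4class{Corpus}.
#' @param ref Entity reference (eid, aid or variant key).
#' @param actor Accepting editor's id.
#' @param comment Optional decision comment.
#' @return The updated corpus.
#' @export
acceptEntity <- function(corpus, ref, actor, comment = NA) {
  .requireEditor(corpus, actor, "accept submissions")
  found <- .findEntity(corpus, ref)
  mod <- found$entity@moderation
  if (identical(mod@submitterId, actor))
    stop("self-acceptance error: curators may reject (but not accept) ",
         "their own submissions")
  if (found$kind == "assertion") {
    ok <- any(vapply(found$entity@supportingEids, function(e) {
      it <- corpus@evidenceItems[[e]]
      !is.null(it) && it@moderation@state == "accepted"
    }, logical(1)))
    if (!ok)
      stop("gate error: an assertion cannot be accepted without at ",
           "least one accepted evidence item")
  }
  ts <- length(corpus@eventLog) + 1L
  mod@state <- "accepted"
  mod@decidedBy <- actor
  if (!is.na(comment)) mod <- .addComment(mod, actor, comment, ts)
  found$entity@moderation <- mod
  corpus <- .storeEntity(corpus, ref, found)
  .appendEvent(corpus, "accept", actor, ref,
               list(comment = if (is.na(comment)) NULL else comment))
}

#' Reject a submitted entity
#'
#' Moves an entity to state \code{rejected}.  Editors/admins may reject
#' anything; a submitter may reject their own pending entity.  A rationale
#' comment is mandatory.  Rejecting the last accepted evidence item of an
#' accepted assertion demotes that assertion back to \code{submitted} and
#' flags it for editor attention.
#'
#' @param corpus A \linkS4class{Corpus}.
#' @param ref Entity reference.
#' @param actor Rejecting actor id.
#' @param comment Rationale (required, non-empty).
#' @return The updated corpus.
#' @export
rejectEntity <- function(corpus, ref, actor, comment) {
  if (missing(comment) || is.na(comment) || !nzchar(trimws(comment)))
    stop("comment-required error: rejections need a rationale comment")
  found <- .findEntity(corpus, ref)
  mod <- found$entity@moderation
  isEditor <- .actorRole(corpus, actor) %in% c("Editor", "Admin")
  if (isEditor && !.actorCoiValid(corpus, actor))
    stop("authorization error: ", actor,
         " has no valid conflict-of-interest statement")
  if (!isEditor && !identical(mod@submitterId, actor))
    stop("authorization error: only editors or the submitter may reject")
  ts <- length(corpus@eventLog) + 1L
  mod@state <- "rejected"
  mod@decidedBy <- actor
  mod <- .addComment(mod, actor, comment, ts)
  found$entity@moderation <- mod
  corpus <- .storeEntity(corpus, ref, found)
  corpus <- .appendEvent(corpus, "reject", actor, ref,
                         list(comment = comment))

  ## gate maintenance: demote accepted assertions stripped of their last
  ## accepted evidence item
  if (found$kind == "evidence") {
    for (aid in names(corpus@assertions)) {
      a <- corpus@assertions[[aid]]
      if (a@moderation@state != "accepted") next
      if (!ref %in% a@supportingEids) next
      still <- any(vapply(a@supportingEids, function(e) {
        it <- corpus@evidenceItems[[e]]
        !is.null(it) && it@moderation@state == "accepted"
      }, logical(1)))
      if (!still) {
        am <- a@moderation
        am@state <- "submitted"
        am@flagged <- TRUE
        am <- .addComment(am, actor,
                          paste0("auto-demoted: last accepted supporting ",
                                 "evidence item ", ref, " was rejected"),
                          length(corpus@eventLog) + 1L)
        a@moderation <- am
        corpus@assertions[[aid]] <- a
        corpus <- .appendEvent(corpus, "auto_demote", actor, aid,
                               list(cause = ref))
      }
    }
  }
  corpus
}

.revisableFields <- list(
  evidence = c("evidence_level", "evidence_rating", "evidence_statement",
               "clinical_significance", "evidence_direction", "drugs",
               "drug_interaction_type", "disease", "variant_origin",
               "phenotypes"),
  variant = c("summary", "variant_types", "hgvs_expressions", "aliases"),
  assertion = c("summary", "description", "amp_tier", "amp_level",
                "acmg_codes", "supporting_eids", "clinical_significance",
                "nccn_guideline")
)

.applyFieldValue <- function(entity, field, value) {
  setter <- switch(field,
    evidence_level = function(e, v) { e@evidenceLevel <- as.character(v); e },
    evidence_rating = function(e, v) { e@evidenceRating <- as.integer(v); e },
    evidence_statement = function(e, v) { e@evidenceStatement <- as.character(v); e },
    clinical_significance = function(e, v) { e@clinicalSignificance <- as.character(v); e },
    evidence_direction = function(e, v) { e@evidenceDirection <- as.character(v); e },
    drugs = function(e, v) { e@drugs <- as.character(unlist(v)); e },
    drug_interaction_type = function(e, v) { e@drugInteractionType <- as.character(v); e },
    disease = function(e, v) { e@diseaseDoid <- as.character(unlist(v)); e },
    variant_origin = function(e, v) { e@variantOrigin <- as.character(v); e },
    phenotypes = function(e, v) { e@phenotypes <- as.character(unlist(v)); e },
    summary = function(e, v) { e@summary <- as.character(v); e },
    description = function(e, v) { e@description <- as.character(v); e },
    variant_types = function(e, v) { e@variantTypes <- as.character(unlist(v)); e },
    hgvs_expressions = function(e, v) { e@hgvsExpressions <- as.character(unlist(v)); e },
    aliases = function(e, v) { e@aliases <- as.character(unlist(v)); e },
    amp_tier = function(e, v) { e@ampTier <- as.character(v); e },
    amp_level = function(e, v) { e@ampLevel <- as.character(v); e },
    acmg_codes = function(e, v) { e@acmgCodes <- as.character(unlist(v)); e },
    supporting_eids = function(e, v) { e@supportingEids <- as.character(unlist(v)); e },
    nccn_guideline = function(e, v) { e@nccnGuideline <- as.character(v); e },
    stop("field '", field, "' is not revisable"))
  setter(entity, value)
}

.currentFieldValue <- function(entity, field) {
  switch(field,
    evidence_level = entity@evidenceLevel,
    evidence_rating = entity@evidenceRating,
    evidence_statement = entity@evidenceStatement,
    clinical_significance = entity@clinicalSignificance,
    evidence_direction = entity@evidenceDirection,
    drugs = entity@drugs,
    drug_interaction_type = entity@drugInteractionType,
    disease = entity@diseaseDoid,
    variant_origin = entity@variantOrigin,
    phenotypes = entity@phenotypes,
    summary = entity@summary,
    description = entity@description,
    variant_types = entity@variantTypes,
    hgvs_expressions = entity@hgvsExpressions,
    aliases = entity@aliases,
    amp_tier = entity@ampTier,
    amp_level = entity@ampLevel,
    acmg_codes = entity@acmgCodes,
    supporting_eids = entity@supportingEids,
    nccn_guideline = entity@nccnGuideline,
    NULL)
}

#' Propose a revision to a field
#'
#' Queues a revision against a curatable entity.  The entity is unchanged
#' until an editor accepts the revision
#' (\code{\link{acceptRevision}}); a non-empty rationale comment is
#' mandatory.
#'
#' @param corpus A \linkS4class{Corpus}.
#' @param ref Entity reference.
#' @param field Field name (snake_case, e.g. \code{"evidence_level"}).
#' @param newValue Proposed value.
#' @param comment Rationale for the change (required).
#' @param actor Proposing actor id.
#' @return The updated corpus with the revision pending.
#' @export
proposeRevision <- function(corpus, ref, field, newValue, comment, actor) {
  if (missing(comment) || is.na(comment) || !nzchar(trimws(comment)))
    stop("comment-required error: suggested revisions require a comment")
  found <- .findEntity(corpus, ref)
  if (!field %in% .revisableFields[[found$kind]])
    stop("field '", field, "' is not revisable on a ", found$kind)
  rev <- list(field_name = field,
              old_value = .currentFieldValue(found$entity, field),
              new_value = newValue, comment = comment,
              state = "submitted", proposer_id = actor)
  mod <- found$entity@moderation
  mod@revisions <- c(mod@revisions, list(rev))
  found$entity@moderation <- mod
  corpus <- .storeEntity(corpus, ref, found)
  .appendEvent(corpus, "propose_revision", actor, ref,
               list(field = field, new_value = newValue,
                    comment = comment))
}

#' Accept a pending revision
#'
#' Applies a queued revision to its entity.  Editor/admin with valid
#' conflict-of-interest statement only; accepting one's own revision is
#' forbidden (same rule as accepting one's own submission).  The caller
#' should re-validate afterwards — an accepted revision can put the record
#' in violation of the content rules, which the validators will report.
#'
#' @param corpus A \linkS4class{Corpus}.
#' @param ref Entity reference.
#' @param index Position of the revision in the entity's revision list.
#' @param actor Accepting editor's id.
#' @return The updated corpus with the revision applied.
#' @export
acceptRevision <- function(corpus, ref, index, actor) {
  .requireEditor(corpus, actor, "accept revisions")
  found <- .findEntity(corpus, ref)
  mod <- found$entity@moderation
  if (index < 1L || index > length(mod@revisions))
    stop("no revision at index ", index)
  rev <- mod@revisions[[index]]
  if (rev$state != "submitted") stop("revision already decided")
  if (identical(rev$proposer_id, actor))
    stop("self-acceptance error: curators may reject (but not accept) ",
         "their own revisions")
  entity <- .applyFieldValue(found$entity, rev$field_name, rev$new_value)
  rev$state <- "accepted"
  mod@revisions[[index]] <- rev
  entity@moderation <- mod
  found$entity <- entity
  corpus <- .storeEntity(corpus, ref, found)
  .appendEvent(corpus, "accept_revision", actor, ref,
               list(index = index))
}

#' Flag and unflag entities
#'
#' \code{flagEntity} marks an entity as needing editor attention (any
#' actor; idempotent) with an explanatory comment.  \code{resolveFlag}
#' clears the flag (editors only) with a resolution comment.
#'
#' @param corpus A \linkS4class{Corpus}.
#' @param ref Entity reference.
#' @param actor Acting actor id.
#' @param comment Explanation (required for resolution).
#' @return The updated corpus.
#' @rdname flagging
#' @export
flagEntity <- function(corpus, ref, actor, comment = NA) {
  found <- .findEntity(corpus, ref)
  mod <- found$entity@moderation
  mod@flagged <- TRUE
  if (!is.na(comment))
    mod <- .addComment(mod, actor, comment,
                       length(corpus@eventLog) + 1L)
  found$entity@moderation <- mod
  corpus <- .storeEntity(corpus, ref, found)
  .appendEvent(corpus, "flag", actor, ref,
               list(comment = if (is.na(comment)) NULL else comment))
}

#' @rdname flagging
#' @export
resolveFlag <- function(corpus, ref, actor, comment) {
  .requireEditor(corpus, actor, "resolve flags")
  if (missing(comment) || is.na(comment) || !nzchar(trimws(comment)))
    stop("comment-required error: flag resolution needs a comment")
  found <- .findEntity(corpus, ref)
  mod <- found$entity@moderation
  mod@flagged <- FALSE
  mod <- .addComment(mod, actor, comment, length(corpus@eventLog) + 1L)
  found$entity@moderation <- mod
  corpus <- .storeEntity(corpus, ref, found)
  .appendEvent(corpus, "resolve_flag", actor, ref,
               list(comment = comment))
}

#' Rebuild a corpus from an event log
#'
#' Folds an event log over a base corpus (registries, clock — no records)
#' by re-running each operation.  Because every operation is deterministic
#' and timestamps are sequence numbers, replaying a corpus's own log
#' reproduces it exactly.
#'
#' @param events List of event records (as in \code{eventLog(corpus)} or
#'   read by \code{\link{readEventLog}}).
#' @param base Base corpus to fold over; defaults to an empty corpus with
#'   the bundled registries.
#' @return The rebuilt \linkS4class{Corpus}.
#' @export
replayEvents <- function(events, base = emptyCorpus()) {
  corpus <- base
  for (ev in events) {
    corpus <- suppressWarnings(switch(ev$action,
      register_actor = registerActor(corpus, ev$entity_ref,
                                     ev$payload$role,
                                     if (is.null(ev$payload$coi_statement_date) ||
                                         is.na(ev$payload$coi_statement_date)) NA
                                     else ev$payload$coi_statement_date),
      submit = {
        entity <- switch(ev$payload$kind,
                         evidence = .eidFromList(ev$payload$entity),
                         assertion = .assertionFromList(ev$payload$entity),
                         variant = .variantFromList(ev$payload$entity))
        submitEntity(corpus, entity, ev$actor_id)
      },
      accept = acceptEntity(corpus, ev$entity_ref, ev$actor_id,
                            if (is.null(ev$payload$comment)) NA
                            else ev$payload$comment),
      reject = rejectEntity(corpus, ev$entity_ref, ev$actor_id,
                            ev$payload$comment),
      propose_revision = proposeRevision(corpus, ev$entity_ref,
                                         ev$payload$field,
                                         ev$payload$new_value,
                                         ev$payload$comment, ev$actor_id),
      accept_revision = acceptRevision(corpus, ev$entity_ref,
                                       ev$payload$index, ev$actor_id),
      flag = flagEntity(corpus, ev$entity_ref, ev$actor_id,
                        if (is.null(ev$payload$comment)) NA
                        else ev$payload$comment),
      resolve_flag = resolveFlag(corpus, ev$entity_ref, ev$actor_id,
                                 ev$payload$comment),
      auto_demote = corpus,   # side effect of its causal reject event
      stop("unknown event action '", ev$action, "'")))
  }
  corpus
}

#' Read and write event logs
#'
#' Event logs are newline-delimited JSON, one event per line.
#'
#' @param corpus A \linkS4class{Corpus} (write) .
#' @param path File path.
#' @return \code{readEventLog} returns the event list.
#' @rdname event-log-io
#' @export
writeEventLog <- function(corpus, path) {
  lines <- vapply(corpus@eventLog, function(ev)
    as.character(jsonlite::toJSON(ev, auto_unbox = TRUE, null = "null",
                                  digits = NA)),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname event-log-io
#' @export
readEventLog <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lapply(lines[nzchar(lines)], function(l)
    jsonlite::fromJSON(l, simplifyVector = TRUE,
                       simplifyDataFrame = FALSE))
}
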