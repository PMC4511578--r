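# Conversion between the event-centric (n-ary) and relation-centric
# (binary) representations. An event with k arguments becomes one
# denotation (typed with the event type, spanning the trigger) plus k
# relations, each from the argument to the event denotation -- the standard
# n-ary-to-n-binary decomposition. The reverse direction reassembles
# events, grouping arguments by the event denotation they point at.

#' Role-to-predicate map
#'
#' Maps event argument base roles to binary predicates. The default covers
#' the Genia Event roles: Theme -> themeOf, Cause -> causeOf. The map must
#' be injective so the reverse conversion can invert it.
#'
#' @param ... named character values extending or overriding the default,
#'   e.g. `Site = "siteOf"`.
#' @return named character vector (role base name -> predicate label).
#' @export
#' @examples
#' role_map()
#' role_map(Site = "siteOf")
role_map <- function(...) {
  m <- c(Theme = "themeOf", Cause = "causeOf")
  extra <- c(...)
  if (length(extra)) m[names(extra)] <- extra
  if (anyDuplicated(m)) {
    stop_config("role map is not injective over predicates")
  }
  m
}

#' Read a role map from a two-column TSV (role, predicate)
#'
#' @param path TSV file with no header.
#' @return named character vector.
#' @export
read_role_map <- function(path) {
  x <- read.delim(path, header = FALSE, col.names = c("role", "pred"),
                  colClasses = "character")
  do.call(role_map, as.list(setNames(x$pred, x$role)))
}

# entity ids consumed as the trigger of >= 1 event and never referenced as
# an argument target: these are represented by the event denotation itself
consumed_triggers <- function(doc) {
  if (!nrow(doc$events)) return(character())
  trig <- doc$events$trigger_id
  counts <- table(trig)
  once <- names(counts)[counts == 1]
  targets <- unlist(map(doc$events$args, "target"))
  setdiff(once, targets)
}

#' Decompose events into binary relations
#'
#' Each entity becomes a denotation; each event becomes a denotation that
#' carries the event id, the event type as its object, and the trigger's
#' span, plus one relation per argument (subject = the argument target,
#' predicate = the mapped base role, object = the event). Trigger entities
#' consumed by exactly one event are omitted as standalone denotations
#' (`keep_triggers = TRUE` restores them). Relation ids are minted R1, R2,
#' ... in document order, so conversion is deterministic.
#'
#' @param doc an [ast_document()].
#' @param rmap a [role_map()].
#' @param keep_triggers keep consumed trigger entities as denotations?
#' @return a [pa_document()].
#' @export
events_to_relations <- function(doc, rmap = role_map(),
                                keep_triggers = FALSE) {
  validate_ast(doc)
  ents <- doc$entities
  evs <- doc$events

  drop_ids <- if (keep_triggers) character() else consumed_triggers(doc)
  den_ent <- ents[!ents$id %in% drop_ids, c("id", "begin", "end", "type")]
  names(den_ent)[names(den_ent) == "type"] <- "obj"

  den_ev <- if (nrow(evs)) {
    spans <- ents[match(evs$trigger_id, ents$id), c("begin", "end")]
    tibble(id = evs$id, begin = spans$begin, end = spans$end, obj = evs$type)
  } else empty_denotations()

  rels <- if (nrow(evs)) {
    flat <- list_rbind(map(seq_len(nrow(evs)), function(i) {
      a <- evs$args[[i]]
      if (!nrow(a)) return(empty_relations()[, c("pred", "subj", "obj")])
      base <- role_base(a$role)
      unmapped <- setdiff(base, names(rmap))
      if (length(unmapped)) {
        stop_conversion(sprintf("no predicate mapped for role %s", unmapped[1]))
      }
      tibble(pred = unname(rmap[base]), subj = a$target, obj = evs$id[i])
    }))
    if (nrow(flat)) {
      tibble(id = paste0("R", seq_len(nrow(flat))), flat)
    } else empty_relations()
  } else empty_relations()

  pa_document(
    text = doc$text,
    denotations = rbind(den_ent, den_ev),
    relations = rels,
    ref = doc$ref
  )
}

#' Reassemble events from binary relations
#'
#' Denotations whose object is one of the `event_types` become events; a
#' fresh trigger entity is minted over the denotation's span (ids continue
#' above the highest existing T index). Every relation pointing at an event
#' denotation becomes an argument with the inverse-mapped role; roles that
#' repeat within one event get coordination suffixes (Theme, Theme2, ...)
#' in relation-id order. Other denotations become entities. Relations whose
#' object is not an event denotation are kept as opaque relation statements
#' with a warning. Events with no argument relations are retained: a lone
#' denotation, or an isolated causal relation, is legitimate partial
#' information.
#'
#' @param doc a [pa_document()].
#' @param rmap a [role_map()] (inverted internally).
#' @param event_types character vector of concept labels treated as event
#'   types.
#' @param strict error on a predicate missing from `rmap` (TRUE) or pass
#'   the relation through opaquely with a warning (FALSE)?
#' @return an [ast_document()].
#' @export
relations_to_events <- function(doc, rmap = role_map(),
                                event_types = genia_event_types(),
                                strict = TRUE) {
  validate_pajson(doc)
  inv <- setNames(names(rmap), rmap)
  den <- doc$denotations
  rel <- doc$relations

  is_event <- den$obj %in% event_types
  ev_den <- den[is_event, ]
  ent_den <- den[!is_event, ]

  entities <- if (nrow(ent_den)) {
    tibble(id = ent_den$id, type = ent_den$obj,
           begin = ent_den$begin, end = ent_den$end)
  } else empty_entities()
  # JSON id prefixes carry no semantics; entity ids must be T<n> in a*.
  # Renumber non-conforming entity ids deterministically.
  rename <- setNames(entities$id, entities$id)
  bad <- !grepl("^T[1-9][0-9]*$", entities$id)
  used_idx <- as.integer(sub("^T", "", entities$id[!bad]))
  next_idx <- if (length(used_idx)) max(used_idx) + 1L else 1L
  if (any(bad)) {
    fresh <- paste0("T", seq(next_idx, length.out = sum(bad)))
    rename[entities$id[bad]] <- fresh
    entities$id <- unname(rename[entities$id])
    next_idx <- next_idx + sum(bad)
  }

  # mint one trigger entity per event denotation
  trig_ids <- if (nrow(ev_den)) {
    paste0("T", seq(next_idx, length.out = nrow(ev_den)))
  } else character()
  triggers <- if (nrow(ev_den)) {
    tibble(id = trig_ids, type = ev_den$obj,
           begin = ev_den$begin, end = ev_den$end)
  } else empty_entities()

  ev_ids <- ev_den$id
  ev_new_ids <- paste0("E", seq_len(nrow(ev_den)))
  id_map <- c(rename, setNames(ev_new_ids, ev_ids))

  extra <- character()
  arg_rel <- rel[rel$obj %in% ev_ids, , drop = FALSE]
  other <- rel[!rel$obj %in% ev_ids, , drop = FALSE]
  if (nrow(other)) {
    warn(sprintf("%d relation(s) do not target an event denotation; kept as opaque statements",
                 nrow(other)), class = "geniakb_opaque_statement")
    extra <- sprintf("%s\t%s Subj:%s Obj:%s", other$id, other$pred,
                     unname(id_map[other$subj]), unname(id_map[other$obj]))
  }
  unmapped <- setdiff(arg_rel$pred, names(inv))
  if (length(unmapped)) {
    if (strict) {
      stop_conversion(sprintf("no role mapped for predicate %s", unmapped[1]))
    }
    drop <- arg_rel$pred %in% unmapped
    warn(sprintf("%d relation(s) with unmapped predicates kept as opaque statements",
                 sum(drop)), class = "geniakb_opaque_statement")
    extra <- c(extra, sprintf("%s\t%s Subj:%s Obj:%s",
                              arg_rel$id[drop], arg_rel$pred[drop],
                              unname(id_map[arg_rel$subj[drop]]),
                              unname(id_map[arg_rel$obj[drop]])))
    arg_rel <- arg_rel[!drop, , drop = FALSE]
  }

  events <- if (nrow(ev_den)) {
    args_by_ev <- map(ev_ids, function(eid) {
      a <- arg_rel[arg_rel$obj == eid, , drop = FALSE]
      if (!nrow(a)) return(empty_args())
      ord <- order(suppressWarnings(as.integer(sub("^[A-Za-z]+", "", a$id))),
                   a$id)
      a <- a[ord, , drop = FALSE]
      base <- unname(inv[a$pred])
      idx <- stats::ave(seq_along(base), base, FUN = seq_along)
      tibble(role = ifelse(idx == 1, base, paste0(base, idx)),
             target = unname(id_map[a$subj]))
    })
    tibble(id = ev_new_ids, type = ev_den$obj, trigger_id = trig_ids,
           args = args_by_ev)
  } else empty_events()

  ast_document(
    text = doc$text,
    entities = rbind(entities, triggers),
    events = events,
    ref = doc$ref,
    extra = extra
  )
}

#' Genia Event type labels
#'
#' The event concepts of the GE task schema: five simple event types whose
#' themes are proteins, binding (1-3 protein themes), protein modification
#' types, and the three recursive regulation types that admit event themes
#' and cause arguments.
#'
#' @return character vector of event type labels.
#' @export
genia_event_types <- function() {
  c("Gene_expression", "Transcription", "Localization",
    "Protein_catabolism", "Phosphorylation", "Binding",
    "Protein_modification", "Acetylation", "Deacetylation", "Ubiquitination",
    "Regulation", "Positive_regulation", "Negative_regulation")
}
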