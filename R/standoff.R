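# BioNLP a* standoff format: event-centric annotation held apart from the
# text it describes, anchored by caret (between-character) offsets.
#
# Grammar handled here (tab is the primary delimiter):
#   T<i><TAB>Type begin end[<TAB>covered text]   entity annotation
#   E<i><TAB>Type:Ttrig Role:Id Role2:Id ...     event annotation
# Offsets are counted in Unicode code points, end-exclusive. Statements with
# any other ID prefix (relations, modifications, comments, equivs) are kept
# as opaque lines and re-emitted verbatim.

#' Document reference
#'
#' Identifies the source of a document: a source database name, a source
#' document id, and a division index (documents served in parts count their
#' divisions from 0). The reference is embedded in span IRIs, so graphs
#' built from the same documents are comparable.
#'
#' @param sourcedb source database name, e.g. "PMC".
#' @param sourceid source document identifier.
#' @param divid division index, default 0.
#' @return a `geniakb_docref` list.
#' @export
#' @examples
#' doc_ref("PMC", "1359074", 0)
doc_ref <- function(sourcedb = "synth", sourceid = "0", divid = 0) {
  structure(
    list(sourcedb = as.character(sourcedb),
         sourceid = as.character(sourceid),
         divid = as.integer(divid)),
    class = "geniakb_docref"
  )
}

empty_entities <- function() {
  tibble(id = character(), type = character(),
         begin = integer(), end = integer())
}

empty_events <- function() {
  tibble(id = character(), type = character(), trigger_id = character(),
         args = list())
}

empty_args <- function() {
  tibble(role = character(), target = character())
}

#' Construct an event-centric standoff document
#'
#' @param text document text (single UTF-8 string).
#' @param entities tibble with columns `id`, `type`, `begin`, `end`; one row
#'   per entity annotation (text-bound mentions: proteins and event triggers).
#' @param events tibble with columns `id`, `type`, `trigger_id`, and a list
#'   column `args` of tibbles with columns `role`, `target` (argument order
#'   and literal role labels such as `Theme2` preserved).
#' @param ref a [doc_ref()].
#' @param extra character vector of opaque annotation lines carried through
#'   verbatim (unknown ID prefixes).
#' @param validate run [validate_ast()]? Default TRUE.
#' @return an `ast_document`.
#' @export
ast_document <- function(text, entities = empty_entities(),
                         events = empty_events(), ref = doc_ref(),
                         extra = character(), validate = TRUE) {
  entities <- as_tibble(entities)
  events <- as_tibble(events)
  if (nrow(entities)) {
    entities$begin <- as.integer(entities$begin)
    entities$end <- as.integer(entities$end)
  }
  doc <- structure(
    list(text = as.character(text), entities = entities, events = events,
         ref = ref, extra = as.character(extra)),
    class = "ast_document"
  )
  if (validate) validate_ast(doc)
  doc
}

#' @export
print.ast_document <- function(x, ...) {
  cat(sprintf("<ast_document %s/%s/%d: %d chars, %d entities, %d events>\n",
              x$ref$sourcedb, x$ref$sourceid, x$ref$divid,
              nchar(x$text), nrow(x$entities), nrow(x$events)))
  invisible(x)
}

#' Validate a standoff document
#'
#' Checks span bounds (0 <= begin < end <= nchar(text)), id uniqueness and
#' shape, and referential integrity: every event trigger and every argument
#' target must resolve to an entity or event in the same document.
#'
#' @param doc an [ast_document()].
#' @return `doc`, invisibly.
#' @export
validate_ast <- function(doc) {
  ents <- doc$entities
  evs <- doc$events
  n <- nchar(doc$text)

  ids <- c(ents$id, evs$id)
  if (anyDuplicated(ids)) {
    stop_validation(sprintf("duplicate annotation id: %s",
                            ids[duplicated(ids)][1]))
  }
  if (nrow(ents)) {
    bad_id <- !grepl("^T[1-9][0-9]*$", ents$id)
    if (any(bad_id)) {
      stop_validation(sprintf("malformed entity id: %s", ents$id[bad_id][1]))
    }
    bad <- ents$begin < 0 | ents$begin >= ents$end | ents$end > n
    if (any(bad)) {
      stop_bounds(sprintf("entity %s span [%d,%d) outside text of length %d",
                          ents$id[bad][1], ents$begin[bad][1],
                          ents$end[bad][1], n))
    }
  }
  if (nrow(evs)) {
    bad_id <- !grepl("^E[1-9][0-9]*$", evs$id)
    if (any(bad_id)) {
      stop_validation(sprintf("malformed event id: %s", evs$id[bad_id][1]))
    }
    missing_trig <- setdiff(evs$trigger_id, ents$id)
    if (length(missing_trig)) {
      stop_reference(sprintf("event trigger %s does not resolve",
                             missing_trig[1]))
    }
    targets <- unlist(map(evs$args, "target"))
    dangling <- setdiff(targets, ids)
    if (length(dangling)) {
      stop_reference(sprintf("argument target %s does not resolve",
                             dangling[1]))
    }
  }
  invisible(doc)
}

#' Parse a* annotation lines
#'
#' Parses the standoff statements against the given text. T-statements are
#' space-delimited (type, begin, end) triples; E-statements are
#' space-delimited colon-joined (role, id) pairs whose first pair is
#' (event type, trigger id). An optional tab-separated trailing field on a
#' T-line (the covered text, emitted by some writers) is accepted and
#' ignored. Lines with other ID prefixes are preserved opaquely with a
#' warning.
#'
#' @param lines character vector of annotation lines.
#' @param text the document text the offsets refer to.
#' @param ref a [doc_ref()].
#' @param validate check document-level invariants (references, bounds,
#'   duplicates) after parsing? Default TRUE; with FALSE only the line
#'   grammar is enforced and [validate_ast()] can be run separately.
#' @return an [ast_document()].
#' @export
#' @examples
#' parse_ast(c("T1\tProtein 0 4"), "MyD8 induces")
parse_ast <- function(lines, text, ref = doc_ref(), validate = TRUE) {
  lines <- lines[nzchar(trimws(lines))]
  ents <- list()
  evs <- list()
  extra <- character()

  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    tab <- regexpr("\t", ln, fixed = TRUE)
    if (tab < 0) stop_parse("missing tab delimiter", i)
    id <- substr(ln, 1, tab - 1)
    body <- sub("\t.*$", "", substr(ln, tab + 1, nchar(ln)))
    prefix <- substr(id, 1, 1)

    if (prefix == "T") {
      fields <- strsplit(body, " ", fixed = TRUE)[[1]]
      if (length(fields) != 3) {
        stop_parse(sprintf("entity statement is not a triple: %s", body), i)
      }
      if (!grepl("^[0-9]+$", fields[2]) || !grepl("^[0-9]+$", fields[3])) {
        stop_parse(sprintf("non-integer offset in %s", body), i)
      }
      ents[[length(ents) + 1]] <- tibble(
        id = id, type = fields[1],
        begin = as.integer(fields[2]), end = as.integer(fields[3])
      )
    } else if (prefix == "E") {
      fields <- strsplit(body, " ", fixed = TRUE)[[1]]
      pairs <- str_split_fixed(fields, ":", 2)
      if (any(!nzchar(pairs[, 1])) || any(!nzchar(pairs[, 2]))) {
        stop_parse(sprintf("malformed role:id pair in %s", body), i)
      }
      evs[[length(evs) + 1]] <- tibble(
        id = id, type = pairs[1, 1], trigger_id = pairs[1, 2],
        args = list(tibble(role = pairs[-1, 1], target = pairs[-1, 2]))
      )
    } else {
      warn(sprintf("preserving unhandled statement %s as an opaque line", id),
           class = "geniakb_opaque_statement")
      extra <- c(extra, ln)
    }
  }

  ast_document(
    text = text,
    entities = if (length(ents)) list_rbind(ents) else empty_entities(),
    events = if (length(evs)) list_rbind(evs) else empty_events(),
    ref = ref, extra = extra, validate = validate
  )
}

#' Serialize a document to a* annotation lines
#'
#' Inverse of [parse_ast()]: emits T-lines, then E-lines, then any opaque
#' lines, in document order. Round-tripping a parsed document reproduces it
#' exactly (up to the order of independent statements, which this writer
#' keeps stable).
#'
#' @param doc an [ast_document()].
#' @return character vector of annotation lines.
#' @export
serialize_ast <- function(doc) {
  validate_ast(doc)
  t_lines <- if (nrow(doc$entities)) {
    sprintf("%s\t%s %d %d", doc$entities$id, doc$entities$type,
            doc$entities$begin, doc$entities$end)
  } else character()
  e_lines <- if (nrow(doc$events)) {
    map_chr(seq_len(nrow(doc$events)), function(i) {
      ev <- doc$events[i, ]
      args <- ev$args[[1]]
      body <- paste0(ev$type, ":", ev$trigger_id)
      if (nrow(args)) {
        body <- paste(c(body, paste0(args$role, ":", args$target)),
                      collapse = " ")
      }
      paste0(ev$id, "\t", body)
    })
  } else character()
  c(t_lines, e_lines, doc$extra)
}

#' Read a standoff document from disk
#'
#' Two dialects are supported: a single-stream `.ann` file holding all
#' statements, and the split `.a1` (entities) / `.a2` (triggers + events)
#' convention. By default the dialect is chosen by which files exist next
#' to the text file.
#'
#' @param txt path to the `.txt` file (UTF-8).
#' @param dialect "auto", "ann", or "a12".
#' @param ref a [doc_ref()]; by default derived from the file name.
#' @return an [ast_document()].
#' @export
read_ast <- function(txt, dialect = c("auto", "ann", "a12"), ref = NULL) {
  dialect <- match.arg(dialect)
  base <- sub("\\.txt$", "", txt)
  if (is.null(ref)) ref <- doc_ref("local", basename(base), 0)
  text <- paste(readLines(txt, encoding = "UTF-8", warn = FALSE),
                collapse = "\n")
  if (dialect == "auto") {
    dialect <- if (file.exists(paste0(base, ".ann"))) "ann" else "a12"
  }
  lines <- if (dialect == "ann") {
    readLines(paste0(base, ".ann"), encoding = "UTF-8", warn = FALSE)
  } else {
    c(readLines(paste0(base, ".a1"), encoding = "UTF-8", warn = FALSE),
      if (file.exists(paste0(base, ".a2"))) {
        readLines(paste0(base, ".a2"), encoding = "UTF-8", warn = FALSE)
      })
  }
  parse_ast(lines, text, ref = ref)
}

#' Write a standoff document to disk
#'
#' @param doc an [ast_document()].
#' @param base output path without extension; writes `<base>.txt` plus
#'   either `<base>.ann` or `<base>.a1`/`<base>.a2`.
#' @param dialect "ann" (single stream) or "a12" (entities that trigger no
#'   event go to `.a1`; triggers and events go to `.a2`).
#' @return `base`, invisibly.
#' @export
write_ast <- function(doc, base, dialect = c("ann", "a12")) {
  dialect <- match.arg(dialect)
  writeLines(doc$text, paste0(base, ".txt"), useBytes = TRUE)
  lines <- serialize_ast(doc)
  if (dialect == "ann") {
    writeLines(lines, paste0(base, ".ann"), useBytes = TRUE)
  } else {
    triggers <- unique(doc$events$trigger_id)
    is_t <- startsWith(lines, "T")
    t_ids <- sub("\t.*$", "", lines[is_t])
    writeLines(lines[is_t][!t_ids %in% triggers], paste0(base, ".a1"),
               useBytes = TRUE)
    writeLines(c(lines[is_t][t_ids %in% triggers], lines[!is_t]),
               paste0(base, ".a2"), useBytes = TRUE)
  }
  invisible(base)
}
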