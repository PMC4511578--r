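# RDF export under a minimal text-annotation vocabulary (TAO). Each
# denotation introduces a context entity: an instance typed both with its
# concept (in the task namespace) and tao:Context_entity, and connected by
# tao:denoted_by to a dereferenceable span IRI that embeds the document
# reference and the caret offsets. Each relation becomes a single statement
# in the task namespace (genia:themeOf, genia:causeOf, ...).

RDF_TYPE <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"

#' Namespace configuration
#'
#' IRIs under which the knowledge base is built. `tao` holds the annotation
#' vocabulary (Context_entity, denoted_by), `task` the event-schema
#' concepts and predicates, `span_base` the document/span IRI scheme, and
#' `inst_base` the per-annotation instance IRIs.
#'
#' @param tao,task,span_base,inst_base absolute IRIs; `tao` and `task` must
#'   end in "/" or "#".
#' @return a `geniakb_ns` list.
#' @export
ns_config <- function(tao = "http://pubannotation.org/ontology/tao#",
                      task = "http://bionlp.dbcls.jp/genia#",
                      span_base = "http://pubannotation.org",
                      inst_base = "http://bionlp.dbcls.jp/inst") {
  for (p in c(tao, task)) {
    if (!grepl("^[a-z][a-z0-9+.-]*://", p) || !grepl("[/#]$", p)) {
      stop_config(sprintf("namespace prefix must be an absolute IRI ending in / or #: %s", p))
    }
  }
  for (p in c(span_base, inst_base)) {
    if (!grepl("^[a-z][a-z0-9+.-]*://", p)) {
      stop_config(sprintf("base must be an absolute IRI: %s", p))
    }
  }
  structure(list(tao = tao, task = task,
                 span_base = sub("/$", "", span_base),
                 inst_base = sub("/$", "", inst_base)),
            class = "geniakb_ns")
}

#' Read a namespace configuration from a YAML-style key: value file
#'
#' Recognized keys: tao, task, span_base, inst_base; unknown keys are
#' rejected.
#'
#' @param path config file path.
#' @return a [ns_config()].
#' @export
read_ns_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  m <- str_match(lines, "^\\s*([A-Za-z_]+)\\s*:\\s*(\\S+)\\s*$")
  if (anyNA(m[, 1])) stop_config(sprintf("cannot parse config line: %s",
                                         lines[is.na(m[, 1])][1]))
  kv <- setNames(m[, 3], m[, 2])
  unknown <- setdiff(names(kv), c("tao", "task", "span_base", "inst_base"))
  if (length(unknown)) {
    stop_config(sprintf("unknown config key: %s", unknown[1]))
  }
  do.call(ns_config, as.list(kv))
}

#' Span IRI
#'
#' Dereferenceable IRI for a text span of a document:
#' `{base}/docs/sourcedb/{db}/sourceid/{id}/divs/{div}/spans/{begin}-{end}`.
#' Distinct spans of a document get distinct IRIs.
#'
#' @param ref a [doc_ref()].
#' @param begin,end caret offsets (integer vectors recycle together).
#' @param cfg a [ns_config()].
#' @return character vector of IRIs.
#' @export
#' @examples
#' span_iri(doc_ref("PMC", "1359074", 0), 0, 4)
span_iri <- function(ref, begin, end, cfg = ns_config()) {
  sprintf("%s/docs/sourcedb/%s/sourceid/%s/divs/%d/spans/%d-%d",
          cfg$span_base, ref$sourcedb, ref$sourceid, ref$divid,
          as.integer(begin), as.integer(end))
}

inst_iri <- function(ref, id, cfg = ns_config()) {
  sprintf("%s/%s-%s-%d#%s", cfg$inst_base, ref$sourcedb, ref$sourceid,
          ref$divid, id)
}

#' Triple graph
#'
#' A named set of (subject, predicate, object) IRI triples with set
#' semantics: duplicates collapse and iteration order is the sorted order,
#' so graph equality is tibble equality.
#'
#' @param triples tibble with character columns `subject`, `predicate`,
#'   `object`.
#' @param name graph label.
#' @return a `triple_graph`.
#' @export
triple_graph <- function(triples = NULL, name = "") {
  if (is.null(triples)) {
    triples <- tibble(subject = character(), predicate = character(),
                      object = character())
  }
  triples <- as_tibble(triples)[c("subject", "predicate", "object")]
  triples <- arrange(distinct(triples), subject, predicate, object)
  structure(list(name = name, triples = triples), class = "triple_graph")
}

#' @export
print.triple_graph <- function(x, ...) {
  cat(sprintf("<triple_graph%s: %d triples>\n",
              if (nzchar(x$name)) paste0(" ", x$name) else "",
              nrow(x$triples)))
  invisible(x)
}

#' Union of triple graphs
#'
#' Set union; order of arguments does not matter.
#'
#' @param ... `triple_graph` objects or a single list of them.
#' @param name label for the union.
#' @return a [triple_graph()].
#' @export
graph_union <- function(..., name = "") {
  gs <- list(...)
  if (length(gs) == 1 && !inherits(gs[[1]], "triple_graph")) gs <- gs[[1]]
  triple_graph(list_rbind(map(gs, "triples")), name = name)
}

#' Convert a relation-centric document to RDF triples
#'
#' Per denotation d three triples are emitted: (inst(d), rdf:type,
#' task:obj), (inst(d), rdf:type, tao:Context_entity), and (inst(d),
#' tao:denoted_by, span IRI). Per relation one triple: (inst(subj),
#' task:pred, inst(obj)). Instance IRIs are deterministic functions of the
#' document reference and the denotation id, so graphs built independently
#' over the same documents share span IRIs but never instance IRIs across
#' different annotation sets. Only denoted_by is emitted; its inverse
#' (denote) is derivable and kept out of the graph.
#'
#' @param doc a [pa_document()].
#' @param cfg a [ns_config()].
#' @param name graph label.
#' @return a [triple_graph()] with `3 * n_denotations + n_relations`
#'   triples.
#' @export
document_to_triples <- function(doc, cfg = ns_config(), name = "") {
  validate_pajson(doc)
  d <- doc$denotations
  r <- doc$relations
  parts <- list()
  if (nrow(d)) {
    inst <- inst_iri(doc$ref, d$id, cfg)
    parts$types <- tibble(subject = inst, predicate = RDF_TYPE,
                          object = paste0(cfg$task, d$obj))
    parts$ctx <- tibble(subject = inst, predicate = RDF_TYPE,
                        object = paste0(cfg$tao, "Context_entity"))
    parts$spans <- tibble(subject = inst,
                          predicate = paste0(cfg$tao, "denoted_by"),
                          object = span_iri(doc$ref, d$begin, d$end, cfg))
  }
  if (nrow(r)) {
    parts$rels <- tibble(subject = inst_iri(doc$ref, r$subj, cfg),
                         predicate = paste0(cfg$task, r$pred),
                         object = inst_iri(doc$ref, r$obj, cfg))
  }
  triple_graph(if (length(parts)) list_rbind(parts) else NULL, name = name)
}

#' Build one graph from a corpus of standoff documents
#'
#' Convenience pipeline: decompose each document's events into relations
#' and union the per-document triples.
#'
#' @param docs list of [ast_document()]s.
#' @param cfg a [ns_config()].
#' @param rmap a [role_map()].
#' @param name graph label.
#' @return a [triple_graph()].
#' @export
corpus_to_graph <- function(docs, cfg = ns_config(), rmap = role_map(),
                            name = "") {
  graph_union(map(docs, function(d) {
    document_to_triples(events_to_relations(d, rmap), cfg)
  }), name = name)
}

escape_ttl <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  gsub(">", "\\>", x, fixed = TRUE)
}

#' Serialize a triple graph
#'
#' N-Triples: one sorted `<s> <p> <o> .` statement per line. Turtle: prefix
#' declarations for the configured namespaces plus rdf:, then sorted
#' statements using prefixed names where a term falls under a declared
#' prefix. Both are read back by [read_graph()] to an equal set.
#'
#' @param g a [triple_graph()].
#' @param format "ntriples" or "turtle".
#' @param path optional output file.
#' @param cfg a [ns_config()] (used for Turtle prefixes).
#' @return character vector of lines, invisibly when `path` is given.
#' @export
serialize_graph <- function(g, format = c("ntriples", "turtle"),
                            path = NULL, cfg = ns_config()) {
  format <- match.arg(format)
  tr <- g$triples
  if (format == "ntriples") {
    lines <- if (nrow(tr)) {
      sprintf("<%s> <%s> <%s> .", escape_ttl(tr$subject),
              escape_ttl(tr$predicate), escape_ttl(tr$object))
    } else character()
  } else {
    prefixes <- c(rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
                  tao = cfg$tao, genia = cfg$task)
    shorten <- function(iri) {
      out <- sprintf("<%s>", escape_ttl(iri))
      for (p in names(prefixes)) {
        ns <- prefixes[[p]]
        hit <- startsWith(iri, ns)
        local <- substr(iri, nchar(ns) + 1, nchar(iri))
        ok <- hit & grepl("^[A-Za-z_][A-Za-z0-9_-]*$", local)
        out[ok] <- paste0(p, ":", local[ok])
      }
      out
    }
    header <- sprintf("@prefix %s: <%s> .", names(prefixes), prefixes)
    body <- if (nrow(tr)) {
      sprintf("%s %s %s .", shorten(tr$subject), shorten(tr$predicate),
              shorten(tr$object))
    } else character()
    lines <- c(header, "", body)
  }
  if (!is.null(path)) {
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(lines))
  }
  lines
}

#' Read a triple graph from N-Triples or Turtle
#'
#' Accepts the output of [serialize_graph()]: full-IRI statements, plus
#' `@prefix` declarations and prefixed names for Turtle. Format is chosen
#' by file extension (.nt / .ttl) unless given.
#'
#' @param path file path (or character vector of lines via `lines`).
#' @param format "ntriples" or "turtle"; default from extension.
#' @param lines character lines, used instead of `path` when given.
#' @param name graph label.
#' @return a [triple_graph()].
#' @export
read_graph <- function(path = NULL, format = NULL, lines = NULL, name = "") {
  if (is.null(lines)) lines <- readLines(path, warn = FALSE)
  if (is.null(format)) {
    format <- if (!is.null(path) && grepl("\\.ttl$", path)) "turtle" else "ntriples"
  }
  format <- match.arg(format, c("ntriples", "turtle"))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  prefixes <- character()
  if (format == "turtle") {
    is_pref <- startsWith(lines, "@prefix")
    m <- str_match(lines[is_pref],
                   "^@prefix\\s+([A-Za-z][A-Za-z0-9_-]*):\\s+<([^>]+)>\\s+\\.$")
    prefixes <- setNames(m[, 3], m[, 2])
    lines <- lines[!is_pref]
  }
  if (!length(lines)) return(triple_graph(name = name))
  m <- str_match(lines, "^(\\S+)\\s+(\\S+)\\s+(\\S+)\\s+\\.$")
  if (anyNA(m[, 1])) {
    stop_parse(sprintf("cannot parse statement: %s", lines[is.na(m[, 1])][1]))
  }
  expand <- function(term) {
    iri <- ifelse(startsWith(term, "<"),
                  gsub("\\>", ">", gsub("\\\\", "\\", substr(term, 2, nchar(term) - 1),
                                        fixed = TRUE), fixed = TRUE),
                  NA_character_)
    pn <- is.na(iri)
    if (any(pn)) {
      if (any(term[pn] == "a")) {
        iri[pn & term == "a"] <- RDF_TYPE
        pn <- is.na(iri)
      }
      parts <- str_match(term[pn], "^([A-Za-z][A-Za-z0-9_-]*):(.*)$")
      if (anyNA(parts[, 1]) || !all(parts[, 2] %in% names(prefixes))) {
        stop_parse(sprintf("cannot resolve term: %s", term[pn][1]))
      }
      iri[pn] <- paste0(prefixes[parts[, 2]], parts[, 3])
    }
    iri
  }
  triple_graph(tibble(subject = expand(m[, 2]), predicate = expand(m[, 3]),
                      object = expand(m[, 4])), name = name)
}
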