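# Relation-centric JSON annotation (PubAnnotation-style): a document is
# {text, sourcedb, sourceid, divid, denotations, relations}. A denotation
# says a text span denotes an object of some concept; a relation links two
# denotations by a binary predicate (subject, predicate, object). Events
# appear decomposed: one denotation for the event plus one relation per
# argument.

empty_denotations <- function() {
  tibble(id = character(), begin = integer(), end = integer(),
         obj = character())
}

empty_relations <- function() {
  tibble(id = character(), pred = character(), subj = character(),
         obj = character())
}

#' Construct a relation-centric JSON document
#'
#' @param text document text.
#' @param denotations tibble with columns `id`, `begin`, `end`, `obj`.
#' @param relations tibble with columns `id`, `pred`, `subj`, `obj`; `subj`
#'   and `obj` are denotation ids.
#' @param ref a [doc_ref()].
#' @param validate run [validate_pajson()]? Default TRUE.
#' @return a `pa_document`.
#' @export
pa_document <- function(text, denotations = empty_denotations(),
                        relations = empty_relations(), ref = doc_ref(),
                        validate = TRUE) {
  denotations <- as_tibble(denotations)
  relations <- as_tibble(relations)
  if (nrow(denotations)) {
    denotations$begin <- as.integer(denotations$begin)
    denotations$end <- as.integer(denotations$end)
  }
  doc <- structure(
    list(text = as.character(text), denotations = denotations,
         relations = relations, ref = ref),
    class = "pa_document"
  )
  if (validate) validate_pajson(doc)
  doc
}

#' @export
print.pa_document <- function(x, ...) {
  cat(sprintf("<pa_document %s/%s/%d: %d chars, %d denotations, %d relations>\n",
              x$ref$sourcedb, x$ref$sourceid, x$ref$divid,
              nchar(x$text), nrow(x$denotations), nrow(x$relations)))
  invisible(x)
}

#' Validate a relation-centric document
#'
#' Checks span bounds, denotation id uniqueness, and that every relation
#' endpoint resolves to a denotation with subject distinct from object.
#'
#' @param doc a [pa_document()].
#' @return `doc`, invisibly.
#' @export
validate_pajson <- function(doc) {
  d <- doc$denotations
  r <- doc$relations
  n <- nchar(doc$text)
  if (anyDuplicated(d$id)) {
    stop_validation(sprintf("duplicate denotation id: %s",
                            d$id[duplicated(d$id)][1]))
  }
  if (nrow(d)) {
    bad <- d$begin < 0 | d$begin >= d$end | d$end > n
    if (any(bad)) {
      stop_bounds(sprintf("denotation %s span [%d,%d) outside text of length %d",
                          d$id[bad][1], d$begin[bad][1], d$end[bad][1], n))
    }
  }
  if (nrow(r)) {
    if (anyDuplicated(r$id)) {
      stop_validation(sprintf("duplicate relation id: %s",
                              r$id[duplicated(r$id)][1]))
    }
    dangling <- setdiff(c(r$subj, r$obj), d$id)
    if (length(dangling)) {
      stop_reference(sprintf("relation endpoint %s does not resolve",
                             dangling[1]))
    }
    loops <- r$subj == r$obj
    if (any(loops)) {
      stop_validation(sprintf("relation %s relates %s to itself",
                              r$id[loops][1], r$subj[loops][1]))
    }
  }
  invisible(doc)
}

#' Parse a relation-centric JSON document
#'
#' Accepts a JSON string or a file path. The `relations` member is optional
#' (missing means no relations); `text` and `denotations` are required.
#' Schema problems raise a validation error naming the offending member;
#' dangling relation endpoints raise a reference error.
#'
#' @param json JSON string, or path to a `.json` file.
#' @return a [pa_document()].
#' @export
parse_pajson <- function(json) {
  if (length(json) == 1 && !grepl("[{]", json) && file.exists(json)) {
    json <- paste(readLines(json, encoding = "UTF-8", warn = FALSE),
                  collapse = "\n")
  }
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  if (is.null(x$text)) stop_validation("missing required member: text")
  if (is.null(x$denotations)) {
    stop_validation("missing required member: denotations")
  }
  den <- if (length(x$denotations)) {
    list_rbind(map(x$denotations, function(d) {
      if (is.null(d$id) || is.null(d$span) || is.null(d$obj) ||
          is.null(d$span$begin) || is.null(d$span$end)) {
        stop_validation("malformed member of denotations (need id, span{begin,end}, obj)")
      }
      tibble(id = d$id, begin = as.integer(d$span$begin),
             end = as.integer(d$span$end), obj = d$obj)
    }))
  } else empty_denotations()
  rel <- if (length(x$relations)) {
    list_rbind(map(x$relations, function(r) {
      if (is.null(r$id) || is.null(r$pred) || is.null(r$subj) ||
          is.null(r$obj)) {
        stop_validation("malformed member of relations (need id, pred, subj, obj)")
      }
      tibble(id = r$id, pred = r$pred, subj = r$subj, obj = r$obj)
    }))
  } else empty_relations()
  pa_document(
    text = x$text, denotations = den, relations = rel,
    ref = doc_ref(x$sourcedb %||% "local", x$sourceid %||% "0",
                  x$divid %||% 0)
  )
}

#' Serialize a relation-centric document to JSON
#'
#' Deterministic: fixed key order (sourcedb, sourceid, divid, text,
#' denotations, relations), arrays in document order, and an explicit
#' `"relations": []` when there are none, so equal documents serialize to
#' equal bytes.
#'
#' @param doc a [pa_document()].
#' @param path optional file to write to.
#' @return the JSON string, invisibly when `path` is given.
#' @export
serialize_pajson <- function(doc, path = NULL) {
  validate_pajson(doc)
  d <- doc$denotations
  r <- doc$relations
  out <- list(
    sourcedb = doc$ref$sourcedb,
    sourceid = doc$ref$sourceid,
    divid = doc$ref$divid,
    text = doc$text,
    denotations = map(seq_len(nrow(d)), function(i) {
      list(id = d$id[i],
           span = list(begin = d$begin[i], end = d$end[i]),
           obj = d$obj[i])
    }),
    relations = map(seq_len(nrow(r)), function(i) {
      list(id = r$id[i], pred = r$pred[i], subj = r$subj[i], obj = r$obj[i])
    })
  )
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, pretty = TRUE)
  json <- as.character(json)
  if (!is.null(path)) {
    writeLines(json, path, useBytes = TRUE)
    return(invisible(json))
  }
  json
}
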