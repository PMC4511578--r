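# Fixture builders and comparison helpers shared across the suite. All
# fixtures are constructed in code.

# Nested-regulation annotation of "MTb induces NFAT5 gene expression via
# the MyD88-dependent signaling cascade": the expression of NFAT5 is the
# theme of a regulation (signaling) which is the theme of another
# regulation (dependent) whose cause is MyD88. The deep variant.
fig_chain_doc <- function() {
  txt <- "NFAT5 expression signaling dependent MyD88"
  parse_ast(c(
    "T1\tProtein 0 5",
    "T2\tGene_expression 6 16",
    "T3\tPositive_regulation 17 26",
    "T4\tRegulation 27 36",
    "T5\tProtein 37 42",
    "E1\tGene_expression:T2 Theme:T1",
    "E2\tPositive_regulation:T3 Theme:E1",
    "E3\tRegulation:T4 Theme:E2 Cause:T5"
  ), txt, ref = doc_ref("synth", "chain", 0))
}

# The flat variant of the same assertion: no second regulation level; the
# cause attaches directly to the first regulation event.
fig_flat_doc <- function() {
  txt <- "NFAT5 expression signaling dependent MyD88"
  parse_ast(c(
    "T1\tProtein 0 5",
    "T2\tGene_expression 6 16",
    "T3\tPositive_regulation 17 26",
    "T5\tProtein 37 42",
    "E1\tGene_expression:T2 Theme:T1",
    "E2\tPositive_regulation:T3 Theme:E1 Cause:T5"
  ), txt, ref = doc_ref("synth", "chain", 0))
}

# One binding event over two proteins (collective), or the same two
# proteins split into two separate binding events (distributive).
binding_doc <- function(collective = TRUE) {
  txt <- "GENE1 GENE2 binding binds"
  ev <- if (collective) {
    c("E1\tBinding:T3 Theme:T1 Theme2:T2")
  } else {
    c("E1\tBinding:T3 Theme:T1", "E2\tBinding:T4 Theme:T2")
  }
  parse_ast(c(
    "T1\tProtein 0 5",
    "T2\tProtein 6 11",
    "T3\tBinding 12 19",
    "T4\tBinding 20 25",
    ev
  ), txt, ref = doc_ref("synth", "bind", 0))
}

# small corpora for property loops; sized so each takes well under a
# second to generate and export
small_corpus <- function(seed, n_docs = 3, events_per_doc = 4) {
  generate_gold(corpus_config(n_docs = n_docs,
                              events_per_doc = events_per_doc,
                              seed = seed))
}

# set equality of result-set tibbles, ignoring attributes and row order
expect_same_rows <- function(a, b) {
  a <- dplyr::arrange_all(tibble::as_tibble(as.data.frame(a)))
  b <- dplyr::arrange_all(tibble::as_tibble(as.data.frame(b)))
  expect_equal(a, b, ignore_attr = TRUE)
}

# canonical multiset signature of a document's events, invariant under id
# renaming and trigger re-minting: (type, trigger span, multiset of
# (base role, target signature)), targets resolved recursively
event_signatures <- function(doc) {
  ent_sig <- function(id) {
    e <- doc$entities[doc$entities$id == id, ]
    sprintf("ent(%s,%d,%d)", e$type, e$begin, e$end)
  }
  memo <- new.env()
  ev_sig <- function(id) {
    if (!is.null(memo[[id]])) return(memo[[id]])
    i <- which(doc$events$id == id)
    ev <- doc$events[i, ]
    trig <- doc$entities[doc$entities$id == ev$trigger_id, ]
    args <- ev$args[[1]]
    arg_sigs <- sort(vapply(seq_len(nrow(args)), function(k) {
      tgt <- args$target[k]
      tsig <- if (startsWith(tgt, "E")) ev_sig(tgt) else ent_sig(tgt)
      sprintf("%s=%s", role_base(args$role[k]), tsig)
    }, character(1)))
    out <- sprintf("ev(%s,%d,%d,[%s])", ev$type, trig$begin, trig$end,
                   paste(arg_sigs, collapse = ";"))
    memo[[id]] <- out
    out
  }
  sort(vapply(doc$events$id, ev_sig, character(1)))
}
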