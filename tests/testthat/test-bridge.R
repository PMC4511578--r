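test_that("an event with Theme and Cause decomposes into two relations", {
  doc <- parse_ast(c(
    "T1\tProtein 0 5",
    "T2\tNegative_regulation 6 14",
    "T3\tGene_expression 15 25",
    "T4\tProtein 29 34",
    "E2\tGene_expression:T3 Theme:T4",
    "E1\tNegative_regulation:T2 Theme:E2 Cause:T1"
  ), "GENE1 inhibits expression of GENE2")
  pa <- events_to_relations(doc)

  r <- pa$relations[pa$relations$obj == "E1", ]
  expect_equal(nrow(r), 2)
  expect_setequal(paste(r$pred, r$subj), c("themeOf E2", "causeOf T1"))
  # event denotation carries the trigger span and the event type
  d <- pa$denotations[pa$denotations$id == "E1", ]
  expect_equal(d$obj, "Negative_regulation")
  expect_equal(c(d$begin, d$end), c(6L, 14L))
  # consumed triggers vanish as standalone denotations
  expect_false(any(pa$denotations$id %in% c("T2", "T3")))
  expect_true(all(c("T1", "T4") %in% pa$denotations$id))
})

test_that("zero-argument events and coordinated themes convert correctly", {
  doc <- parse_ast(c("T1\tGene_expression 0 10", "E1\tGene_expression:T1"),
                   "expression")
  pa <- events_to_relations(doc)
  expect_equal(nrow(pa$relations), 0)
  expect_equal(pa$denotations$id, "E1")

  bind <- binding_doc(collective = TRUE)
  pb <- events_to_relations(bind)
  r <- pb$relations[pb$relations$obj == "E1", ]
  expect_equal(r$pred, c("themeOf", "themeOf"))
  expect_setequal(r$subj, c("T1", "T2"))
})

test_that("relation count equals total argument count", {
  for (s in 1:5) {
    corpus <- small_corpus(seed = 100 + s)
    for (d in corpus$docs) {
      pa <- events_to_relations(d)
      expect_equal(nrow(pa$relations),
                   sum(vapply(d$events$args, nrow, integer(1))))
    }
  }
})

test_that("an isolated causal relation reassembles into a cause-only event", {
  doc <- parse_pajson('{"text": "GENE1 inhibits",
    "denotations": [
      {"id": "T1", "span": {"begin": 0, "end": 5}, "obj": "Protein"},
      {"id": "E1", "span": {"begin": 6, "end": 14}, "obj": "Negative_regulation"}],
    "relations": [{"id": "R1", "pred": "causeOf", "subj": "T1", "obj": "E1"}]}')
  ast <- relations_to_events(doc)
  expect_equal(nrow(ast$events), 1)
  args <- ast$events$args[[1]]
  expect_equal(args$role, "Cause")
  # partial information is representable: no theme required
  expect_false("Theme" %in% args$role)
})

test_that("documents without event denotations become entity-only documents", {
  doc <- parse_pajson('{"text": "GENE1 GENE2", "denotations": [
    {"id": "T1", "span": {"begin": 0, "end": 5}, "obj": "Protein"},
    {"id": "T2", "span": {"begin": 6, "end": 11}, "obj": "Protein"}]}')
  ast <- relations_to_events(doc)
  expect_equal(nrow(ast$events), 0)
  expect_equal(nrow(ast$entities), 2)
})

test_that("unmapped predicates error in strict mode and pass through leniently", {
  json <- '{"text": "GENE1 inhibits",
    "denotations": [
      {"id": "T1", "span": {"begin": 0, "end": 5}, "obj": "Protein"},
      {"id": "E1", "span": {"begin": 6, "end": 14}, "obj": "Negative_regulation"}],
    "relations": [{"id": "R1", "pred": "locatedIn", "subj": "T1", "obj": "E1"}]}'
  doc <- parse_pajson(json)
  expect_error(relations_to_events(doc, strict = TRUE),
               class = "geniakb_conversion_error")
  expect_warning(ast <- relations_to_events(doc, strict = FALSE),
                 class = "geniakb_opaque_statement")
  expect_equal(length(ast$extra), 1)
  expect_match(ast$extra, "locatedIn")
})

test_that("decompose-then-reassemble is a semantic identity on generated corpora", {
  for (s in 1:2) {
    corpus <- small_corpus(seed = 200 + s, n_docs = 50, events_per_doc = 5)
    for (d in corpus$docs) {
      back <- relations_to_events(events_to_relations(d))
      expect_identical(event_signatures(back), event_signatures(d))
    }
  }
})

test_that("conversion is deterministic", {
  d <- small_corpus(seed = 9)$docs[[1]]
  expect_identical(serialize_pajson(events_to_relations(d)),
                   serialize_pajson(events_to_relations(d)))
  pa <- events_to_relations(d)
  expect_identical(serialize_ast(relations_to_events(pa)),
                   serialize_ast(relations_to_events(pa)))
})
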