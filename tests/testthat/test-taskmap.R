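m <- concept_map()
h <- read_hierarchy()

test_that("direct equivalences and ancestor subsumption resolve concepts", {
  expect_equal(nearest_mapped_ancestor("Transcription", h, m), "Transcription")
  expect_equal(nearest_mapped_ancestor("RegulationOfGeneExpression", h, m),
               "Regulation")
  expect_equal(nearest_mapped_ancestor("TranscriptionFactor", h, m), "Protein")
  expect_equal(nearest_mapped_ancestor("ProteinTargeting", h, m),
               "Localization")
  expect_true(is.na(nearest_mapped_ancestor("Disease", h, m)))
  expect_true(is.na(nearest_mapped_ancestor("Organism", h, m)))
  expect_true(is.na(nearest_mapped_ancestor("NeverSeenConcept", h, m)))
  # both Gene and Protein collapse onto the single Genia protein concept
  expect_equal(nearest_mapped_ancestor("Gene", h, m), "Protein")
  expect_equal(nearest_mapped_ancestor("Protein", h, m), "Protein")
})

test_that("ancestor search agrees with exhaustive path enumeration on random hierarchies", {
  all_ancestor_paths <- function(node, edges) {
    # depth-first enumeration of every ancestor with its minimum distance
    res <- new.env()
    walk <- function(n, d) {
      for (p in edges$parent[edges$child == n]) {
        if (is.null(res[[p]]) || res[[p]] > d) {
          res[[p]] <- d
          walk(p, d + 1)
        }
      }
    }
    walk(node, 1)
    tibble::tibble(concept = ls(res),
                   dist = vapply(ls(res), function(k) res[[k]], numeric(1)))
  }
  set.seed(99)
  for (k in 1:10) {
    n <- 50
    # random forest: each node links to 1-2 earlier nodes (acyclic)
    kids <- paste0("c", 2:n)
    edges <- dplyr::bind_rows(lapply(kids, function(ch) {
      i <- as.integer(sub("c", "", ch))
      parents <- paste0("c", sample(seq_len(i - 1),
                                    min(sample(1:2, 1), i - 1)))
      tibble::tibble(child = ch, parent = parents)
    }))
    mapped <- paste0("c", sample(n, 8))
    mm <- list(gro_to_ge = setNames(paste0("GE_", mapped), mapped))
    hh <- structure(split(edges$parent, edges$child),
                    class = "concept_hierarchy")
    for (node in paste0("c", sample(n, 10))) {
      got <- nearest_mapped_ancestor(node, hh, mm)
      exp_val <- if (node %in% mapped) paste0("GE_", node) else {
        anc <- all_ancestor_paths(node, edges)
        anc <- anc[anc$concept %in% mapped, ]
        if (!nrow(anc)) NA_character_ else {
          best <- anc[anc$dist == min(anc$dist), ]
          paste0("GE_", sort(best$concept)[1])
        }
      }
      expect_identical(got, exp_val)
    }
  }
})

test_that("hierarchy cycles are rejected", {
  bad <- withr::local_tempfile(lines = c("child\tparent", "a\tb", "b\ta"))
  expect_error(read_hierarchy(bad), class = "geniakb_config_error")
})

test_that("GE to GRO relabels by equivalence and drops the unmappable", {
  doc <- parse_ast(c(
    "T1\tProtein 0 5",
    "T2\tProtein 6 11",
    "T3\tBinding 12 19",
    "T4\tDeacetylation 20 33",
    "E1\tBinding:T3 Theme:T1 Theme2:T2",
    "E2\tDeacetylation:T4 Theme:T1"
  ), "GENE1 GENE2 binding deacetylation")
  res <- convert_ge_to_gro(doc)
  out <- res$doc
  expect_equal(out$events$type, "BindingToProtein")
  expect_equal(out$entities$type[out$entities$id %in% c("T1", "T2")],
               c("Protein", "Protein"))
  expect_false("Deacetylation" %in% c(out$entities$type, out$events$type))
  expect_equal(res$stats$convertible, c(2L, 1L))
  expect_equal(res$stats$dropped, c(0L, 1L))

  # one-to-many choice: Protein can be sent to Gene instead
  res_gene <- convert_ge_to_gro(doc, concept_map(ge_protein_as = "gene"))
  expect_true(all(res_gene$doc$entities$type[
    res_gene$doc$entities$id %in% c("T1", "T2")] == "Gene"))

  expect_error(
    convert_ge_to_gro(parse_ast(c("T1\tMystery 0 5"), "GENE1"), strict = TRUE),
    class = "geniakb_conversion_error")
})

test_that("GRO to GE converts via ancestors and drops unreachable branches", {
  doc <- parse_ast(c(
    "T1\tTranscriptionFactor 0 5",
    "T2\tOrganism 6 11",
    "T3\tPositiveRegulationOfGeneExpression 12 21",
    "T4\tGene 22 27",
    "E1\tPositiveRegulationOfGeneExpression:T3 Theme:T4 Cause:T1"
  ), "GENE1 mouse activates GENE2")
  res <- convert_gro_to_ge(doc)
  out <- res$doc
  expect_setequal(out$entities$type[out$entities$id %in% c("T1", "T4")],
                  "Protein")
  expect_false("T2" %in% out$entities$id)  # organism branch unconvertible
  expect_equal(out$events$type, "Regulation")
  expect_equal(res$stats$convertible, c(2L, 1L))
  expect_equal(res$stats$dropped, c(1L, 0L))
})

test_that("arguments pointing at dropped annotation are removed recursively", {
  doc <- parse_ast(c(
    "T1\tProtein 0 5",
    "T2\tUbiquitination 6 11",
    "T3\tRegulation 12 21",
    "E1\tUbiquitination:T2 Theme:T1",
    "E2\tRegulation:T3 Theme:E1 Cause:T1"
  ), "GENE1 added regulates")
  res <- convert_ge_to_gro(doc)
  out <- res$doc
  expect_equal(out$events$id, "E2")
  # the dropped event's slot vanishes; the cause survives
  expect_equal(out$events$args[[1]]$role, "Cause")
  expect_equal(res$stats$dropped[res$stats$kind == "events"], 1L)
})

test_that("equivalence-only documents survive the GE-GRO round trip", {
  corpus <- small_corpus(seed = 61, n_docs = 10, events_per_doc = 5)
  for (doc in corpus$docs) {
    fwd <- convert_ge_to_gro(doc)
    expect_equal(fwd$stats$dropped, c(0L, 0L))
    back <- convert_gro_to_ge(fwd$doc)
    expect_identical(event_signatures(back$doc), event_signatures(doc))
    expect_identical(back$doc$entities[c("type", "begin", "end")],
                     doc$entities[c("type", "begin", "end")])
  }
})

test_that("drop counting is conserved on every input", {
  gro_labels <- c("TranscriptionFactor", "Organism", "Disease", "Gene",
                  "Protein", "Tissue", "Enzyme", "DNA")
  set.seed(8)
  for (k in 1:10) {
    n <- sample(3:8, 1)
    types <- sample(gro_labels, n, replace = TRUE)
    toks <- sprintf("W%02d", seq_len(n))
    starts <- (seq_len(n) - 1L) * 4L
    doc <- ast_document(
      paste(toks, collapse = " "),
      tibble::tibble(id = paste0("T", seq_len(n)), type = types,
                     begin = starts, end = starts + 3L))
    res <- convert_gro_to_ge(doc)
    expect_equal(res$stats$convertible[1] + res$stats$dropped[1], n)
  }
})

test_that("the statistics report renders counts, shares, and degenerate rows", {
  s <- tibble::tibble(kind = c("entities", "events"),
                      convertible = c(6449L, 3436L),
                      dropped = c(125L, 280L))
  rep <- conversion_stats_report(s)
  expect_true(any(grepl("6,449 \\(98.1%\\)", rep)))
  expect_true(any(grepl("3,436 \\(92.5%\\)", rep)))
  expect_true(any(grepl("125 \\(1.9%\\)", rep)))
  zero <- tibble::tibble(kind = "entities", convertible = 0L, dropped = 0L)
  expect_warning(rep0 <- conversion_stats_report(zero),
                 class = "geniakb_degenerate_stats")
  expect_true(any(grepl("0 \\(0.0%\\)", rep0)))
})
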