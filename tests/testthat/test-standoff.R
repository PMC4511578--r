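test_that("entity and event statements parse per the a* grammar", {
  txt <- "MTb4 induces binding of GENE1 and GENE2"
  doc <- parse_ast(c(
    "T1\tProtein 0 4",
    "T2\tNegative_regulation 5 12",
    "T3\tGene_expression 13 20",
    "T5\tBinding 13 20",
    "T6\tProtein 24 29",
    "T7\tProtein 34 39",
    "E2\tGene_expression:T3 Theme:T6",
    "E1\tNegative_regulation:T2 Theme:E2 Cause:T1",
    "E3\tBinding:T5 Theme:T6 Theme2:T7"
  ), txt)

  e <- doc$entities[doc$entities$id == "T1", ]
  expect_equal(e$type, "Protein")
  expect_equal(c(e$begin, e$end), c(0L, 4L))

  ev <- doc$events[doc$events$id == "E1", ]
  expect_equal(ev$type, "Negative_regulation")
  expect_equal(ev$trigger_id, "T2")
  expect_equal(ev$args[[1]]$role, c("Theme", "Cause"))
  expect_equal(ev$args[[1]]$target, c("E2", "T1"))

  bind <- doc$events[doc$events$id == "E3", ]
  expect_equal(bind$args[[1]]$role, c("Theme", "Theme2"))
  expect_equal(role_base(bind$args[[1]]$role), c("Theme", "Theme"))
})

test_that("malformed lines and broken references raise typed errors", {
  txt <- "GENE1 binds"
  expect_error(parse_ast("T1 Protein 0 5", txt), class = "geniakb_parse_error")
  expect_error(parse_ast("T1\tProtein zero 5", txt),
               class = "geniakb_parse_error")
  expect_error(parse_ast("T1\tProtein 0 99", txt),
               class = "geniakb_bounds_error")
  expect_error(parse_ast(c("T1\tProtein 0 5", "E1\tBinding:T9"), txt),
               class = "geniakb_reference_error")
  expect_error(parse_ast(c("T1\tProtein 0 5", "T1\tProtein 6 11",
                           "E1\tBinding:T1 Theme:T9"),
                         "GENE1 GENE2"),
               class = "geniakb_validation_error")
})

test_that("unknown statement prefixes are preserved opaquely with a warning", {
  txt <- "GENE1 binds GENE2"
  expect_warning(
    doc <- parse_ast(c("T1\tProtein 0 5", "*\tEquiv T1 T1"), txt),
    class = "geniakb_opaque_statement"
  )
  expect_equal(doc$extra, "*\tEquiv T1 T1")
  expect_true("*\tEquiv T1 T1" %in% serialize_ast(doc))
})

test_that("parse and serialize round-trip, byte-stably, on generated corpora", {
  corpus <- small_corpus(seed = 11, n_docs = 50, events_per_doc = 4)
  for (doc in corpus$docs) {
    lines1 <- serialize_ast(doc)
    doc2 <- parse_ast(lines1, doc$text, ref = doc$ref)
    expect_identical(serialize_ast(doc2), lines1)
    expect_equal(doc2$entities, doc$entities)
    expect_equal(doc2$events, doc$events)
  }
})

test_that("role suffix stripping is idempotent", {
  roles <- c("Theme", "Theme2", "Theme13", "Cause", "Site2")
  expect_identical(role_base(role_base(roles)), role_base(roles))
  expect_identical(role_base("Theme3"), "Theme")
})

test_that("streaming parser and post-hoc validator reject the same mutants", {
  set.seed(42)
  base <- small_corpus(seed = 3, n_docs = 1, events_per_doc = 6)$docs[[1]]
  lines <- serialize_ast(base)
  mutate_once <- function(lines, text) {
    op <- sample(4, 1)
    i <- sample(length(lines), 1)
    if (op == 1) { # corrupt an offset beyond the text
      lines[i] <- sub(" ([0-9]+)$", sprintf(" %d", nchar(text) + 50), lines[i])
    } else if (op == 2) { # dangle a reference
      lines[i] <- gsub(":T[0-9]+", ":T999", lines[i])
    } else if (op == 3) { # duplicate a statement id
      j <- sample(length(lines), 1)
      id_j <- sub("\t.*$", "", lines[j])
      lines[i] <- sub("^[TE][0-9]+", id_j, lines[i])
    } else { # harmless reordering
      lines <- rev(lines)
    }
    lines
  }
  for (k in seq_len(200)) {
    mut <- mutate_once(lines, base$text)
    streaming <- tryCatch({parse_ast(mut, base$text); TRUE},
                          error = function(e) FALSE)
    posthoc <- tryCatch({
      validate_ast(parse_ast(mut, base$text, validate = FALSE))
      TRUE
    }, error = function(e) FALSE)
    expect_identical(streaming, posthoc)
  }
})

test_that("single-stream and split-file dialects round-trip through disk", {
  doc <- fig_chain_doc()
  base1 <- file.path(withr::local_tempdir(), "d1")
  write_ast(doc, base1, dialect = "ann")
  back1 <- read_ast(paste0(base1, ".txt"), ref = doc$ref)
  expect_identical(serialize_ast(back1), serialize_ast(doc))

  base2 <- file.path(withr::local_tempdir(), "d2")
  write_ast(doc, base2, dialect = "a12")
  expect_true(file.exists(paste0(base2, ".a1")))
  # entities that trigger no event go to .a1; triggers ride with events
  a1 <- readLines(paste0(base2, ".a1"))
  expect_true(all(grepl("Protein", a1)))
  back2 <- read_ast(paste0(base2, ".txt"), dialect = "a12", ref = doc$ref)
  expect_identical(sort(serialize_ast(back2)), sort(serialize_ast(doc)))
})
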