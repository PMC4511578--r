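Package: geniakb
Title: Knowledge-Base-Oriented Evaluation of Biomedical Event Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with biomedical event annotation from a
    knowledge-base perspective. Reads and writes the BioNLP shared-task
    standoff (a*) format and the relation-centric PubAnnotation-style JSON
    format, converts losslessly between the event-centric (n-ary) and
    relation-centric (binary) representations, exports annotation to RDF
    triples under a minimal text-annotation vocabulary, answers eight fixed
    benchmark queries (protein themes of gene expression, localization and
    binding; binding pairs; regulation pairs with and without transitive
    themeOf inference), and scores system knowledge bases against a gold
    knowledge base in recall, precision and F1. Also converts corpora between
    the Genia Event (GE) and Gene Regulation Ontology (GRO) schemata via
    concept equivalences and is-a subsumption, reporting convertibility
    statistics, and generates seeded synthetic corpora with controllable
    perturbations for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
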