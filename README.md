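# geniakb

Knowledge-base-oriented evaluation of biomedical event annotation.

## The problem

Biomedical event extraction systems annotate text with typed n-ary
events: a *Gene_expression* event whose Theme is a protein, a
*Regulation* event whose Theme is another event and whose Cause is a
protein, a *Binding* event with one to three protein themes. The
traditional way to evaluate such systems compares annotation instances
one by one against a gold standard. But the users of the extracted
knowledge — biologists querying a knowledge base — do not care whether a
causal link was annotated through one regulation event or through a
chain of two; they care whether the KB answers *"which protein regulates
the expression of which protein?"* correctly. Structurally different but
semantically equivalent annotations (schematic variants) should score
the same.

`geniakb` implements that KB-oriented evaluation pipeline end to end,
for tool builders and evaluation designers in biomedical text mining:

1. **Formats** — read/write the BioNLP shared-task standoff `a*` format
   (`parse_ast()`, `serialize_ast()`) and the relation-centric
   PubAnnotation-style JSON format (`parse_pajson()`,
   `serialize_pajson()`).
2. **Bridge** — lossless conversion between the event-centric n-ary and
   the relation-centric binary representation: an event with k arguments
   becomes one denotation plus k binary relations
   (`events_to_relations()`, `relations_to_events()`).
3. **RDF export** — each denotation becomes a `tao:Context_entity`
   instance `tao:denoted_by` a dereferenceable span IRI; each relation a
   `genia:themeOf` / `genia:causeOf` statement (`document_to_triples()`,
   `serialize_graph()`).
4. **Queries** — the eight benchmark queries Q1–Q8 over the triple
   graph, including transitive closure of `themeOf`
   (`run_query()`, `theme_closure()`): with closure, *A theme-of B* and
   *B theme-of C* entail *A theme-of C*, which is what abstracts out the
   schematic variants.
5. **Scoring** — result sets from a system graph are compared to the
   gold graph's result sets; recall = TP/|gold|, precision = TP/|system|,
   F1 the harmonic mean, reported as percentages rounded half-up to two
   decimals (`kb_score()`, `score()`, `evaluate_submission()`, with
   `tidy()`, `glance()` and `autoplot()` methods).
6. **GE ↔ GRO conversion** — relabel corpora between the Genia Event
   schema and the Gene Regulation Ontology via concept equivalences and
   is-a subsumption, with convertibility statistics
   (`convert_ge_to_gro()`, `convert_gro_to_ge()`,
   `nearest_mapped_ancestor()`, `conversion_stats_report()`).
7. **Synthetic corpora** — a seeded generator of gold corpora (nested
   regulation chains, multi-theme binding, cause attachments) and
   controllably perturbed system submissions, with a ground-truth fact
   ledger used as a query oracle (`generate_gold()`, `perturb()`).

## A worked example

Gold annotation of "NFAT5 expression signaling dependent MyD88" — the
expression of NFAT5 is the theme of a regulation chain whose top event
has MyD88 as cause:

```r
library(geniakb)

txt <- "NFAT5 expression signaling dependent MyD88"
gold <- parse_ast(c(
  "T1\tProtein 0 5",
  "T2\tGene_expression 6 16",
  "T3\tPositive_regulation 17 26",
  "T4\tRegulation 27 36",
  "T5\tProtein 37 42",
  "E1\tGene_expression:T2 Theme:T1",
  "E2\tPositive_regulation:T3 Theme:E1",
  "E3\tRegulation:T4 Theme:E2 Cause:T5"
), txt, ref = doc_ref("synth", "chain", 0))

g <- corpus_to_graph(list(gold))
run_query(g, "Q5")   # 0 rows: no single-step protein->regulation theme
run_query(g, "Q6")
#> # A tibble: 1 x 2
#>   s1                                                                           s2
#> 1 http://pubannotation.org/docs/sourcedb/synth/sourceid/chain/divs/0/spans/0-5 http://pubannotation.org/docs/sourcedb/synth/sourceid/chain/divs/0/spans/37-42
```

Q5 (no inference) cannot see that MyD88 regulates NFAT5 — the cause sits
two regulation levels above the protein theme. Q6's transitive `themeOf`
finds the pair, identified by the two span IRIs (characters 0–5 =
NFAT5, 37–42 = MyD88).

Scoring a submission that annotated the same assertion with one
regulation level fewer (the flat schematic variant):

```r
flat <- parse_ast(c(
  "T1\tProtein 0 5",
  "T2\tGene_expression 6 16",
  "T3\tPositive_regulation 17 26",
  "T5\tProtein 37 42",
  "E1\tGene_expression:T2 Theme:T1",
  "E2\tPositive_regulation:T3 Theme:E1 Cause:T5"
), txt, ref = doc_ref("synth", "chain", 0))

evaluate_submission(g, corpus_to_graph(list(flat)), queries = c("Q6", "Q8"))
#> KB-oriented evaluation (2 queries)
#> query  GS  P  TP  R / Pr / F
#> Q6     1   1  1   100.00 / 100.00 / 100.00
#> Q8     1   1  1   100.00 / 100.00 / 100.00
```

The structurally different submission scores perfectly on the inference
queries: the schematic difference is abstracted out.

Score arithmetic follows the benchmark's conventions exactly, e.g. a
gold set of 604, a submission of 604 and 497 true positives give
82.28 / 82.28 / 82.28, and an empty submission prints
`00.00 / 00.00 / 00.00`:

```r
kb_score(604, 604, 497)$f1      # 82.28
format_pct(kb_score(83, 0, 0)$f1)  # "00.00"
expected_pair_score(59.12)      # 34.95 — the P x P pair-score expectation
```

## Command line

A thin launcher over the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","geniakb.R",package="geniakb"))')" \
  convert --from ast --to json --in doc.txt --out doc.json
# subcommands: convert | rdf | query | evaluate | taskconvert | simulate
```

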