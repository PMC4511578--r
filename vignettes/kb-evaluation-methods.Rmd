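---
title: "Methods: KB-oriented evaluation of event annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: KB-oriented evaluation of event annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geniakb)
```

## The evaluation model

Event annotation assigns text spans typed n-ary predicate-argument
structures: an event has a type, a trigger span, and arguments filling
roles such as Theme and Cause, where an argument may itself be an event
(regulation events are recursive). Two annotation sets can encode the
same biological assertion with different structure — a cause attached to
a regulation event directly, or through an extra regulation level. The
package's premise is that an evaluation aimed at knowledge-base
construction should be invariant under such *schematic variation*,
which it achieves by (i) decomposing events into binary relations,
(ii) exporting them as RDF triples, and (iii) scoring answers to fixed
queries, one pair of which closes the `themeOf` relation transitively.

The pipeline is: standoff document → relation-centric document
(`events_to_relations()`) → triple graph (`document_to_triples()`) →
per-query result sets (`run_query()`) → recall/precision/F1 against the
gold graph's result sets (`evaluate_submission()`).

### Representations

The standoff (`a*`) grammar is tab-primary: `T<i>` lines hold
space-delimited `(type, begin, end)` triples; `E<i>` lines hold
space-delimited `role:id` pairs, the first being `event-type:trigger`.
Coordinated arguments carry number suffixes (`Theme2`, `Theme3`); the
suffix is surface syntax, stripped by `role_base()` for semantics and
preserved verbatim for round-tripping. Offsets are caret positions
counted in Unicode code points, end-exclusive; the format itself does
not fix the unit, and code points are the only choice that survives
round-trips through JSON (UTF-8 byte offsets would not). Statements
with other prefixes (relations, modifications, equivalence classes) are
preserved as opaque lines: the package does not interpret coreference.
Duplicate statement ids are a hard error — silently keeping either line
would make round-trips ambiguous.

The JSON form is relation-centric: `denotations` state that a span
denotes an object; `relations` connect two denotations by a predicate.
An event with k arguments maps to one denotation (id = event id, span =
trigger span, object = event type) plus k relations, subject = argument,
predicate = `themeOf`/`causeOf` (the role map is an injective,
extensible table), object = the event. The relation direction
(participant → event) matches the benchmark query patterns. Relation
ids are minted `R1, R2, ...` in document order so conversion is
deterministic.

Two choices in the bridge were genuinely open:

* **Consumed triggers.** A trigger entity used by exactly one event and
  never referenced as an argument is represented by the event denotation
  itself and omitted as a standalone denotation (`keep_triggers = TRUE`
  restores it). Triggers shared between events, or targeted by
  arguments, are kept.
* **Partial information.** The reverse conversion keeps events with
  zero or one arguments — an isolated causal relation is legitimate
  content of the relation-centric form, and dropping it would make the
  bridge lossy in exactly the situation the binary representation
  exists for.

### RDF export

Per denotation, three triples: the instance is typed with its concept
(in the task namespace) and with `tao:Context_entity`, and linked by
`tao:denoted_by` to a span IRI of the form
`{base}/docs/sourcedb/{db}/sourceid/{id}/divs/{div}/spans/{begin}-{end}`.
Per relation, one triple. So `|triples| = 3·|denotations| +
|relations|`. Only `denoted_by` is emitted; its inverse is derivable.
Span IRIs are functions of the document reference and offsets only, so
independently built gold and system graphs over the same documents are
comparable at the span level. Instance IRIs
(`{inst_base}/{db}-{id}-{div}#{denotation id}`) are deterministic but
annotation-set-specific; the scheme is this package's own, since only
the span-IRI scheme is externally fixed. Graphs have set semantics and
sorted iteration order, which makes serialization deterministic and
graph equality testable as tibble equality.

### Queries and inference

Q1–Q3 project the spans of proteins that are one-step themes of gene
expression, localization and binding events. Q4 projects distinct
protein span pairs bound by one binding event, ordered by codepoint-wise
IRI comparison (`s1 < s2`) — so collective parsing (two themes on one
event) yields a pair while distributive parsing (two one-theme events)
does not. Q5/Q6 project (theme, cause) protein pairs of one event,
without/with transitive closure of `themeOf`; Q7/Q8 do the same with the
theme protein anchored to a typed gene-expression event one/many
`themeOf` steps below the cause-bearing event.

Deliberate non-tightenings: Q5–Q8 carry no `s1 != s2` filter and no
type constraint on the regulation event, exactly as the benchmark
defines them; self-loops in `themeOf` are retained and closure then
contains `(x, x)`. The Q4 ordering is lexical comparison of full span
IRIs: membership of a pair is base-independent, but its orientation
depends on the IRI base, which is why the ordering semantics is stated
here. Strict SPARQL 1.1 engines treat `<` on IRIs as a type error; the
shipped `.rq` files keep the benchmark's verbatim filter, and the
delegation harness used in the tests evaluates it over `STR()` forms,
which is the lexical semantics the native engine implements.

`theme_closure()` computes reachability by semi-naive fixpoint
iteration (join the newest pairs against the base edges until no new
pair appears); the test suite checks it against per-node BFS on random
graphs, cycles included, and checks `run_query()` against an
independent standards-compliant SPARQL engine executing the shipped
query texts.

### Scoring

With gold result size GS, system size P and true positives TP (tuple
intersection): recall = 100·TP/GS, precision = 100·TP/P, F1 their
harmonic mean. Empty gold or system sets score 0 — the convention the
benchmark's printed tables use. Percentages are rounded half-up to two
decimals, computed from the *unrounded* recall and precision; this
reproduces every published cell (e.g. 45/56 = 80.357 → 80.36), whereas
rounding before the harmonic mean does not. Display zero-pads to two
integer digits (`04.20`, `00.00`) to match the printed tables; stored
values are plain numbers. `evaluate_submission()` refuses graph pairs
whose span-IRI document bases are disjoint, because every score would
then be vacuously zero.

The pair-score expectation `expected_pair_score()` encodes the
independence argument: if single items are found at F-score P, pairs
should be found at P·P; observed pair scores below that expose the
extra difficulty of deciding collective versus distributive readings.

### GE ↔ GRO conversion

Forward (GE → GRO) uses direct equivalences only. The equivalence table
is one-to-many at Protein (GRO separates Gene from Protein); the
forward default sends Protein to Protein, configurable to Gene — the
benchmark does not state the forward choice, and both invert to
Protein. GE concepts with no GRO correspondent (Deacetylation,
Ubiquitination) are dropped and counted.

Reverse (GRO → GE) relabels each concept to the equivalence of its
nearest mapped is-a ancestor: breadth-first by level, ties at a level
broken lexicographically, absent-and-unmapped concepts dropping out
silently. Only is-a edges are traversed: the conversion is defined by
subsumption, so part-of edges are excluded. Dropped annotation is
removed together with the arguments that pointed at it; an event counts
as convertible iff its own type maps — argument loss does not
reclassify it, and that counting policy is printed in the statistics
header because the benchmark's own counting rule is unstated.
Convertibility shares are reported at one decimal, half-up; the two
shares of a row always sum to 100.0.

The shipped hierarchy (`gro_isa_synthetic.tsv`) is a synthetic fragment
covering every concept chain the converter's reference points name,
plus the non-convertible branches (organisms, tissues, chemicals,
disease, DNA-level binding); the real ontology's edge list is a drop-in
replacement via `read_hierarchy()`.

## The synthetic corpus

`generate_gold()` emulates the structures the queries probe, not
biomedical prose: documents are space-joined tokens (protein mentions,
trigger words), so offsets are trivially consistent. Per document the
generator draws event units — direct regulation events (protein theme +
protein cause), or simple typed events (binding with 1–3 themes) on
which a regulation chain of depth 1–2 may be stacked, the top of the
chain receiving a protein cause with high probability. Defaults: 10
documents, ~6 units each, event-type distribution weighted toward gene
expression and binding, chain probability 0.7, cause probability 0.9,
direct-regulation probability 0.3. These defaults were chosen once so
that every query has nonempty gold answers with overwhelming
probability at the corpus sizes the tests use; they are documented
here and not revisited per test.

Every query-relevant generative decision is recorded in a fact ledger
(which protein is a theme of which event type, which pairs bind
collectively, which protein causes which regulated protein, at which
chain depth). `ledger_result_set()` replays the ledger into expected
result sets — an oracle that never touches the query engine, avoiding
circular testing.

`perturb()` degrades a gold corpus per event: deletions (dependent
arguments removed, orphaned triggers dropped), within-family retypings,
protein span shifts, and schematic rewrites. A rewrite moves a cause
one nesting level down (collapsing the extra regulation event) when the
event's theme is itself a regulation event, and otherwise one level up
(minting a fresh regulation event). Perturbations never shift existing
offsets: the minted trigger token is appended at the end of the text
and a collapsed trigger's token simply stays unannotated. Span IRIs
embed offsets, so any offset shift would destroy the span-level
comparability between gold and perturbed graphs that the evaluation
depends on. Schematic rewrites therefore leave Q6 and Q8 answers
exactly invariant while changing Q5/Q7 — the property the evaluation
design is meant to have, and the one the acceptance suite checks over
20 seeds.

What the generator does not emulate: realistic trigger lexicalization,
sentence grammar, coreference, overlapping or discontinuous spans,
shared arguments between units, and the empirical type distribution of
real corpora. Passing tests show the pipeline's algebra is right
(round trips, closures, invariances, scoring conventions); they say
nothing about extraction quality on real text, and the published
corpus-scale statistics (absolute conversion counts, per-system
scores on the shared-task corpora) are not reproducible without those
corpora and systems.

## Numerical and engineering choices

* Half-up rounding is implemented as `floor(x·10^d + 0.5 + 1e-9)/10^d`;
  the epsilon guards against binary representation of values like
  80.357·100.
* All generators and perturbations run under a private RNG stream
  seeded from their configuration, restoring the caller's RNG state;
  identical configuration and seed give byte-identical corpora.
* Determinism everywhere else is by construction: sorted graph
  iteration, fixed JSON key order, document-order relation ids,
  trigger ids minted above the highest existing index.
* Problem sizes in the test suite: round-trip properties on 50–100
  generated documents; closure oracle on 50 random 30-node graphs;
  engine-agreement on 50 seeded 2-document corpora; the
  schematic-abstraction property on 20 seeds of 8×8 corpora. These
  sizes make every property run comfortably while exercising the
  combinatorics (multi-theme binding, depth-2 chains, shared spans).

## Known limitations

* The standoff reader preserves but does not interpret relation,
  modification and equivalence statements.
* The native query layer implements exactly the eight benchmark
  patterns plus the closure primitive; it is not a general SPARQL
  engine.
* Turtle output uses prefixed names only for terms under the configured
  namespaces and is read back only in the dialect the writer emits.
* The GRO hierarchy shipped is a synthetic fragment; conversion results
  on real GRO data require the real ontology's edge list.
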