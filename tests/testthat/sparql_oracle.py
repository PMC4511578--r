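#!/usr/bin/env python
"""Independent SPARQL oracle: run the shipped benchmark query texts over
N-Triples graphs with rdflib and dump all result rows as TSV.

usage: sparql_oracle.py QUERIES_DIR MANIFEST OUT_TSV

MANIFEST lists one .nt path per line. OUT_TSV rows are:
graph-basename, query id, binding values (tab-separated, in SELECT order).

rdflib implements strict SPARQL 1.1 semantics, under which `<` on IRIs is
a type error; the benchmark's pair-ordering filter intends lexical IRI
comparison (the semantics of the store the benchmark ran on), so that
filter is evaluated over STR() forms here.
"""
import sys
from pathlib import Path

import rdflib

queries_dir, manifest, out_tsv = sys.argv[1:4]

queries = {}
for qid in [f"Q{i}" for i in range(1, 9)]:
    text = Path(queries_dir, qid + ".rq").read_text()
    text = text.replace("FILTER (?s1 < ?s2)", "FILTER (STR(?s1) < STR(?s2))")
    queries[qid] = text

rows = []
for line in Path(manifest).read_text().splitlines():
    line = line.strip()
    if not line:
        continue
    g = rdflib.Graph()
    g.parse(line, format="nt")
    name = Path(line).name
    for qid, text in queries.items():
        for binding in g.query(text):
            rows.append("\t".join([name, qid] + [str(v) for v in binding]))

Path(out_tsv).write_text("\n".join(sorted(rows)) + ("\n" if rows else ""))
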