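---
title: "Marking up tabular metadata with KOS concepts and browsing it through facets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marking up tabular metadata with KOS concepts and browsing it through facets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontofacet)
```

## The problem

Biological metadata is scattered across many tabular resources — strain
collections, genome project catalogues, sequence databases, literature
abstracts — each describing samples in free text: a `habitat` column saying
"isolated from kefir", a `location` column saying "Stockholm". Keyword search
over such tables fails in a characteristic way: a user looking for *dairy
products from the Scandinavian Peninsula* will never type "kefir" or
"Stockholm", so the relevant rows are invisible.

ontofacet addresses this with two coupled ideas:

1. **Semantic indexing**: detect mentions of concepts from Knowledge
   Organization Systems (KOS) — ontologies, taxonomies, gazetteers — in the
   scanned columns of each table, producing *hits* `(record, column, term,
   span, kind)`.
2. **Subsumption-expanded faceted browsing**: each KOS becomes a facet. A
   selected concept is silently replaced by its full descendant closure, so
   selecting *dairy product* retrieves records annotated with *kefir*
   (kefir is a kind of fermented dairy product, which is a kind of dairy
   product), and selecting *Scandinavian Peninsula* retrieves *Stockholm*
   records. Distinct-record counts at every facet node give continuous
   navigational feedback while drilling down.

## KOS model

A KOS is a DAG of terms (`term_id`, `label`, synonyms, parent links,
obsolete flag), loaded from OBO 1.2 flat files by `read_obo()`. Design
choices:

* **Only `is_a` edges** define the hierarchy. Other relationship types
  (`part_of`, `located_in`, ...) are ignored: the facets behave as pure
  subsumption DAGs. Geographic containment in the demo gazetteer is
  therefore encoded directly as parent edges (Stockholm → Sweden →
  Scandinavian Peninsula → Europe → Earth).
* **Multiple parents are allowed** (DAG, not tree); the descendant closure
  (`kos_descendants()`) is a set, so a node reachable along two paths is
  counted once. Cycles and rootless KOS are load-time errors.
* **Obsolete terms** are kept in the term set (so ids stay resolvable) but
  excluded from roots, children, autocomplete and match dictionaries.
* Sibling ordering is lexicographic by label; the ordering is a determinism
  contract, not a relevance ranking.
* Closures are cached per term inside the `kos` object; any reload rebuilds
  the cache (a KOS update invalidates every annotation anyway, which is why
  a changed KOS forces a full re-index rather than an incremental one).

## Concept recognition

`build_dictionary()` turns a KOS into a matching dictionary: every
non-obsolete term contributes its label and synonyms under two normalised
keys — the **ordered** Porter-stem sequence and the **order-insensitive**
sorted stem multiset — after removing the stop-words
`of, the, a, an, and` from multi-word names. `annotate_text()` scans every
contiguous token window (windows never start or end on a stop-word) and
classifies matches as:

* `exact` — the verbatim slice case-folds to a concept name;
* `stemmed` — the window's ordered stems equal a key ("dairy products");
* `rearranged` — only the stem multiset matches ("product, dairy").

The stemmer is the classic Porter (1980) algorithm, implemented here
following the reference implementation's control flow and frozen by tests
against its published example stems; pinning one stemmer keeps dictionary
keys stable across runs. "Phrase rearrangement" is deliberately interpreted
as order-insensitive matching **within a contiguous window of the same
token content** — not gapped or subsequence matching, which would explode
false positives in free text.

Overlapping hits to the *same* term are deduplicated keeping the longest
span (ties: exact > stemmed > rearranged, then earliest start). Hits to
*different* terms may nest freely: "fermented dairy product" yields hits
for both *fermented dairy product* and the nested *dairy product*. Keeping
nested distinct concepts is what makes the hierarchical rollup counts
coherent.

A **blacklist** of known false-positive phrases is normalised through the
same pipeline as dictionary keys (so "Milks" suppresses "milk") and is
enforced twice: blacklisted names contribute no dictionary entries, and
blacklisted windows never match. A term whose every name is blacklisted
becomes unmatchable and is reported in the build log.

The window length is capped at `max(longest entry, 6)` tokens to bound
work; no demo dictionary entry exceeds 3 tokens.

## Ingest

Each source is declared by a JSON config (`read_source_config()`): file,
delimiter, key columns, `scan_map` (column → KOS list) and a URL template
for the back-link to the primary resource. Conventions chosen where the
behaviour was open: record ids join key-column values with `":"`; template
substitutions are URL-escaped; encoding is strictly UTF-8 (malformed bytes
are an error, not silently replaced); header names match case-sensitively;
a cell is one text passage — multi-valued cells are not split, the matcher
simply finds several hits in them.

## Query semantics

A query maps facets to selected terms. Within one facet, selections OR
together; across facets they AND. The AND/OR split follows the
drill-down reading of faceted browsing: restricting two different facets
("dairy product" *and* "Scandinavian Peninsula") narrows, while picking two
siblings in one facet broadens. All counts are **distinct records**, not
raw hit occurrences — required for the additive drill-down reading (a
parent showing 4 when its disjoint children show 1 + 2 + 1) and safe on
multi-parent DAGs. `facet_counts()` recomputes each child's count under the
full remaining query, so the displayed distribution always reflects the
current restrictions; `query_items()` reports per-source totals under the
same query for every source, which is the "how many hits would I get over
there" feedback. Result ordering is ascending `record_id`: determinism is
the contract, no relevance ranking is attempted.

`update_records()` implements incremental refresh: hits of changed records
are dropped and recomputed, everything else untouched; the tested
invariant is exact equality with a one-shot rebuild of the final record
set. The index persists as documented JSON; dictionaries and closure
caches are rebuilt on load, and a reloaded index answers every query
identically.

## Service and CLI

The seven browsing functions (source listing, KOS roots, children,
autocomplete, column metadata, item queries, per-item match breakdown) are
exposed as a pure request dispatcher (`handle_request()`) returning
status + JSON body, and `serve()` wraps it in a minimal HTTP/1.1 loop on a
base R server socket (GET only, one request at a time, read-only). The
equivalence of service answers and direct library calls is tested rather
than assumed, since the dispatcher only delegates. `max_visible_facets`
(default 4) is a client-display constant carried in the service config.
The `ontofacet` CLI (`build`, `query`, `annotate`, `serve`, `fixtures`)
is a thin wrapper over these functions; `build` writes the index
atomically so a failed build never leaves a partial artifact.

## The demo instance and the synthetic corpus

The packaged demo emulates a small four-facet, five-source integration
instance at desk scale: a 9-term environment ontology, a 6-term gazetteer,
a 5-term taxonomy and a 5-term anatomy branch (the anatomy facet is a
structural placeholder exercising a fourth facet, not a claim about any
real anatomy resource), over a 7-record strain collection, small genome /
marine / rRNA catalogues and 3 literature abstracts. The strain table
plants exactly one cheese record, two milk records, one kefir record and
three non-dairy records, so the drill-down distribution at *dairy product*
is 4 = cheese 1 + milk 2 + fermented dairy product 1, and the kefir record
(organism *Leuconostoc*, habitat *kefir*, location *Stockholm*) is
retrievable through pure subsumption although no query term appears in it.
Real-instance magnitudes (e.g. literature hit counts in the dozens) are
instance-dependent and deliberately not emulated; the fixture preserves
the qualitative cross-resource behaviour (a non-zero literature count for
the same query).

`synth_corpus()` generates property-test corpora: filler text with 0–3
planted concept names per record, optionally mutated by pluralisation or
word reordering, with the planted ground truth recorded. The filler
vocabulary is invented words sharing no Porter stem with any demo KOS
name, so on generated corpora every false positive would be a bug, not an
ambiguity. What passing tests on such corpora shows is that the matcher
implements its stated contract (perfect recall on verbatim plants,
rearranged recovery of reordered plants); it does not show robustness to
real-world noise — misspellings, abbreviations, term ambiguity across
domains — which dictionary matching inherently does not provide.

## Problem sizes and numerical choices

The suite exercises: matcher-vs-brute-force equality on 200 random
text/dictionary pairs (≤ 40 tokens, ≤ 30 terms); closure coherence on all
fixture KOS plus 20 random DAGs of ≤ 50 nodes; anti-monotone refinement on
100 random queries over planted corpora; and incremental-equals-full on 50
randomized edit sequences. These sizes give each property thousands of
individual assertions while keeping the whole suite a desk-scale run. All
randomized tests fix their seeds; the package itself has no stochastic
component — identical inputs always produce byte-identical indexes.

Degenerate inputs are defined, not accidental: empty query = no
restriction; empty autocomplete query = no matches (not an error); paging
past the total returns an empty page with the true total; an empty change
list is the identity update.

## Known limitations

* Dictionary matching only: no statistical NER, no disambiguation (a name
  shared by two terms yields hits for both), no abbreviation handling,
  English-only stemming.
* Subsumption expansion uses `is_a` closure only; no reasoning, no
  cross-KOS mappings, no semantic-distance "similar to" retrieval.
* The HTTP loop is single-threaded and unauthenticated — suitable for
  local browsing and as a reference surface, not a production server.
* Matching is token-window based; a concept name interrupted by anything
  other than stop-words ("dairy fresh product" for *dairy product*) is not
  recovered — the window's token content must equal the name's, in some
  order.
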