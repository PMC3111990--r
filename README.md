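# ontofacet

Ontology-based markup and faceted browsing of tabular biological metadata.

Strain collections, genome project catalogues, sequence databases and
literature abstracts describe samples in free-text columns ("habitat:
kefir", "location: Stockholm"). Keyword search over such tables misses
everything the user did not literally type. ontofacet marks the tables up
with concepts from Knowledge Organization Systems (KOS) — ontologies,
taxonomies and gazetteers in OBO 1.2 format — and answers faceted queries
with *subsumption expansion*: a selected concept is replaced by its full
descendant closure in the concept DAG, so the engine can *look for dairy
product but find kefir*.

The core pieces:

* **Concept recognition** (`build_dictionary()`, `annotate_text()`):
  dictionary matching of term labels/synonyms over token windows, with
  Porter stemming (so "products" matches *product*), phrase rearrangement
  (order-insensitive stem-multiset matching, so "product, dairy" matches
  *dairy product*) and a blacklist for known false positives. Every hit
  carries its character span and match kind (`exact` / `stemmed` /
  `rearranged`).
* **Faceted retrieval** (`matching_items()`, `facet_counts()`,
  `query_items()`, `match_breakdown()`): for a query
  `{facet_1: terms, facet_2: terms, ...}`, a record matches iff for every
  restricted facet it has a hit in the union of descendant closures
  `∪_{t ∈ selection} desc(t)` (OR within a facet, AND across facets). All
  counts are distinct records, aggregated hierarchically: the count at a
  facet node is `|{records hit on any term in desc(node)}|`, so disjoint
  children of a node add up to its rollup.
* **Service + CLI**: the seven browsing functions (sources, KOS roots,
  children, autocomplete, column metadata, item queries with per-source
  totals, per-item match breakdown) as a JSON dispatcher / HTTP loop and an
  `ontofacet` command-line tool (`build`, `query`, `annotate`, `serve`,
  `fixtures`).

## Worked example

The package ships a miniature demonstration instance: four facets
(taxonomy, anatomy, environment, geography as small OBO files) over five
sources (a 7-record strain collection, genome / marine / rRNA catalogues
and literature abstracts).

```r
library(ontofacet)
idx <- demo_index()

# Drill-down feedback: expanding the EnvO node "dairy product" on the
# strain collection, no other restrictions:
fc <- facet_counts(idx, "straininfo", list(), "envo", parent = "dairy product")
setNames(as.integer(fc$counts), kos_label(idx$kos_set$envo, names(fc$counts)))
#>                  cheese fermented dairy product                    milk
#>                       1                       1                       2
```

The node "dairy product" itself shows 4 — one cheese record, two milk
records and one kefir record, counted as distinct records over the node's
descendant closure (1 + 2 + 1 = 4).

```r
# Subsumption retrieval: dairy product AND Scandinavian Peninsula
q <- list(envo = "dairy product", gaz = "Scandinavian Peninsula")
query_items(idx, "straininfo", q)
#> <result_page> source 'straininfo': 1 match(es), showing 1 from offset 0
#>   record_id                             link_url
#> 1   LMG:104 https://example.org/strain/LMG%3A104
#> per-source totals: straininfo=1, gold=0, camera=0, silva=0, pubmed=1
```

Record `LMG:104` (a *Leuconostoc* culture isolated from kefir in
Stockholm) contains neither query term; it matches because kefir is a kind
of (fermented) dairy product and Stockholm lies in the Scandinavian
Peninsula. The per-source totals show in real time that the same query
also has a hit in the literature source. The breakdown explains the match:

```r
match_breakdown(idx, "straininfo", "LMG:104", q)
#>    source_id record_id   column kos_id      term_id start end matched_text
#> 1 straininfo   LMG:104  habitat   envo ENVO:0000006     0   5        kefir
#> 2 straininfo   LMG:104 location    gaz  GAZ:0000006     0   9    Stockholm
#>    kind    satisfies
#> 1 exact ENVO:0000002
#> 2 exact  GAZ:0000003
```

From the shell, the same instance end to end:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "ontofacet.R", package = "ontofacet"))')
Rscript "$CLI" fixtures --out demo/
Rscript "$CLI" build --sources demo/sources.json --kos-dir demo/ \
    --blacklist demo/blacklist.txt --out index.json
Rscript "$CLI" query --index index.json --source straininfo \
    --query "envo=dairy product&gaz=Scandinavian Peninsula"
Rscript "$CLI" serve --index index.json --port 8080   # GET /sources, /kos/envo/roots, ...
```

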