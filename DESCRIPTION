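Package: ontofacet
Title: Ontology-Based Markup and Faceted Browsing of Tabular Biological Metadata
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Marks up tabular biological metadata (strain collections, genome
    project catalogues, sequence databases, literature abstracts) with concepts
    from Knowledge Organization Systems (KOS) -- ontologies, taxonomies and
    gazetteers in OBO 1.2 flat-file format -- using dictionary-based concept
    recognition with Porter stemming, phrase rearrangement and blacklisting.
    The resulting annotation index answers faceted, subsumption-expanded
    queries with hierarchical distinct-item counts per facet node and
    per-source totals, exposed as a library, a command-line tool and a small
    read-only HTTP/JSON service.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
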