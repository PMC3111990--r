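idx <- demo_index()

test_that("selections expand to their descendant closure", {
  envo <- idx$kos_set$envo
  cl <- expand_selection(envo, "dairy product")
  expect_length(cl, 5L)
  expect_true(kos_resolve(envo, "kefir") %in% cl)
  gaz <- idx$kos_set$gaz
  expect_true(kos_resolve(gaz, "Stockholm") %in%
                expand_selection(gaz, "Scandinavian Peninsula"))
  expect_length(expand_selection(envo, character(0)), 0L)
})

test_that("facets AND together and terms within a facet OR together", {
  q <- list(envo = "dairy product", gaz = "Scandinavian Peninsula")
  expect_true("LMG:104" %in% matching_items(idx, "straininfo", q))
  expect_equal(length(matching_items(idx, "straininfo", list())), 7L)
  q3 <- c(q, list(taxo = "Archaea"))
  expect_length(matching_items(idx, "straininfo", q3), 0L)
  # OR within one facet: cheese-or-milk covers three strain records
  q_or <- list(envo = c("cheese", "milk"))
  expect_length(matching_items(idx, "straininfo", q_or), 3L)
  expect_error(matching_items(idx, "nosuch", list()), "unknown source")
})

test_that("result pages are deterministic with correct arithmetic", {
  q <- list(envo = "dairy product")
  expect_length(matching_items(idx, "straininfo", q), 4L)
  p1 <- query_items(idx, "straininfo", q, offset = 0, page_size = 2)
  p2 <- query_items(idx, "straininfo", q, offset = 2, page_size = 2)
  p3 <- query_items(idx, "straininfo", q, offset = 4, page_size = 2)
  expect_equal(nrow(p1$items), 2L)
  expect_equal(nrow(p2$items), 2L)
  expect_equal(nrow(p3$items), 0L)
  expect_equal(p3$total, 4L) # beyond-range offset keeps the true total
  expect_equal(p1$items$record_id, sort(p1$items$record_id))
  expect_identical(query_items(idx, "straininfo", q, 0, 2), p1)
})

test_that("per-source totals are reported for all sources and do not depend on the active source", {
  q <- list(envo = "dairy product", gaz = "Scandinavian Peninsula")
  p_strain <- query_items(idx, "straininfo", q)
  p_pubmed <- query_items(idx, "pubmed", q)
  expect_identical(p_strain$per_source, p_pubmed$per_source)
  expect_equal(p_strain$per_source[["pubmed"]], 1L) # cross-resource feedback
  expect_equal(p_strain$per_source[["straininfo"]], p_strain$total)
})

test_that("drill-down counts distribute over the children", {
  fc <- facet_counts(idx, "straininfo", list(), "envo", parent = "dairy product")
  lab <- kos_label(idx$kos_set$envo, names(fc$counts))
  counts <- stats::setNames(as.integer(fc$counts), lab)
  expect_equal(counts[["cheese"]], 1L)
  expect_equal(counts[["milk"]], 2L)
  expect_equal(counts[["fermented dairy product"]], 1L)
  # parent rollup: read the dairy product node at its parent's level
  top <- facet_counts(idx, "straininfo", list(), "envo",
                      parent = "environmental material")
  expect_equal(top$counts[["ENVO:0000002"]], 4L)
  # no annotated descendants -> all-zero counts
  anat <- facet_counts(idx, "straininfo", list(), "anat", parent = NULL)
  expect_true(all(anat$counts == 0L))
  expect_error(facet_counts(idx, "straininfo", list(), "nokos"), "unknown KOS")
})

test_that("a record hit on two children counts once at the parent", {
  kos <- demo_kos()
  recs <- data.frame(
    rid = "r1", text = "cheese and milk", record_id = "r1", link_url = "u",
    stringsAsFactors = FALSE
  )
  attr(recs, "header") <- c("rid", "text")
  cfg <- structure(list(
    source_id = "both", display_name = "Both", file = NA, delimiter = "\t",
    key_columns = "rid", scan_map = list(text = "envo"), url_template = "u"
  ), class = "source_config")
  bidx <- index_from_records(kos, list(list(config = cfg, records = recs)))
  fc <- facet_counts(bidx, "both", list(), "envo", parent = "ENVO:0000002")
  expect_equal(fc$counts[["ENVO:0000003"]], 1L) # cheese
  expect_equal(fc$counts[["ENVO:0000004"]], 1L) # milk
  top <- facet_counts(bidx, "both", list(), "envo", parent = "ENVO:0000001")
  expect_equal(top$counts[["ENVO:0000002"]], 1L) # distinct record, not 2
})

test_that("match breakdown names the selected ancestor each hit satisfies", {
  q <- list(envo = "dairy product", gaz = "Scandinavian Peninsula")
  bd <- match_breakdown(idx, "straininfo", "LMG:104", q)
  expect_setequal(bd$term_id, c("ENVO:0000006", "GAZ:0000006"))
  expect_equal(bd$satisfies[bd$term_id == "ENVO:0000006"], "ENVO:0000002")
  expect_equal(bd$satisfies[bd$term_id == "GAZ:0000006"], "GAZ:0000003")
  # empty query returns every hit of the record
  all_hits <- match_breakdown(idx, "straininfo", "LMG:104", list())
  expect_gte(nrow(all_hits), 3L)
  expect_true(all(is.na(all_hits$satisfies)))
  # breakdown is a filter of the record's hits
  expect_true(all(bd$term_id %in% all_hits$term_id))
  expect_error(match_breakdown(idx, "straininfo", "nope", q), "unknown record")
})

test_that("queries leave the index unchanged", {
  p0 <- tempfile(); write_index(idx, p0)
  invisible(matching_items(idx, "straininfo", list(envo = "dairy product")))
  invisible(query_items(idx, "pubmed", list(gaz = "Scandinavian Peninsula")))
  invisible(facet_counts(idx, "gold", list(), "envo", parent = NULL))
  invisible(match_breakdown(idx, "straininfo", "LMG:104", list()))
  p1 <- tempfile(); write_index(idx, p1)
  expect_identical(readLines(p0), readLines(p1))
})
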