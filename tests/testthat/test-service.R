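idx <- demo_index()
app <- facet_app(idx, service_config())

test_that("the source listing names all five demo sources", {
  res <- handle_request(app, "/sources")
  expect_equal(res$status, 200L)
  expect_length(res$body, 5L)
  expect_setequal(vapply(res$body, `[[`, character(1), "source_id"),
                  c("straininfo", "gold", "camera", "silva", "pubmed"))
})

test_that("kos navigation endpoints mirror the library calls", {
  res <- handle_request(app, "/kos/envo/roots")
  expect_equal(vapply(res$body, `[[`, character(1), "term_id"),
               kos_roots(idx$kos_set$envo))
  res <- handle_request(app, "/kos/envo/terms/dairy product/children",
                        params = list(source = "straininfo"))
  expect_equal(res$status, 200L)
  expect_length(res$body, 3L)
  labels <- vapply(res$body, `[[`, character(1), "label")
  counts <- vapply(res$body, `[[`, integer(1), "count")
  expect_equal(stats::setNames(counts, labels),
               c(cheese = 1L, `fermented dairy product` = 1L, milk = 2L))
  ac <- handle_request(app, "/kos/envo/autocomplete",
                       params = list(q = "dairy", limit = "5"))
  expect_equal(vapply(ac$body, `[[`, character(1), "label"),
               c("dairy product", "fermented dairy product"))
})

test_that("items endpoint returns pages, per-source totals and back-links", {
  res <- handle_request(app, "/sources/straininfo/items",
                        params = list(query = "envo=dairy product&gaz=Scandinavian Peninsula"))
  expect_equal(res$status, 200L)
  expect_equal(res$body$total, 1L)
  expect_equal(res$body$items[[1]]$record_id, "LMG:104")
  expect_match(res$body$items[[1]]$link_url, "^https://example.org/strain/")
  expect_equal(res$body$per_source$pubmed, 1L)
  lib <- query_items(idx, "straininfo",
                     list(envo = "dairy product", gaz = "Scandinavian Peninsula"))
  expect_equal(unlist(res$body$per_source), lib$per_source)
})

test_that("breakdown endpoint explains why the record matched", {
  res <- handle_request(app, "/sources/straininfo/items/LMG:104/breakdown",
                        params = list(query = "envo=dairy product&gaz=Scandinavian Peninsula"))
  expect_equal(res$status, 200L)
  expect_equal(res$body$n_hits, 2L)
  terms <- vapply(res$body$hits, `[[`, character(1), "term_id")
  expect_setequal(terms, c("ENVO:0000006", "GAZ:0000006"))
})

test_that("columns endpoint reports scan metadata", {
  res <- handle_request(app, "/sources/straininfo/columns")
  expect_equal(vapply(res$body, `[[`, character(1), "column"),
               c("accession", "organism", "habitat", "location"))
  habitat <- res$body[[3]]
  expect_true(habitat$scanned)
  expect_equal(unlist(habitat$kos_ids), "envo")
})

test_that("unknown ids give 404 and malformed input gives 400, never 5xx", {
  expect_equal(handle_request(app, "/sources/nosuch/items")$status, 404L)
  expect_equal(handle_request(app, "/kos/nosuch/roots")$status, 404L)
  expect_equal(handle_request(app, "/kos/envo/terms/ENVO:99/children")$status, 404L)
  expect_equal(handle_request(app, "/sources/straininfo/items",
                              params = list(query = "notkosterm"))$status, 400L)
  expect_equal(handle_request(app, "/sources/straininfo/items",
                              params = list(offset = "x"))$status, 400L)
  expect_equal(handle_request(app, "/nope")$status, 404L)
})

test_that("query expressions parse with OR within and AND across facets", {
  q <- parse_query_expr("envo=cheese&envo=milk&gaz=Sweden", idx)
  expect_equal(q$envo, c("ENVO:0000003", "ENVO:0000004"))
  expect_equal(q$gaz, "GAZ:0000004")
  expect_equal(parse_query_expr("", idx), list())
  expect_error(parse_query_expr("envo", idx), "malformed query token 'envo'")
})

test_that("the visible-facet default limits the facet browsers to four", {
  cfg <- service_config()
  expect_equal(cfg$max_visible_facets, 4L)
  expect_length(visible_facets(app), 4L)
  expect_error(service_config(max_visible_facets = 0), "max_visible_facets")
  # file-based config overridable by arguments
  f <- tempfile(fileext = ".json")
  writeLines('{"port": 9999, "max_visible_facets": 2}', f)
  cfg2 <- service_config(path = f, port = 7777L)
  expect_equal(cfg2$port, 7777L)
  expect_equal(cfg2$max_visible_facets, 2L)
})

test_that("the live HTTP loop serves the dispatcher's answers", {
  index_path <- tempfile(fileext = ".json")
  write_index(idx, index_path)
  port <- sample(20000:40000, 1)
  script <- tempfile(fileext = ".R")
  writeLines(sprintf(
    'suppressPackageStartupMessages(library(ontofacet))
     idx <- read_index("%s")
     serve(idx, service_config(port = %dL), max_requests = 2, quiet = TRUE)',
    index_path, port), script)
  rlibs <- paste(.libPaths(), collapse = .Platform$path.sep)
  system2(file.path(R.home("bin"), "Rscript"), script,
          env = paste0("R_LIBS=", rlibs), wait = FALSE,
          stdout = NULL, stderr = NULL)

  http_get <- function(target) {
    for (attempt in 1:40) {
      con <- tryCatch(
        socketConnection("127.0.0.1", port, open = "r+", blocking = TRUE,
                         timeout = 5),
        error = function(e) NULL, warning = function(w) NULL
      )
      if (!is.null(con)) break
      Sys.sleep(0.25)
    }
    if (is.null(con)) return(NULL)
    on.exit(close(con))
    writeLines(c(paste("GET", target, "HTTP/1.1"), "Host: localhost", ""),
               con, sep = "\r\n")
    flush(con)
    paste(readLines(con, warn = FALSE), collapse = "\n")
  }

  r1 <- http_get("/sources")
  expect_false(is.null(r1))
  expect_match(r1, "HTTP/1.1 200 OK")
  expect_match(r1, "straininfo")
  r2 <- http_get("/kos/envo/terms/dairy+product/children?source=straininfo")
  expect_match(r2, "HTTP/1.1 200 OK")
  expect_match(r2, "fermented dairy product")
})
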