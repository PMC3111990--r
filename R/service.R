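# Read-only browsing service: the seven retrieval functions exposed as GET
# endpoints returning JSON. The route handlers are pure (request in,
# status + body out) and delegate to the kos/facets modules, so service
# answers are the library's answers by construction; serve() is a thin
# HTTP/1.1 loop on a base R server socket.
#
# Endpoints:
#   /sources
#   /kos/{id}/roots
#   /kos/{id}/terms/{term}/children
#   /kos/{id}/autocomplete?q=&limit=
#   /sources/{id}/columns
#   /sources/{id}/items?query=&offset=&limit=
#   /sources/{id}/items/{record}/breakdown?query=
# roots/children/items responses carry distinct-item counts (per node and
# per source) for real-time navigational feedback.

#' Service configuration
#'
#' Defaults may come from a JSON config file and are overridable by
#' arguments (and by CLI flags). `max_visible_facets` is the number of
#' facet browsers a client shows side by side at once; the default is 4.
#'
#' @param path optional JSON file with any of the fields below.
#' @param host bind address.
#' @param port TCP port.
#' @param max_visible_facets positive integer, default 4.
#' @param page_size default result page length.
#' @return object of class `service_config`.
#' @export
service_config <- function(path = NULL, host = NULL, port = NULL,
                           max_visible_facets = NULL, page_size = NULL) {
  cfg <- list(host = "127.0.0.1", port = 8080L, max_visible_facets = 4L,
              page_size = 10L)
  if (!is.null(path)) {
    file_cfg <- jsonlite::read_json(path)
    for (k in intersect(names(file_cfg), names(cfg))) cfg[[k]] <- file_cfg[[k]]
  }
  override <- list(host = host, port = port,
                   max_visible_facets = max_visible_facets,
                   page_size = page_size)
  for (k in names(override)) if (!is.null(override[[k]])) cfg[[k]] <- override[[k]]
  cfg$port <- as.integer(cfg$port)
  cfg$max_visible_facets <- as.integer(cfg$max_visible_facets)
  cfg$page_size <- as.integer(cfg$page_size)
  if (cfg$max_visible_facets < 1L) stop("max_visible_facets must be >= 1",
                                        call. = FALSE)
  structure(cfg, class = "service_config")
}

#' Bundle an index and a service config into an app
#'
#' @param index an `annotation_index`.
#' @param config a `service_config`.
#' @return object of class `facet_app` passed to [handle_request()] and
#'   [serve()].
#' @export
facet_app <- function(index, config = service_config()) {
  structure(list(index = index, config = config), class = "facet_app")
}

#' Facets a client should display by default
#'
#' The first `max_visible_facets` facets of the index, in index order.
#'
#' @param app a `facet_app`.
#' @return character vector of kos ids.
#' @export
visible_facets <- function(app) {
  utils::head(names(app$index$kos_set), app$config$max_visible_facets)
}

#' Parse a facet-selection query expression
#'
#' Wire format: repeated `kos=term` pairs joined by `&`, e.g.
#' `"envo=dairy product&gaz=Scandinavian Peninsula"`. Repeats of the same
#' kos OR together; distinct kos AND together (the facets-module
#' semantics). Terms may be ids or labels.
#'
#' @param expr the expression; `""`/`NULL` means no restriction.
#' @param index the `annotation_index` used to validate kos ids and resolve
#'   labels.
#' @return named list `kos_id -> character vector of term ids`.
#' @export
parse_query_expr <- function(expr, index) {
  if (is.null(expr) || !nzchar(expr)) return(list())
  out <- list()
  for (tok in strsplit(expr, "&", fixed = TRUE)[[1L]]) {
    eq <- regexpr("=", tok, fixed = TRUE)
    if (eq < 2L || eq == nchar(tok)) {
      stop("malformed query token '", tok, "' (expected kos=term)", call. = FALSE)
    }
    kid <- substr(tok, 1L, eq - 1L)
    val <- substr(tok, eq + 1L, nchar(tok))
    if (!(kid %in% names(index$kos_set))) {
      stop("unknown KOS '", kid, "' in query token '", tok, "'", call. = FALSE)
    }
    term <- kos_resolve(index$kos_set[[kid]], val)
    out[[kid]] <- unique(c(out[[kid]], term))
  }
  out
}

.term_entry <- function(kos, term_id, count = NULL) {
  t <- kos$terms[[term_id]]
  e <- list(term_id = t$term_id, label = t$label,
            n_children = length(kos_children(kos, term_id)))
  if (!is.null(count)) e$count <- count
  e
}

.record_entry <- function(records, i, header) {
  list(
    record_id = records$record_id[i],
    link_url = records$link_url[i],
    fields = as.list(records[i, header, drop = FALSE])
  )
}

.hit_entries <- function(hits) {
  lapply(seq_len(nrow(hits)), function(i) {
    e <- as.list(hits[i, , drop = FALSE])
    e
  })
}

#' Dispatch one service request
#'
#' Pure request handler: given a path and decoded query parameters, returns
#' the HTTP status and the JSON-ready body. Unknown sources/KOS/terms map to
#' 404, malformed parameters to 400; a valid index never yields 5xx.
#'
#' @param app a `facet_app`.
#' @param path request path, e.g. `"/kos/envo/terms/ENVO:0000002/children"`
#'   (segments already URL-decoded).
#' @param params named list of query parameters (`query`, `offset`,
#'   `limit`, `q`, `source`), already URL-decoded.
#' @return list with `status` (integer) and `body` (list, serializable with
#'   `jsonlite::toJSON(auto_unbox = TRUE)`).
#' @export
handle_request <- function(app, path, params = list()) {
  stopifnot(inherits(app, "facet_app"))
  res <- tryCatch(
    list(status = 200L, body = .route(app, path, params)),
    ontofacet_http_error = function(e) {
      list(status = attr(e, "status"), body = list(error = conditionMessage(e)))
    },
    error = function(e) {
      msg <- conditionMessage(e)
      status <- if (grepl("unknown|not found", msg, ignore.case = TRUE)) 404L else 400L
      list(status = status, body = list(error = msg))
    }
  )
  res
}

.http_fail <- function(status, msg) {
  cond <- structure(
    class = c("ontofacet_http_error", "error", "condition"),
    list(message = msg, call = NULL)
  )
  attr(cond, "status") <- status
  stop(cond)
}

.route <- function(app, path, params) {
  index <- app$index
  seg <- strsplit(sub("^/+", "", path), "/", fixed = TRUE)[[1L]]
  seg <- seg[nzchar(seg)]
  n <- length(seg)
  query <- parse_query_expr(params$query, index)
  int_param <- function(name, default) {
    v <- params[[name]]
    if (is.null(v)) return(default)
    iv <- suppressWarnings(as.integer(v))
    if (is.na(iv)) .http_fail(400L, paste0("parameter '", name, "' must be an integer"))
    iv
  }

  if (n == 1L && seg[1L] == "sources") {
    return(lapply(unname(index$sources), function(s) {
      list(source_id = s$config$source_id,
           display_name = s$config$display_name,
           n_records = nrow(s$records))
    }))
  }

  if (n >= 2L && seg[1L] == "kos") {
    kid <- seg[2L]
    if (!(kid %in% names(index$kos_set))) .http_fail(404L, paste0("unknown KOS '", kid, "'"))
    kos <- index$kos_set[[kid]]
    counts_for <- function(parent) {
      if (is.null(params$source)) return(NULL)
      facet_counts(index, params$source, query, kid, parent = parent)$counts
    }
    if (n == 3L && seg[3L] == "roots") {
      counts <- counts_for(NULL)
      ids <- kos_roots(kos)
      return(lapply(ids, function(id) .term_entry(kos, id, counts[[id]])))
    }
    if (n == 5L && seg[3L] == "terms" && seg[5L] == "children") {
      term <- kos_resolve(kos, seg[4L])
      counts <- counts_for(term)
      ids <- kos_children(kos, term)
      return(lapply(ids, function(id) .term_entry(kos, id, counts[[id]])))
    }
    if (n == 3L && seg[3L] == "autocomplete") {
      q <- params$q
      if (is.null(q)) q <- ""
      limit <- int_param("limit", 10L)
      if (limit < 1L) .http_fail(400L, "limit must be >= 1")
      hits <- kos_autocomplete(kos, q, limit)
      return(lapply(hits, function(t) .term_entry(kos, t$term_id)))
    }
    .http_fail(404L, paste0("no such endpoint: /", paste(seg, collapse = "/")))
  }

  if (n >= 2L && seg[1L] == "sources") {
    sid <- seg[2L]
    if (!(sid %in% names(index$sources))) .http_fail(404L, paste0("unknown source '", sid, "'"))
    src <- index$sources[[sid]]
    if (n == 3L && seg[3L] == "columns") {
      meta <- column_metadata_from_records(src$config, src$records)
      return(lapply(seq_len(nrow(meta)), function(i) {
        list(column = meta$column[i], scanned = meta$scanned[i],
             is_key = meta$is_key[i], kos_ids = as.list(meta$kos_ids[[i]]))
      }))
    }
    if (n == 3L && seg[3L] == "items") {
      offset <- int_param("offset", 0L)
      limit <- int_param("limit", app$config$page_size)
      if (offset < 0L) .http_fail(400L, "offset must be >= 0")
      if (limit < 1L) .http_fail(400L, "limit must be >= 1")
      page <- query_items(index, sid, query, offset = offset, page_size = limit)
      header <- attr(src$records, "header")
      return(list(
        source_id = page$source_id, total = page$total, offset = page$offset,
        page_size = page$page_size,
        per_source = as.list(page$per_source),
        items = lapply(seq_len(nrow(page$items)),
                       function(i) .record_entry(page$items, i, header))
      ))
    }
    if (n == 5L && seg[3L] == "items" && seg[5L] == "breakdown") {
      bd <- match_breakdown(index, sid, seg[4L], query)
      return(list(
        source_id = sid, record_id = seg[4L], n_hits = nrow(bd),
        hits = .hit_entries(bd)
      ))
    }
    .http_fail(404L, paste0("no such endpoint: /", paste(seg, collapse = "/")))
  }

  .http_fail(404L, paste0("no such endpoint: /", paste(seg, collapse = "/")))
}

# column_metadata reads the header from the table file; inside the service
# we already hold the records, so allow path = NULL by reconstructing from
# the in-memory header
column_metadata_from_records <- function(config, records) {
  header <- attr(records, "header")
  kos_ids <- lapply(header, function(col) {
    v <- config$scan_map[[col]]
    if (is.null(v)) character(0) else v
  })
  data.frame(
    column = header,
    scanned = header %in% names(config$scan_map) &
      vapply(kos_ids, length, integer(1)) > 0L,
    is_key = header %in% config$key_columns,
    kos_ids = I(kos_ids),
    stringsAsFactors = FALSE
  )
}

# ---- HTTP loop -------------------------------------------------------------

.url_decode <- function(x) utils::URLdecode(gsub("+", " ", x, fixed = TRUE))

# "GET /a/b?x=1&y=2 HTTP/1.1" -> list(path, params)
.parse_request_line <- function(line) {
  parts <- strsplit(trimws(line), " +")[[1L]]
  if (length(parts) < 2L || parts[1L] != "GET") {
    return(NULL)
  }
  target <- parts[2L]
  qpos <- regexpr("?", target, fixed = TRUE)
  raw_path <- if (qpos > 0L) substr(target, 1L, qpos - 1L) else target
  raw_query <- if (qpos > 0L) substr(target, qpos + 1L, nchar(target)) else ""
  seg <- strsplit(sub("^/+", "", raw_path), "/", fixed = TRUE)[[1L]]
  path <- paste0("/", paste(vapply(seg, .url_decode, character(1)), collapse = "/"))
  params <- list()
  if (nzchar(raw_query)) {
    for (pair in strsplit(raw_query, "&", fixed = TRUE)[[1L]]) {
      eq <- regexpr("=", pair, fixed = TRUE)
      if (eq < 1L) next
      key <- .url_decode(substr(pair, 1L, eq - 1L))
      params[[key]] <- .url_decode(substr(pair, eq + 1L, nchar(pair)))
    }
  }
  list(path = path, params = params)
}

.http_status_text <- c("200" = "OK", "400" = "Bad Request",
                       "404" = "Not Found", "405" = "Method Not Allowed")

#' Run the read-only HTTP/JSON service
#'
#' Serves the seven browsing endpoints over HTTP/1.1 (GET only,
#' `Connection: close`) on a base R server socket, one request at a time.
#' All endpoints are side-effect-free.
#'
#' @param index an `annotation_index`.
#' @param config a `service_config` (host, port, paging and facet
#'   defaults).
#' @param max_requests stop after this many requests (`Inf` to run until
#'   interrupted); useful for scripted runs and tests.
#' @param quiet suppress the per-request log line on stderr.
#' @return number of requests served, invisibly.
#' @export
serve <- function(index, config = service_config(), max_requests = Inf,
                  quiet = FALSE) {
  app <- facet_app(index, config)
  srv <- serverSocket(config$port)
  on.exit(close(srv), add = TRUE)
  if (!quiet) message("ontofacet service listening on ", config$host, ":",
                      config$port)
  served <- 0L
  while (served < max_requests) {
    con <- socketAccept(srv, blocking = TRUE, open = "r+")
    req_line <- tryCatch(readLines(con, n = 1L, warn = FALSE),
                         error = function(e) character(0))
    # drain request headers
    repeat {
      h <- tryCatch(readLines(con, n = 1L, warn = FALSE),
                    error = function(e) character(0))
      if (!length(h) || !nzchar(h)) break
    }
    req <- if (length(req_line)) .parse_request_line(req_line) else NULL
    res <- if (is.null(req)) {
      list(status = 405L, body = list(error = "only GET is supported"))
    } else {
      handle_request(app, req$path, req$params)
    }
    payload <- as.character(jsonlite::toJSON(res$body, auto_unbox = TRUE,
                                             null = "null", digits = NA))
    status <- as.character(res$status)
    writeLines(c(
      paste0("HTTP/1.1 ", status, " ", .http_status_text[[status]]),
      "Content-Type: application/json",
      paste0("Content-Length: ", nchar(payload, type = "bytes")),
      "Connection: close",
      "",
      payload
    ), con, sep = "\r\n")
    flush(con)
    close(con)
    served <- served + 1L
    if (!quiet && !is.null(req)) {
      message(sprintf("%s %s -> %s", "GET", req$path, status))
    }
  }
  invisible(served)
}
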