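# Faceted retrieval with subsumption expansion. A query is a named list
# mapping kos_id -> selected term ids. Semantics: OR within a facet
# (selected terms combine by union of their descendant closures), AND
# across facets (a record must have at least one qualifying hit in every
# restricted facet). Counts are always DISTINCT records, never raw hit
# occurrences — required both for the additive drill-down reading
# (parent 4 = 1 + 2 + 1 over disjoint children) and for multi-parent DAG
# safety.

# validate a query and resolve labels to ids
.validate_query <- function(index, query) {
  if (is.null(query)) return(list())
  stopifnot(is.list(query))
  out <- list()
  for (kid in names(query)) {
    if (!(kid %in% names(index$kos_set))) {
      stop("unknown KOS '", kid, "' in query", call. = FALSE)
    }
    kos <- index$kos_set[[kid]]
    terms <- vapply(as.character(query[[kid]]), function(x) kos_resolve(kos, x),
                    character(1), USE.NAMES = FALSE)
    if (length(terms)) out[[kid]] <- unique(terms)
  }
  out
}

.check_source <- function(index, source_id) {
  if (!(source_id %in% names(index$sources))) {
    stop("unknown source '", source_id, "'", call. = FALSE)
  }
  invisible(source_id)
}

#' Expand a facet selection to its descendant closure
#'
#' @param kos a `kos` object.
#' @param terms character vector of selected term ids (labels accepted).
#' @return character vector: the union of [kos_descendants()] over the
#'   selection; empty selection expands to the empty set (no restriction).
#' @export
expand_selection <- function(kos, terms) {
  if (!length(terms)) return(character(0))
  terms <- vapply(as.character(terms), function(x) kos_resolve(kos, x),
                  character(1), USE.NAMES = FALSE)
  sort(unique(unlist(lapply(terms, function(t) kos_descendants(kos, t)))),
       method = "radix")
}

#' Records of a source matching a faceted query
#'
#' A record matches when, for every facet carrying a selection, it has at
#' least one hit whose term lies in that facet's subsumption-expanded
#' selection. The empty query matches every record of the source.
#'
#' @param index an `annotation_index`.
#' @param source_id id of a source in the index.
#' @param query named list `kos_id -> character vector of term ids/labels`.
#' @return sorted character vector of matching record ids.
#' @export
matching_items <- function(index, source_id, query = list()) {
  .check_source(index, source_id)
  query <- .validate_query(index, query)
  ids <- index$sources[[source_id]]$records$record_id
  h <- index$hits[index$hits$source_id == source_id, , drop = FALSE]
  for (kid in names(query)) {
    closure <- expand_selection(index$kos_set[[kid]], query[[kid]])
    ok <- unique(h$record_id[h$kos_id == kid & h$term_id %in% closure])
    ids <- ids[ids %in% ok]
  }
  sort(ids, method = "radix")
}

#' One page of query results with per-source totals
#'
#' @param index an `annotation_index`.
#' @param source_id the active source.
#' @param query named list `kos_id -> term ids/labels`.
#' @param offset number of matches to skip (>= 0).
#' @param page_size page length (>= 1).
#' @return object of class `result_page`: `source_id`, `total` (distinct
#'   matching records of the active source), `offset`, `page_size`, `items`
#'   (record data.frame rows in ascending `record_id` order) and
#'   `per_source` (named integer vector of distinct-match totals for every
#'   source under the same query — the real-time cross-resource feedback).
#' @export
query_items <- function(index, source_id, query = list(), offset = 0L,
                        page_size = 10L) {
  .check_source(index, source_id)
  stopifnot(offset >= 0L, page_size >= 1L)
  query <- .validate_query(index, query)
  per_source <- vapply(names(index$sources), function(sid) {
    length(matching_items(index, sid, query))
  }, integer(1))
  matches <- matching_items(index, source_id, query)
  total <- length(matches)
  page_ids <- if (offset >= total) character(0) else {
    matches[(offset + 1L):min(total, offset + page_size)]
  }
  records <- index$sources[[source_id]]$records
  items <- records[match(page_ids, records$record_id), , drop = FALSE]
  rownames(items) <- NULL
  structure(
    list(source_id = source_id, total = total, offset = as.integer(offset),
         page_size = as.integer(page_size), items = items,
         per_source = per_source),
    class = "result_page"
  )
}

#' @export
print.result_page <- function(x, ...) {
  cat(sprintf("<result_page> source '%s': %d match(es), showing %d from offset %d\n",
              x$source_id, x$total, nrow(x$items), x$offset))
  if (nrow(x$items)) print(x$items[, c("record_id", "link_url")])
  cat("per-source totals:",
      paste(sprintf("%s=%d", names(x$per_source), x$per_source), collapse = ", "),
      "\n")
  invisible(x)
}

#' Hierarchical facet count distribution
#'
#' The navigational feedback behind drill-down: for every child of `parent`
#' (or every root when `parent` is `NULL`), the number of DISTINCT records
#' of the active source that would match if this facet's selection were
#' replaced by that child alone — all other facets' restrictions staying in
#' force. Each child's count aggregates over its full descendant closure,
#' so a node's count reflects everything filed below it.
#'
#' @param index an `annotation_index`.
#' @param source_id the active source.
#' @param query named list `kos_id -> term ids/labels` (the current
#'   restrictions).
#' @param kos_id the facet whose level is being expanded.
#' @param parent term id/label whose children are counted, or `NULL` for
#'   the root level.
#' @return object of class `facet_counts`: `kos_id`, `parent` (id or `NA`),
#'   and `counts`, a named integer vector keyed by child term id.
#' @export
facet_counts <- function(index, source_id, query = list(), kos_id,
                         parent = NULL) {
  .check_source(index, source_id)
  if (!(kos_id %in% names(index$kos_set))) {
    stop("unknown KOS '", kos_id, "'", call. = FALSE)
  }
  kos <- index$kos_set[[kos_id]]
  query <- .validate_query(index, query)
  kids <- if (is.null(parent)) {
    kos_roots(kos)
  } else {
    kos_children(kos, kos_resolve(kos, parent))
  }
  counts <- vapply(kids, function(child) {
    q2 <- query
    q2[[kos_id]] <- child
    length(matching_items(index, source_id, q2))
  }, integer(1))
  names(counts) <- kids
  structure(
    list(kos_id = kos_id,
         parent = if (is.null(parent)) NA_character_ else kos_resolve(kos, parent),
         counts = counts),
    class = "facet_counts"
  )
}

#' @export
print.facet_counts <- function(x, ...) {
  at <- if (is.na(x$parent)) "<roots>" else x$parent
  cat(sprintf("<facet_counts> facet '%s' at %s:\n", x$kos_id, at))
  for (id in names(x$counts)) cat(sprintf("  %-30s %d\n", id, x$counts[[id]]))
  invisible(x)
}

#' Why a record matches: per-item hit breakdown
#'
#' Returns the record's hits that satisfy the query: each hit whose term
#' lies in some facet's expanded selection, annotated (column `satisfies`)
#' with the selected ancestor term(s) it descends from — e.g. a hit on
#' "kefir" satisfying the selection "dairy product". With an empty query,
#' all hits of the record are returned with `satisfies = NA`.
#'
#' @param index an `annotation_index`.
#' @param source_id source of the record.
#' @param record_id the record.
#' @param query named list `kos_id -> term ids/labels`.
#' @return data.frame of hits with an extra character column `satisfies`
#'   (comma-joined selected ancestors).
#' @export
match_breakdown <- function(index, source_id, record_id, query = list()) {
  .check_source(index, source_id)
  records <- index$sources[[source_id]]$records
  if (!(record_id %in% records$record_id)) {
    stop("unknown record '", record_id, "' in source '", source_id, "'",
         call. = FALSE)
  }
  query <- .validate_query(index, query)
  h <- index$hits[index$hits$source_id == source_id &
                    index$hits$record_id == record_id, , drop = FALSE]
  if (!length(query)) {
    h$satisfies <- NA_character_
    rownames(h) <- NULL
    return(h)
  }
  keep <- logical(nrow(h))
  satisfies <- character(nrow(h))
  for (kid in names(query)) {
    kos <- index$kos_set[[kid]]
    sel <- query[[kid]]
    closures <- lapply(sel, function(t) kos_descendants(kos, t))
    idx <- which(h$kos_id == kid)
    for (i in idx) {
      anc <- sel[vapply(closures, function(cl) h$term_id[i] %in% cl, logical(1))]
      if (length(anc)) {
        keep[i] <- TRUE
        satisfies[i] <- paste(anc, collapse = ",")
      }
    }
  }
  out <- h[keep, , drop = FALSE]
  out$satisfies <- satisfies[keep]
  rownames(out) <- NULL
  out
}
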