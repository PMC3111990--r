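# The annotation index: every source's config and records, the KOS set, the
# match dictionaries and all hits. Queries are read-only; the only mutating
# operation is update_records(), which re-annotates just the changed rows
# and is guaranteed to equal a full rebuild of the same final record set.

.index_hit_cols <- c("source_id", "record_id", "column", "kos_id",
                     "term_id", "start", "end", "matched_text", "kind")

.empty_index_hits <- function() {
  data.frame(
    source_id = character(0), record_id = character(0), column = character(0),
    kos_id = character(0), term_id = character(0), start = integer(0),
    end = integer(0), matched_text = character(0), kind = character(0),
    stringsAsFactors = FALSE
  )
}

# canonical hit order so that rebuilds and incremental updates are
# byte-comparable
.sort_hits <- function(hits) {
  if (!nrow(hits)) return(hits)
  hits <- hits[order(hits$source_id, hits$record_id, hits$column, hits$kos_id,
                     hits$start, hits$end, hits$term_id, method = "radix"), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Annotate all scanned columns of a source's records
#'
#' Applies [annotate_text()] to every (record, scanned column) pair, each
#' column against its configured KOS dictionaries only, and attaches full
#' record context to every hit.
#'
#' @param records record data.frame from [read_table()].
#' @param config the source's `source_config`.
#' @param dicts named list mapping `kos_id` to `match_dict`; every KOS named
#'   in the config's `scan_map` must be present (checked before any work).
#' @return data.frame of hits with columns `source_id`, `record_id`,
#'   `column`, `kos_id`, `term_id`, `start`, `end`, `matched_text`, `kind`.
#' @export
index_source <- function(records, config, dicts) {
  need <- unique(unlist(config$scan_map, use.names = FALSE))
  missing <- setdiff(need, names(dicts))
  if (length(missing)) {
    stop("source '", config$source_id, "': no dictionary for KOS: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (col in names(config$scan_map)) {
    for (kid in config$scan_map[[col]]) {
      dict <- dicts[[kid]]
      for (i in seq_len(nrow(records))) {
        h <- annotate_text(dict, records[[col]][i])
        if (!nrow(h)) next
        h$source_id <- config$source_id
        h$record_id <- records$record_id[i]
        h$column <- col
        h$kos_id <- kid
        out[[length(out) + 1L]] <- h[, .index_hit_cols]
      }
    }
  }
  if (!length(out)) return(.empty_index_hits())
  .sort_hits(do.call(rbind, out))
}

#' Build an annotation index
#'
#' End-to-end construction: build one match dictionary per KOS, read every
#' source table, annotate all scanned columns, and assemble the queryable
#' index.
#'
#' @param kos_set named list of `kos` objects (names are the kos ids) or a
#'   list whose `$kos_id` fields name them.
#' @param configs list of `source_config` objects.
#' @param blacklists either a character vector applied to every KOS, or a
#'   named list mapping `kos_id` to its own blacklist.
#' @return object of class `annotation_index` with fields `kos_set`,
#'   `dicts`, `sources` (named list of `list(config, records)`) and `hits`.
#' @export
build_index <- function(kos_set, configs, blacklists = character(0)) {
  sources <- lapply(configs, function(cfg) {
    list(config = cfg, records = read_table(cfg))
  })
  index_from_records(kos_set, sources, blacklists)
}

#' Assemble an annotation index from in-memory records
#'
#' Same result as [build_index()] but takes already-read record
#' data.frames, which lets generated corpora be indexed without touching
#' the file system.
#'
#' @param kos_set named list of `kos` objects.
#' @param sources list of `list(config = <source_config>, records =
#'   <record data.frame>)`.
#' @param blacklists as in [build_index()].
#' @return an `annotation_index`.
#' @export
index_from_records <- function(kos_set, sources, blacklists = character(0)) {
  if (is.null(names(kos_set)) || any(!nzchar(names(kos_set)))) {
    names(kos_set) <- vapply(kos_set, `[[`, character(1), "kos_id")
  }
  bl_for <- function(kid) {
    if (is.list(blacklists)) {
      v <- blacklists[[kid]]
      if (is.null(v)) character(0) else v
    } else {
      blacklists
    }
  }
  dicts <- lapply(names(kos_set), function(kid) {
    build_dictionary(kos_set[[kid]], blacklist = bl_for(kid))
  })
  names(dicts) <- names(kos_set)

  out <- list()
  hits <- list()
  for (s in sources) {
    cfg <- s$config
    unknown <- setdiff(unique(unlist(cfg$scan_map, use.names = FALSE)),
                       names(kos_set))
    if (length(unknown)) {
      stop("source '", cfg$source_id, "': scan_map names unknown KOS: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (cfg$source_id %in% names(out)) {
      stop("duplicate source id '", cfg$source_id, "'", call. = FALSE)
    }
    out[[cfg$source_id]] <- list(config = cfg, records = s$records)
    hits[[length(hits) + 1L]] <- index_source(s$records, cfg, dicts)
  }
  hits <- if (length(hits)) .sort_hits(do.call(rbind, hits)) else .empty_index_hits()

  structure(
    list(kos_set = kos_set, dicts = dicts, sources = out, hits = hits),
    class = "annotation_index"
  )
}

#' @export
print.annotation_index <- function(x, ...) {
  cat(sprintf("<annotation_index> %d KOS, %d source(s), %d hit(s)\n",
              length(x$kos_set), length(x$sources), nrow(x$hits)))
  for (s in x$sources) {
    cat(sprintf("  %-12s %4d record(s), %4d hit(s)\n", s$config$source_id,
                nrow(s$records), sum(x$hits$source_id == s$config$source_id)))
  }
  invisible(x)
}

#' Re-annotate changed records of one source
#'
#' Implements incremental refresh: hits of the changed record ids are
#' dropped and recomputed from the new cell contents; all other hits are
#' untouched. The result is identical to a full rebuild of the same final
#' record set (tested property). New record ids are appended.
#'
#' @param index an `annotation_index`.
#' @param source_id id of an existing source in the index.
#' @param changed data.frame of the new state of the changed records: same
#'   columns as the source's record data.frame (including `record_id` and
#'   `link_url`).
#' @return the updated `annotation_index`.
#' @export
update_records <- function(index, source_id, changed) {
  if (!(source_id %in% names(index$sources))) {
    stop("unknown source '", source_id, "'", call. = FALSE)
  }
  if (!nrow(changed)) return(index)
  src <- index$sources[[source_id]]
  if (!setequal(names(changed), names(src$records))) {
    stop("changed records must carry exactly the source's columns", call. = FALSE)
  }
  changed <- changed[, names(src$records), drop = FALSE]
  records <- src$records
  is_existing <- changed$record_id %in% records$record_id
  for (i in which(is_existing)) {
    records[records$record_id == changed$record_id[i], ] <- changed[i, ]
  }
  if (any(!is_existing)) {
    records <- rbind(records, changed[!is_existing, , drop = FALSE])
    rownames(records) <- NULL
  }
  index$sources[[source_id]]$records <- records

  drop <- index$hits$source_id == source_id &
    index$hits$record_id %in% changed$record_id
  kept <- index$hits[!drop, , drop = FALSE]
  fresh <- index_source(changed, src$config, index$dicts)
  index$hits <- .sort_hits(rbind(kept, fresh))
  index
}

# ---- persistence -----------------------------------------------------------

#' Persist / load an annotation index as JSON
#'
#' The on-disk form carries the KOS set, the source configs and records, and
#' all hits; dictionaries and closure caches are rebuilt on load, so a
#' reloaded index answers every query identically (tested property).
#'
#' @param index an `annotation_index`.
#' @param path file path.
#' @return `read_index` returns an `annotation_index`; `write_index` returns
#'   `path` invisibly.
#' @export
write_index <- function(index, path) {
  payload <- list(
    format = "ontofacet-index",
    version = 1L,
    kos = lapply(unname(index$kos_set), .kos_to_list),
    sources = lapply(unname(index$sources), function(s) {
      cfg <- s$config
      list(
        config = list(
          source_id = cfg$source_id, display_name = cfg$display_name,
          file = cfg$file, delimiter = cfg$delimiter,
          key_columns = as.list(cfg$key_columns),
          scan_map = lapply(cfg$scan_map, as.list),
          url_template = cfg$url_template
        ),
        columns = as.list(names(s$records)),
        records = lapply(seq_len(nrow(s$records)), function(i) {
          as.list(s$records[i, , drop = FALSE])
        })
      )
    }),
    hits = index$hits
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  x <- jsonlite::read_json(path)
  if (!identical(x$format, "ontofacet-index")) {
    stop(path, " is not an ontofacet index file", call. = FALSE)
  }
  kos_set <- lapply(x$kos, .kos_from_list)
  names(kos_set) <- vapply(kos_set, `[[`, character(1), "kos_id")
  dicts <- lapply(kos_set, build_dictionary)

  sources <- list()
  for (s in x$sources) {
    c0 <- s$config
    cfg <- structure(
      list(
        source_id = c0$source_id, display_name = c0$display_name,
        file = c0$file, delimiter = c0$delimiter,
        key_columns = as.character(unlist(c0$key_columns)),
        scan_map = lapply(c0$scan_map, function(v) as.character(unlist(v))),
        url_template = c0$url_template
      ),
      class = "source_config"
    )
    cols <- as.character(unlist(s$columns))
    rec_rows <- lapply(s$records, function(r) {
      vapply(cols, function(cn) as.character(r[[cn]]), character(1))
    })
    records <- as.data.frame(
      do.call(rbind, c(rec_rows, list(deparse.level = 0))),
      stringsAsFactors = FALSE
    )
    if (!length(rec_rows)) {
      records <- as.data.frame(
        stats::setNames(rep(list(character(0)), length(cols)), cols),
        stringsAsFactors = FALSE, check.names = FALSE
      )
    } else {
      names(records) <- cols
    }
    attr(records, "header") <- setdiff(cols, c("record_id", "link_url"))
    sources[[cfg$source_id]] <- list(config = cfg, records = records)
  }

  h <- x$hits
  hits <- if (length(h) && length(h$source_id)) {
    data.frame(
      source_id = as.character(unlist(h$source_id)),
      record_id = as.character(unlist(h$record_id)),
      column = as.character(unlist(h$column)),
      kos_id = as.character(unlist(h$kos_id)),
      term_id = as.character(unlist(h$term_id)),
      start = as.integer(unlist(h$start)),
      end = as.integer(unlist(h$end)),
      matched_text = as.character(unlist(h$matched_text)),
      kind = as.character(unlist(h$kind)),
      stringsAsFactors = FALSE
    )
  } else {
    .empty_index_hits()
  }

  structure(
    list(kos_set = kos_set, dicts = dicts, sources = sources,
         hits = .sort_hits(hits)),
    class = "annotation_index"
  )
}
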