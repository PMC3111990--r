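# Ingest: turn a delimited table plus a declarative per-source JSON config
# into uniquely identified records. The config declares which columns are
# scanned against which KOS, which columns form the record identifier, and
# the URL template for the back-link to the primary resource.

#' Load and validate a source configuration
#'
#' The JSON schema:
#' ```
#' {
#'   "source_id":    "straininfo",
#'   "display_name": "Strain collection",
#'   "file":         "straininfo.tsv",          // relative to the config file
#'   "delimiter":    "\t",
#'   "key_columns":  ["accession"],
#'   "scan_map":     {"habitat": ["envo"], "location": ["gaz"]},
#'   "url_template": "https://example.org/strain/{accession}"
#' }
#' ```
#' `key_columns` must be non-empty; whether the named columns exist is
#' checked against the table header by [read_table()], and whether each
#' `kos_id` resolves is checked at index time.
#'
#' @param path path to the config JSON file.
#' @return object of class `source_config`; `$file` is resolved relative to
#'   the config file's directory.
#' @export
read_source_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path)
  required <- c("source_id", "display_name", "file", "delimiter",
                "key_columns", "url_template")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop("source config ", path, ": missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  key_columns <- as.character(unlist(x$key_columns))
  if (!length(key_columns)) {
    stop("source config ", path, ": key_columns must be non-empty", call. = FALSE)
  }
  delim <- as.character(x$delimiter)
  if (nchar(delim) != 1L) {
    stop("source config ", path, ": delimiter must be a single character",
         call. = FALSE)
  }
  scan_map <- lapply(x$scan_map, function(v) as.character(unlist(v)))
  file <- as.character(x$file)
  if (!grepl("^(/|[A-Za-z]:)", file)) {
    file <- file.path(dirname(path), file)
  }
  structure(
    list(
      source_id = as.character(x$source_id),
      display_name = as.character(x$display_name),
      file = file,
      delimiter = delim,
      key_columns = key_columns,
      scan_map = scan_map,
      url_template = as.character(x$url_template)
    ),
    class = "source_config"
  )
}

#' @export
print.source_config <- function(x, ...) {
  cat(sprintf("<source_config> %s (\"%s\"): file %s, key [%s], %d scanned column(s)\n",
              x$source_id, x$display_name, basename(x$file),
              paste(x$key_columns, collapse = ", "), length(x$scan_map)))
  invisible(x)
}

# instantiate "https://x/{accession}" from a row; values are URL-escaped;
# any residual placeholder is an error
.fill_url_template <- function(template, row) {
  out <- template
  for (col in names(row)) {
    out <- gsub(paste0("{", col, "}"),
                utils::URLencode(row[[col]], reserved = TRUE),
                out, fixed = TRUE)
  }
  left <- regmatches(out, regexpr("\\{[^}]*\\}", out))
  if (length(left)) {
    stop("url_template placeholder ", left, " does not name a table column",
         call. = FALSE)
  }
  out
}

#' Read a source table into records
#'
#' Reads the delimited file named by the config (header row required, cells
#' trimmed of surrounding whitespace, empty cells kept as empty strings,
#' UTF-8 enforced) and builds one record per data row. The record id is the
#' key-column values joined by `":"`; a duplicate record id is a hard error.
#'
#' @param config a `source_config`.
#' @param path table path; defaults to the config's `file`.
#' @return data.frame with one row per record: all table columns (header
#'   order, names as in the file) plus `record_id` and `link_url`. The
#'   original header is kept in `attr(, "header")`.
#' @export
read_table <- function(config, path = config$file) {
  if (!file.exists(path)) stop("table file not found: ", path, call. = FALSE)
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (any(!validUTF8(raw))) {
    stop("table file ", path, " is not valid UTF-8", call. = FALSE)
  }
  nf <- utils::count.fields(path, sep = config$delimiter, quote = "\"",
                            comment.char = "", blank.lines.skip = TRUE)
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop("table file ", path, ", line ", bad, ": expected ", nf[1L],
         " fields, found ", nf[bad], call. = FALSE)
  }
  df <- utils::read.table(
    path, sep = config$delimiter, header = TRUE, quote = "\"",
    colClasses = "character", check.names = FALSE, comment.char = "",
    encoding = "UTF-8", stringsAsFactors = FALSE
  )
  header <- names(df)
  missing_keys <- setdiff(config$key_columns, header)
  if (length(missing_keys)) {
    stop("source '", config$source_id, "': key column(s) not in header: ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  missing_scan <- setdiff(names(config$scan_map), header)
  if (length(missing_scan)) {
    stop("source '", config$source_id, "': scanned column(s) not in header: ",
         paste(missing_scan, collapse = ", "), call. = FALSE)
  }
  for (col in header) df[[col]] <- trimws(df[[col]])

  record_id <- do.call(paste, c(unname(df[config$key_columns]), sep = ":"))
  if (anyDuplicated(record_id)) {
    dup <- record_id[duplicated(record_id)][1L]
    rows <- which(record_id == dup)
    stop("source '", config$source_id, "': duplicate record id '", dup,
         "' in data rows ", rows[1L], " and ", rows[2L], call. = FALSE)
  }
  link_url <- vapply(seq_len(nrow(df)), function(i) {
    .fill_url_template(config$url_template, as.list(df[i, , drop = FALSE]))
  }, character(1))

  out <- df
  out$record_id <- record_id
  out$link_url <- link_url
  attr(out, "header") <- header
  rownames(out) <- NULL
  out
}

#' Column metadata of a source
#'
#' @param config a `source_config`.
#' @param path table path; defaults to the config's `file`.
#' @return data.frame with one row per column in header order: `column`,
#'   `scanned`, `is_key`, and a list column `kos_ids` naming the KOS each
#'   scanned column is matched against.
#' @export
column_metadata <- function(config, path = config$file) {
  header <- names(utils::read.table(
    path, sep = config$delimiter, header = TRUE, quote = "\"", nrows = 1L,
    colClasses = "character", check.names = FALSE, comment.char = ""
  ))
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

#' Read a blacklist file
#'
#' Plain text, one phrase per line; blank lines and `#` comments ignored.
#'
#' @param path file path.
#' @return character vector of phrases.
#' @export
read_blacklist <- function(path) {
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}
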