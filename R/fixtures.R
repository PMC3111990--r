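# Demo instance fixtures and synthetic corpora. The demo emulates a small
# metadata-integration instance: four facets (species taxonomy, anatomy,
# environment, geography) over five tabular sources (a strain collection, a
# genome project catalogue, marine metagenome samples, an rRNA database and
# literature abstracts). The KOS ship as OBO 1.2 files so the reader is
# exercised end-to-end. synth_corpus() plants known concept mentions into
# filler text for property tests; its filler vocabulary shares no stem with
# any demo KOS, so false positives on generated corpora are impossible by
# construction.

demo_dir <- function() {
  dir <- system.file("extdata", "demo", package = "ontofacet")
  if (!nzchar(dir)) stop("demo fixtures not found; is ontofacet installed?",
                         call. = FALSE)
  dir
}

#' The four demo KOS
#'
#' Loads the checked-in miniature OBO files: `taxo` (species taxonomy with
#' Bacteria/Archaea and Leuconostoc under Firmicutes), `anat` (a small
#' anatomy branch), `envo` (environmental materials with a dairy branch
#' down to kefir) and `gaz` (a gazetteer with Stockholm under Sweden under
#' the Scandinavian Peninsula).
#'
#' @return named list of four `kos` objects.
#' @export
demo_kos <- function() {
  ids <- c("taxo", "anat", "envo", "gaz")
  names_ <- c(taxo = "Taxonomy", anat = "Anatomy",
              envo = "Environment", gaz = "Geography")
  kos <- lapply(ids, function(k) {
    read_obo(file.path(demo_dir(), paste0(k, ".obo")), kos_id = k,
             name = names_[[k]])
  })
  names(kos) <- ids
  kos
}

#' The five demo source configurations
#'
#' @return list of five `source_config` objects (strain collection, genome
#'   project catalogue, marine samples, rRNA database, literature
#'   abstracts), file paths resolved into the installed fixture directory.
#' @export
demo_sources <- function() {
  read_source_list(file.path(demo_dir(), "sources.json"))
}

#' Read a source list file
#'
#' A JSON object `{"sources": [<config path>, ...]}`; relative paths are
#' resolved against the list file's directory.
#'
#' @param path path to the source list JSON.
#' @return list of `source_config` objects.
#' @export
read_source_list <- function(path) {
  x <- jsonlite::read_json(path)
  paths <- as.character(unlist(x$sources))
  if (!length(paths)) stop("source list ", path, " names no sources", call. = FALSE)
  lapply(paths, function(p) {
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(dirname(path), p)
    read_source_config(p)
  })
}

#' Build the demo annotation index
#'
#' End-to-end build of the demo instance: four KOS, five sources, the
#' checked-in blacklist. Deterministic — repeated builds are identical.
#'
#' @return an `annotation_index`.
#' @export
demo_index <- function() {
  build_index(demo_kos(), demo_sources(),
              blacklists = read_blacklist(file.path(demo_dir(), "blacklist.txt")))
}

#' Copy the demo fixture files into a directory
#'
#' Writes the OBO files, tables, source configs, source list and blacklist
#' so they can be inspected or used as a template for a new instance.
#'
#' @param dir target directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_demo_fixtures <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  src <- list.files(demo_dir(), full.names = TRUE)
  ok <- file.copy(src, dir, overwrite = TRUE)
  if (!all(ok)) stop("could not copy fixtures into ", dir, call. = FALSE)
  invisible(file.path(dir, basename(src)))
}

# run fn with a private RNG stream so generators are deterministic per seed
# without clobbering the caller's RNG state
.with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# filler words; none of their Porter stems occurs in any demo KOS name
.synth_fillers <- c(
  "blorp", "znag", "quivvle", "frall", "dronk", "plizz", "vornak",
  "grubbin", "sloosh", "krandle", "fweep", "zorter", "mipsle", "trandor",
  "glieb", "snorf", "wubble", "crintz", "drazzle", "plonk"
)

#' Generate a corpus with planted concept mentions
#'
#' Each record's scanned cell (`text`) is filler prose carrying 0-3 planted
#' concept names from `kos`. With probability `mutation_rate` a plant is
#' mutated: `"inflect"` pluralises its last word, `"reorder"` permutes the
#' words of a multi-word name (single-word plants are left verbatim under
#' reorder-only mutation). The planted ground truth is recorded, so
#' annotator recall can be measured exactly. Deterministic per seed.
#'
#' @param n_records number of records (>= 1).
#' @param kos the `kos` whose term labels are planted.
#' @param seed integer seed.
#' @param mutation_rate fraction of plants mutated, in `[0, 1]`.
#' @param mutation_kinds subset of `c("inflect", "reorder")`.
#' @return object of class `planted_corpus`: `records` (data.frame with
#'   `rid`, `text`, `record_id`, `link_url`), `config` (a `source_config`
#'   scanning `text` against the KOS), `ground_truth` (data.frame
#'   `record_id`, `column`, `term_id`, `mutated`) and `seed`.
#' @export
synth_corpus <- function(n_records, kos, seed, mutation_rate = 0,
                         mutation_kinds = c("inflect", "reorder")) {
  stopifnot(n_records >= 1L, mutation_rate >= 0, mutation_rate <= 1)
  mutation_kinds <- match.arg(mutation_kinds, several.ok = TRUE)
  dict <- build_dictionary(kos)
  plantable <- setdiff(names(kos$terms), dict$unmatchable)
  plantable <- plantable[!vapply(kos$terms[plantable], `[[`, logical(1), "obsolete")]
  labels <- vapply(kos$terms[plantable], `[[`, character(1), "label")

  .with_seed(seed, function() {
    texts <- character(n_records)
    gt <- list()
    for (i in seq_len(n_records)) {
      n_plants <- sample(0:3, 1L)
      plants <- if (n_plants) sample(plantable, min(n_plants, length(plantable))) else character(0)
      words <- sample(.synth_fillers, sample(2:4, 1L), replace = TRUE)
      for (tid in plants) {
        nm <- labels[[tid]]
        toks <- strsplit(nm, "\\s+")[[1L]]
        mutated <- "none"
        if (stats::runif(1) < mutation_rate) {
          kind <- if (length(mutation_kinds) == 1L) mutation_kinds else sample(mutation_kinds, 1L)
          if (kind == "inflect") {
            # pluralising a word already ending in s would not stem back to
            # the dictionary key; leave such plants verbatim
            if (!endsWith(toks[length(toks)], "s")) {
              toks[length(toks)] <- paste0(toks[length(toks)], "s")
              mutated <- "inflect"
            }
          } else if (length(toks) > 1L) {
            repeat {
              perm <- sample(seq_along(toks))
              if (any(perm != seq_along(toks))) break
            }
            toks <- toks[perm]
            mutated <- "reorder"
          }
        }
        words <- c(words, toks,
                   sample(.synth_fillers, sample(1:3, 1L), replace = TRUE))
        gt[[length(gt) + 1L]] <- data.frame(
          record_id = sprintf("S%04d", i), column = "text", term_id = tid,
          mutated = mutated, stringsAsFactors = FALSE
        )
      }
      texts[i] <- paste(words, collapse = " ")
    }
    rid <- sprintf("S%04d", seq_len(n_records))
    records <- data.frame(
      rid = rid, text = texts, record_id = rid,
      link_url = paste0("https://example.org/synth/", rid),
      stringsAsFactors = FALSE
    )
    attr(records, "header") <- c("rid", "text")
    config <- structure(
      list(
        source_id = "synth", display_name = "Planted corpus",
        file = NA_character_, delimiter = "\t", key_columns = "rid",
        scan_map = stats::setNames(list(kos$kos_id), "text"),
        url_template = "https://example.org/synth/{rid}"
      ),
      class = "source_config"
    )
    ground_truth <- if (length(gt)) do.call(rbind, gt) else data.frame(
      record_id = character(0), column = character(0), term_id = character(0),
      mutated = character(0), stringsAsFactors = FALSE
    )
    structure(
      list(records = records, config = config, ground_truth = ground_truth,
           seed = seed),
      class = "planted_corpus"
    )
  })
}

#' @export
print.planted_corpus <- function(x, ...) {
  cat(sprintf("<planted_corpus> seed %d: %d record(s), %d planted mention(s)\n",
              x$seed, nrow(x$records), nrow(x$ground_truth)))
  invisible(x)
}
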