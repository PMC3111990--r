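# Knowledge Organization Systems (KOS): ontologies, taxonomies and gazetteers
# represented as concept DAGs. One Kos per facet. Only is_a edges define the
# hierarchy; other OBO relationship lines are ignored. Obsolete terms are kept
# in the term set but excluded from roots, children, autocomplete and match
# dictionaries.

#' Construct a KOS from a list of terms
#'
#' Low-level constructor used by [read_obo()] and by tests/generators that
#' build concept DAGs in code. Validates the invariants every KOS must hold:
#' unique non-empty ids, labels on non-obsolete terms, resolvable parents,
#' acyclicity, and at least one root.
#'
#' @param kos_id short facet key, e.g. `"envo"`.
#' @param terms list of term lists, each with `term_id`, `label`,
#'   optional `synonyms` (character), `parents` (character of term ids) and
#'   `obsolete` (logical).
#' @param name display name; defaults to `kos_id`.
#' @return object of class `kos`.
#' @export
new_kos <- function(kos_id, terms, name = kos_id) {
  stopifnot(is.character(kos_id), length(kos_id) == 1L, nzchar(kos_id))
  terms <- lapply(terms, function(t) {
    list(
      term_id = as.character(t$term_id),
      label = if (is.null(t$label)) "" else as.character(t$label),
      synonyms = if (is.null(t$synonyms)) character(0) else as.character(t$synonyms),
      parents = if (is.null(t$parents)) character(0) else as.character(t$parents),
      obsolete = isTRUE(t$obsolete)
    )
  })
  ids <- vapply(terms, `[[`, character(1), "term_id")
  if (any(!nzchar(ids))) stop("KOS '", kos_id, "': empty term id", call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("KOS '", kos_id, "': duplicate term id '", ids[duplicated(ids)][1L], "'",
         call. = FALSE)
  }
  names(terms) <- ids
  for (t in terms) {
    if (!t$obsolete && !nzchar(t$label)) {
      stop("KOS '", kos_id, "': term '", t$term_id, "' has no label", call. = FALSE)
    }
    bad <- setdiff(t$parents, ids)
    if (length(bad)) {
      stop("KOS '", kos_id, "': term '", t$term_id,
           "' has unresolvable parent '", bad[1L], "'", call. = FALSE)
    }
  }

  kos <- structure(
    list(kos_id = kos_id, name = name, terms = terms),
    class = "kos"
  )
  cyc <- .kos_find_cycle(kos)
  if (!is.null(cyc)) {
    stop("KOS '", kos_id, "': is_a cycle detected: ",
         paste(cyc, collapse = " -> "), call. = FALSE)
  }
  if (!length(kos_roots(kos))) {
    stop("KOS '", kos_id, "': no root terms (every non-obsolete term has parents, ",
         "or the KOS is empty)", call. = FALSE)
  }
  kos$children <- .kos_children_map(kos)
  kos$cache <- new.env(parent = emptyenv())
  kos
}

# child adjacency: named list term_id -> character vector of child ids,
# each sorted by child label
.kos_children_map <- function(kos) {
  ids <- names(kos$terms)
  ch <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) ch[[id]] <- character(0)
  for (t in kos$terms) {
    for (p in t$parents) ch[[p]] <- c(ch[[p]], t$term_id)
  }
  labels <- vapply(kos$terms, `[[`, character(1), "label")
  lapply(ch, function(kids) kids[order(labels[kids], kids, method = "radix")])
}

# returns one cycle as a vector of ids, or NULL if acyclic (Kahn's algorithm
# on parent edges, then a walk through the leftover subgraph)
.kos_find_cycle <- function(kos) {
  ids <- names(kos$terms)
  parents <- lapply(kos$terms, `[[`, "parents")
  indeg <- stats::setNames(integer(length(ids)), ids) # number of parents left
  for (id in ids) indeg[[id]] <- length(parents[[id]])
  kids <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) for (p in parents[[id]]) kids[[p]] <- c(kids[[p]], id)
  queue <- ids[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (k in kids[[v]]) {
      indeg[[k]] <- indeg[[k]] - 1L
      if (indeg[[k]] == 0L) queue <- c(queue, k)
    }
  }
  if (seen == length(ids)) return(NULL)
  # walk parent links inside the residual graph until a node repeats
  left <- ids[indeg > 0L]
  v <- left[[1L]]
  path <- character(0)
  while (!(v %in% path)) {
    path <- c(path, v)
    v <- intersect(parents[[v]], left)[[1L]]
  }
  c(path[which(path == v):length(path)], v)
}

.kos_check_term <- function(kos, term_id) {
  if (!(term_id %in% names(kos$terms))) {
    stop("KOS '", kos$kos_id, "': unknown term '", term_id, "'", call. = FALSE)
  }
  invisible(term_id)
}

#' @export
print.kos <- function(x, ...) {
  n_obs <- sum(vapply(x$terms, `[[`, logical(1), "obsolete"))
  cat(sprintf("<kos> %s (\"%s\"): %d terms (%d obsolete), %d roots\n",
              x$kos_id, x$name, length(x$terms), n_obs, length(kos_roots(x))))
  invisible(x)
}

#' Root concepts of a KOS
#'
#' @param kos a `kos` object.
#' @return character vector of term ids of all non-obsolete terms with no
#'   parents, sorted by label.
#' @export
kos_roots <- function(kos) {
  keep <- vapply(kos$terms, function(t) !t$obsolete && !length(t$parents), logical(1))
  ids <- names(kos$terms)[keep]
  labels <- vapply(kos$terms[ids], `[[`, character(1), "label")
  ids[order(labels, ids, method = "radix")]
}

#' Child concepts of a term
#'
#' @param kos a `kos` object.
#' @param term_id a term id present in `kos`.
#' @return character vector of ids of non-obsolete terms having `term_id`
#'   among their parents, sorted by label; empty for leaves.
#' @export
kos_children <- function(kos, term_id) {
  .kos_check_term(kos, term_id)
  kids <- kos$children[[term_id]]
  kids[!vapply(kos$terms[kids], `[[`, logical(1), "obsolete")]
}

#' Descendant closure of a term
#'
#' Reflexive transitive closure under the child relation: the term itself
#' plus everything reachable downward. Correct on DAGs (a node reachable by
#' several paths appears once). This closure is what subsumption-expanded
#' queries search over: selecting "dairy product" retrieves items annotated
#' with "kefir" because kefir lies in the closure. Closures are cached per
#' term; the cache lives inside the `kos` object and is rebuilt on reload.
#'
#' @param kos a `kos` object.
#' @param term_id a term id present in `kos`.
#' @return character vector of term ids, sorted; always contains `term_id`.
#' @export
kos_descendants <- function(kos, term_id) {
  .kos_check_term(kos, term_id)
  cached <- kos$cache[[term_id]]
  if (!is.null(cached)) return(cached)
  seen <- character(0)
  stack <- term_id
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (v %in% seen) next
    seen <- c(seen, v)
    stack <- c(stack, kos$children[[v]])
  }
  out <- sort(seen, method = "radix")
  assign(term_id, out, envir = kos$cache)
  out
}

#' Substring autocomplete over concept names
#'
#' Finds non-obsolete terms whose label or any synonym contains `query`
#' case-insensitively, ranked by earliest match position, then shorter
#' label, then label lexicographically.
#'
#' @param kos a `kos` object.
#' @param query substring to look for; empty string returns no matches.
#' @param limit maximum number of terms returned (>= 1).
#' @return list of term entries (`term_id`, `label`, `synonyms`, `parents`,
#'   `obsolete`), best match first.
#' @export
kos_autocomplete <- function(kos, query, limit = 10L) {
  stopifnot(limit >= 1L)
  if (is.na(query) || !nzchar(query)) return(list())
  q <- tolower(query)
  hits <- list(); pos <- integer(0); lablen <- integer(0); lab <- character(0)
  for (t in kos$terms) {
    if (t$obsolete) next
    names_ <- tolower(c(t$label, t$synonyms))
    p <- regexpr(q, names_, fixed = TRUE)
    p <- p[p > 0L]
    if (!length(p)) next
    hits[[length(hits) + 1L]] <- t
    pos <- c(pos, min(p))
    lablen <- c(lablen, nchar(t$label))
    lab <- c(lab, t$label)
  }
  if (!length(hits)) return(list())
  ord <- order(pos, lablen, lab, method = "radix")
  hits[ord][seq_len(min(limit, length(hits)))]
}

#' Resolve a term label or id to a term id
#'
#' Accepts either a term id or a (case-insensitive) label of a non-obsolete
#' term. Used wherever queries arrive as human-readable labels (CLI, service).
#'
#' @param kos a `kos` object.
#' @param x a single term id or label.
#' @return the term id.
#' @export
kos_resolve <- function(kos, x) {
  stopifnot(length(x) == 1L)
  if (x %in% names(kos$terms)) return(x)
  labels <- vapply(kos$terms, `[[`, character(1), "label")
  obs <- vapply(kos$terms, `[[`, logical(1), "obsolete")
  cand <- names(kos$terms)[!obs & tolower(labels) == tolower(x)]
  if (length(cand) == 1L) return(cand)
  if (length(cand) > 1L) {
    stop("KOS '", kos$kos_id, "': label '", x, "' is ambiguous (",
         paste(cand, collapse = ", "), ")", call. = FALSE)
  }
  stop("KOS '", kos$kos_id, "': unknown term '", x, "'", call. = FALSE)
}

#' Labels of term ids
#'
#' @param kos a `kos` object.
#' @param term_ids character vector of term ids.
#' @return character vector of labels, same order.
#' @export
kos_label <- function(kos, term_ids) {
  vapply(term_ids, function(id) {
    .kos_check_term(kos, id)
    kos$terms[[id]]$label
  }, character(1), USE.NAMES = FALSE)
}

# ---- OBO 1.2 reader --------------------------------------------------------

# extracts the quoted definition from a synonym line:
#   synonym: "raw milk" EXACT []
.obo_synonym_text <- function(value, path, lineno) {
  m <- regmatches(value, regexec('^"((?:[^"\\\\]|\\\\.)*)"', value))[[1L]]
  if (length(m) < 2L) {
    stop("OBO parse error at ", path, ":", lineno,
         ": malformed synonym line", call. = FALSE)
  }
  gsub('\\\\(.)', "\\1", m[[2L]])
}

#' Read a KOS from an OBO 1.2 flat file
#'
#' Parses `[Term]` stanzas: `id` and `name` become the term id and label,
#' `synonym` lines contribute alternative names, `is_a` lines the parent
#' links, and `is_obsolete: true` marks obsolete terms. All other stanza
#' types and tags (including non-`is_a` relationships such as `part_of`)
#' are ignored: the facet hierarchy is pure subsumption. The loaded DAG is
#' validated (acyclic, at least one root, parents resolvable).
#'
#' @param path path to an OBO 1.2 flat file.
#' @param kos_id facet key; defaults to the file name without extension.
#' @param name display name; defaults to `kos_id`.
#' @return object of class `kos`.
#' @export
read_obo <- function(path, kos_id = NULL, name = NULL) {
  if (!file.exists(path)) stop("OBO file not found: ", path, call. = FALSE)
  if (is.null(kos_id)) kos_id <- tools::file_path_sans_ext(basename(path))
  if (is.null(name)) name <- kos_id
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (any(!validUTF8(lines))) {
    stop("OBO file ", path, " is not valid UTF-8", call. = FALSE)
  }

  terms <- list()
  cur <- NULL
  cur_line <- 0L
  in_term <- FALSE
  flush <- function() {
    if (is.null(cur)) return()
    if (is.null(cur$term_id)) {
      stop("OBO parse error at ", path, ":", cur_line,
           ": [Term] stanza without id", call. = FALSE)
    }
    terms[[length(terms) + 1L]] <<- cur
  }
  for (i in seq_along(lines)) {
    line <- sub("\\s+$", "", lines[[i]])
    # strip unescaped trailing comment
    line <- sub("(^|[^\\\\]) !.*$", "\\1", line)
    if (!nzchar(line)) next
    if (grepl("^\\[", line)) {
      flush()
      cur <- NULL
      in_term <- identical(line, "[Term]")
      if (in_term) {
        cur <- list(term_id = NULL, label = "", synonyms = character(0),
                    parents = character(0), obsolete = FALSE)
        cur_line <- i
      }
      next
    }
    if (!in_term) next
    sep <- regexpr(":", line, fixed = TRUE)
    if (sep < 1L) {
      stop("OBO parse error at ", path, ":", i, ": expected 'tag: value' line",
           call. = FALSE)
    }
    tag <- substr(line, 1L, sep - 1L)
    value <- trimws(substr(line, sep + 1L, nchar(line)))
    if (tag == "id") {
      if (!nzchar(value)) {
        stop("OBO parse error at ", path, ":", i, ": empty id", call. = FALSE)
      }
      cur$term_id <- value
    } else if (tag == "name") {
      cur$label <- value
    } else if (tag == "synonym") {
      cur$synonyms <- c(cur$synonyms, .obo_synonym_text(value, path, i))
    } else if (tag == "is_a") {
      parent <- trimws(strsplit(value, "!", fixed = TRUE)[[1L]][[1L]])
      if (!nzchar(parent)) {
        stop("OBO parse error at ", path, ":", i, ": empty is_a target",
             call. = FALSE)
      }
      cur$parents <- unique(c(cur$parents, parent))
    } else if (tag == "is_obsolete") {
      cur$obsolete <- tolower(value) == "true"
    }
    # other tags (def, xref, part_of relationships, ...) are ignored
  }
  flush()
  new_kos(kos_id, terms, name = name)
}

# ---- JSON serialization ----------------------------------------------------

.kos_to_list <- function(kos) {
  list(
    kos_id = kos$kos_id,
    name = kos$name,
    terms = lapply(unname(kos$terms), function(t) {
      list(term_id = t$term_id, label = t$label,
           synonyms = as.list(t$synonyms), parents = as.list(t$parents),
           obsolete = t$obsolete)
    })
  )
}

.kos_from_list <- function(x) {
  terms <- lapply(x$terms, function(t) {
    list(term_id = t$term_id, label = t$label,
         synonyms = as.character(unlist(t$synonyms)),
         parents = as.character(unlist(t$parents)),
         obsolete = isTRUE(t$obsolete))
  })
  new_kos(x$kos_id, terms, name = x$name)
}

#' Write / read the stable JSON form of a KOS
#'
#' The persisted form (kos_id, name, term array with ids, labels, synonyms,
#' parents, obsolete flags) round-trips to an identical term set; caches are
#' rebuilt on load.
#'
#' @param kos a `kos` object.
#' @param path file path.
#' @return `read_kos_json` returns a `kos`; `write_kos_json` returns `path`
#'   invisibly.
#' @export
write_kos_json <- function(kos, path) {
  jsonlite::write_json(.kos_to_list(kos), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_kos_json
#' @export
read_kos_json <- function(path) {
  .kos_from_list(jsonlite::read_json(path))
}
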