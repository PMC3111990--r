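# Match dictionaries: every non-obsolete term contributes its label and all
# synonyms. Each name is normalised to (a) an ordered Porter-stem key and
# (b) an order-insensitive sorted-stem key, with stop-words removed from
# multi-word names. Blacklisted phrases (normalised the same way) contribute
# nothing and are additionally suppressed at match time.

# normalised token stems of a phrase after stop-word removal; NULL when
# nothing matchable remains (empty phrase, or a lone stop-word)
.dict_key_stems <- function(phrase, stopwords) {
  toks <- tokenize(phrase)
  if (!nrow(toks)) return(NULL)
  if (nrow(toks) > 1L) toks <- toks[!(toks$lower %in% stopwords), , drop = FALSE]
  if (!nrow(toks) || all(toks$lower %in% stopwords)) return(NULL)
  toks$stem
}

.dict_ordered_key <- function(stems) paste(stems, collapse = " ")
.dict_sorted_key <- function(stems) paste(sort(stems, method = "radix"), collapse = " ")

#' Build a concept-matching dictionary from a KOS
#'
#' @param kos a `kos` object.
#' @param blacklist character vector of phrases whose matches are suppressed
#'   as known false positives; normalised with the same stemming pipeline as
#'   dictionary keys, so suppression is robust to case and inflection.
#' @param stopwords words removed from multi-word keys (and match windows);
#'   a single stop-word is never matchable.
#' @return object of class `match_dict` with ordered and order-insensitive
#'   key maps, the case-folded verbatim names per term (for exact-match
#'   classification), the longest entry length and the normalised blacklist.
#'   Terms left without any usable name are recorded in `$unmatchable`.
#' @export
build_dictionary <- function(kos, blacklist = character(0),
                             stopwords = .default_stopwords) {
  bl_keys <- character(0)
  for (b in blacklist) {
    stems <- .dict_key_stems(b, stopwords)
    if (is.null(stems)) next
    bl_keys <- c(bl_keys, .dict_ordered_key(stems), .dict_sorted_key(stems))
  }
  bl_keys <- unique(bl_keys)

  ordered <- new.env(parent = emptyenv())
  unordered <- new.env(parent = emptyenv())
  names_folded <- list()
  max_len <- 0L
  unmatchable <- character(0)

  add <- function(env, key, term_id) {
    cur <- env[[key]]
    if (is.null(cur)) cur <- character(0)
    if (!(term_id %in% cur)) assign(key, c(cur, term_id), envir = env)
  }

  for (t in kos$terms) {
    if (t$obsolete) next
    any_entry <- FALSE
    folded <- character(0)
    for (nm in c(t$label, t$synonyms)) {
      toks <- tokenize(nm)
      stems <- .dict_key_stems(nm, stopwords)
      if (is.null(stems)) next
      ok <- .dict_ordered_key(stems)
      sk <- .dict_sorted_key(stems)
      if (ok %in% bl_keys || sk %in% bl_keys) next
      add(ordered, ok, t$term_id)
      add(unordered, sk, t$term_id)
      folded <- c(folded, tolower(nm))
      max_len <- max(max_len, nrow(toks))
      any_entry <- TRUE
    }
    if (any_entry) {
      names_folded[[t$term_id]] <- unique(folded)
    } else {
      unmatchable <- c(unmatchable, t$term_id)
    }
  }

  structure(
    list(
      kos_id = kos$kos_id,
      ordered = ordered,
      unordered = unordered,
      names_folded = names_folded,
      max_len = max_len,
      blacklist = bl_keys,
      stopwords = stopwords,
      unmatchable = unmatchable
    ),
    class = "match_dict"
  )
}

#' @export
print.match_dict <- function(x, ...) {
  cat(sprintf("<match_dict> kos '%s': %d ordered keys, max entry %d tokens, %d blacklisted keys, %d unmatchable terms\n",
              x$kos_id, length(ls(x$ordered)), x$max_len,
              length(x$blacklist), length(x$unmatchable)))
  invisible(x)
}
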