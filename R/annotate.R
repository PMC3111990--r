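# Dictionary-based concept recognition over free text. A token window
# matches a term when its (stop-word-filtered) stems equal a dictionary key
# in order (kind "stemmed", upgraded to "exact" when the verbatim slice
# case-folds to a concept name) or as a multiset (kind "rearranged").
# Overlapping hits to the SAME term are deduplicated keeping the longest
# span; hits to different terms may overlap or nest freely — nested
# distinct concepts ("fermented dairy product" containing "dairy product")
# are all kept, which the hierarchical rollup counts rely on.

.hit_cols <- c("term_id", "start", "end", "matched_text", "kind")

.empty_hits <- function() {
  data.frame(
    term_id = character(0), start = integer(0), end = integer(0),
    matched_text = character(0), kind = character(0), stringsAsFactors = FALSE
  )
}

.kind_rank <- c(exact = 1L, stemmed = 2L, rearranged = 3L)

# per-term dedup: keep longest span, ties by kind priority then earliest
# start; later candidates overlapping a kept span for the same term drop out
.dedup_hits <- function(hits) {
  if (nrow(hits) <= 1L) return(hits)
  keep <- logical(nrow(hits))
  for (tid in unique(hits$term_id)) {
    idx <- which(hits$term_id == tid)
    ord <- idx[order(-(hits$end[idx] - hits$start[idx]),
                     .kind_rank[hits$kind[idx]],
                     hits$start[idx], method = "radix")]
    kept_start <- integer(0); kept_end <- integer(0)
    for (i in ord) {
      if (any(hits$start[i] < kept_end & kept_start < hits$end[i])) next
      keep[i] <- TRUE
      kept_start <- c(kept_start, hits$start[i])
      kept_end <- c(kept_end, hits$end[i])
    }
  }
  hits[keep, , drop = FALSE]
}

#' Detect concept mentions in a text passage
#'
#' Scans every contiguous token window (up to the dictionary's longest entry,
#' with slack for interior stop-words) and reports all concept matches with
#' character spans into the original text. Match kinds: `exact` (the verbatim
#' slice case-folds to a concept name), `stemmed` (ordered stems equal an
#' ordered key) and `rearranged` (stem multiset equals a key, order
#' ignored). Windows whose normalised form is blacklisted never match.
#'
#' @param dict a `match_dict` from [build_dictionary()].
#' @param text a single string.
#' @return data.frame of hits with columns `term_id`, `start`, `end`
#'   (0-based half-open character offsets), `matched_text` (the original
#'   slice) and `kind`; sorted by (start, end, term_id). Zero rows when
#'   nothing matches.
#' @examples
#' \dontrun{
#' annotate_text(dict, "isolated from kefir in Stockholm")
#' }
#' @export
annotate_text <- function(dict, text) {
  stopifnot(inherits(dict, "match_dict"), length(text) == 1L)
  if (is.na(text) || !nzchar(text) || dict$max_len == 0L) return(.empty_hits())
  toks <- tokenize(text)
  n <- nrow(toks)
  if (!n) return(.empty_hits())
  win_cap <- max(dict$max_len, 6L)
  is_stop <- toks$lower %in% dict$stopwords

  out_term <- character(0); out_start <- integer(0); out_end <- integer(0)
  out_text <- character(0); out_kind <- character(0)

  for (i in seq_len(n)) {
    if (is_stop[i]) next # windows never start on a stop-word
    for (j in i:min(n, i + win_cap - 1L)) {
      if (is_stop[j]) next # nor end on one
      sel <- i:j
      sel <- sel[!is_stop[sel]]
      stems <- toks$stem[sel]
      if (length(stems) > dict$max_len) break
      ok <- .dict_ordered_key(stems)
      sk <- .dict_sorted_key(stems)
      if (ok %in% dict$blacklist || sk %in% dict$blacklist) next
      terms_o <- dict$ordered[[ok]]
      terms_u <- dict$unordered[[sk]]
      cand <- unique(c(terms_o, terms_u))
      if (!length(cand)) next
      slice <- substr(text, toks$start[i] + 1L, toks$end[j])
      slice_folded <- tolower(slice)
      for (tid in cand) {
        kind <- if (slice_folded %in% dict$names_folded[[tid]]) {
          "exact"
        } else if (tid %in% terms_o) {
          "stemmed"
        } else {
          "rearranged"
        }
        out_term <- c(out_term, tid)
        out_start <- c(out_start, toks$start[i])
        out_end <- c(out_end, toks$end[j])
        out_text <- c(out_text, slice)
        out_kind <- c(out_kind, kind)
      }
    }
  }
  hits <- data.frame(
    term_id = out_term, start = out_start, end = out_end,
    matched_text = out_text, kind = out_kind, stringsAsFactors = FALSE
  )
  hits <- .dedup_hits(hits)
  hits <- hits[order(hits$start, hits$end, hits$term_id, method = "radix"), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}
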