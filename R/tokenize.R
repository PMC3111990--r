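#' Tokenize text with character offsets
#'
#' Splits a string into word tokens on non-alphanumeric boundaries, keeping
#' for every token its character span in the original text (0-based,
#' half-open) and its Porter stem. Offsets always satisfy
#' `substr(text, start + 1, end) == surface`.
#'
#' @param text a single string; `""` or `NA` yields zero tokens.
#' @return data.frame with columns `surface` (original slice), `lower`
#'   (case-folded surface), `stem` (Porter stem of `lower`), `start`, `end`
#'   (integer offsets).
#' @examples
#' tokenize("Dairy products.")
#' @export
tokenize <- function(text) {
  stopifnot(length(text) == 1L)
  empty <- data.frame(
    surface = character(0), lower = character(0), stem = character(0),
    start = integer(0), end = integer(0), stringsAsFactors = FALSE
  )
  if (is.na(text) || !nzchar(text)) return(empty)
  m <- gregexpr("[[:alnum:]]+", text)[[1L]]
  if (m[1L] == -1L) return(empty)
  start1 <- as.integer(m)
  len <- attr(m, "match.length")
  surface <- substring(text, start1, start1 + len - 1L)
  lower <- tolower(surface)
  data.frame(
    surface = surface,
    lower = lower,
    stem = porter_stem(lower),
    start = start1 - 1L,
    end = start1 + len - 1L,
    stringsAsFactors = FALSE
  )
}

# default stop-words removed from multi-token dictionary keys and match
# windows; a single stop-word token is never matchable on its own
.default_stopwords <- c("of", "the", "a", "an", "and")
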