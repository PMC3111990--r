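# Porter stemming algorithm (classic 1980 definition), used to normalise
# dictionary keys and text tokens so that inflected mentions ("products",
# "soils") still match concept names. Follows the reference implementation's
# control flow: within each step the first matching rule in listed order is
# tried and, if its measure condition fails, no other rule of that step fires.

.pt_vowels <- c("a", "e", "i", "o", "u")

# consonant test on a letter vector; 'y' is a consonant at position 1 or
# after a vowel
.pt_cons <- function(l, i) {
  ch <- l[i]
  if (ch %in% .pt_vowels) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!.pt_cons(l, i - 1L))
  }
  TRUE
}

.pt_types <- function(l) {
  if (!length(l)) return(logical(0))
  vapply(seq_along(l), function(i) .pt_cons(l, i), logical(1))
}

# measure m: number of vowel->consonant transitions, i.e. the m of
# [C](VC){m}[V]
.pt_m <- function(l) {
  tp <- .pt_types(l)
  if (length(tp) < 2L) return(0L)
  sum(!tp[-length(tp)] & tp[-1L])
}

.pt_has_vowel <- function(l) any(!.pt_types(l))

.pt_double_cons <- function(l) {
  n <- length(l)
  n >= 2L && l[n] == l[n - 1L] && .pt_cons(l, n)
}

# *o: stem ends cvc where the final c is not w, x or y
.pt_cvc <- function(l) {
  n <- length(l)
  if (n < 3L) return(FALSE)
  .pt_cons(l, n - 2L) && !.pt_cons(l, n - 1L) && .pt_cons(l, n) &&
    !(l[n] %in% c("w", "x", "y"))
}

.pt_ends <- function(l, suf) {
  n <- length(l)
  k <- nchar(suf)
  if (k > n) return(FALSE)
  paste(l[(n - k + 1L):n], collapse = "") == suf
}

.pt_chop <- function(l, suf) l[seq_len(length(l) - nchar(suf))]

.pt_replace <- function(l, suf, rep) {
  stem <- .pt_chop(l, suf)
  if (nzchar(rep)) c(stem, strsplit(rep, "", fixed = TRUE)[[1L]]) else stem
}

# steps 2-4 share the shape "first listed suffix that matches wins; apply
# replacement only when m(stem) > m_min"
.pt_rule_step <- function(l, rules, m_min) {
  for (r in rules) {
    if (.pt_ends(l, r[[1L]])) {
      stem <- .pt_chop(l, r[[1L]])
      extra <- if (length(r) >= 3L) r[[3L]] else NULL
      ok <- .pt_m(stem) > m_min && (is.null(extra) || extra(stem))
      if (ok) l <- .pt_replace(l, r[[1L]], r[[2L]])
      return(l)
    }
  }
  l
}

.pt_step2_rules <- list(
  list("ational", "ate"), list("tional", "tion"),
  list("enci", "ence"), list("anci", "ance"),
  list("izer", "ize"),
  list("abli", "able"), list("alli", "al"), list("entli", "ent"),
  list("eli", "e"), list("ousli", "ous"),
  list("ization", "ize"), list("ation", "ate"), list("ator", "ate"),
  list("alism", "al"), list("iveness", "ive"), list("fulness", "ful"),
  list("ousness", "ous"),
  list("aliti", "al"), list("iviti", "ive"), list("biliti", "ble")
)

.pt_step3_rules <- list(
  list("icate", "ic"), list("ative", ""), list("alize", "al"),
  list("iciti", "ic"), list("ical", "ic"), list("ful", ""), list("ness", "")
)

.pt_step4_rules <- list(
  list("ement", ""),
  list("ance", ""), list("ence", ""), list("able", ""), list("ible", ""),
  list("ment", ""),
  list("ant", ""), list("ent", ""),
  list("ion", "", function(stem) {
    n <- length(stem)
    n >= 1L && stem[n] %in% c("s", "t")
  }),
  list("ism", ""), list("ate", ""), list("iti", ""), list("ous", ""),
  list("ive", ""), list("ize", ""),
  list("al", ""), list("er", ""), list("ic", ""), list("ou", "")
)

.pt_stem_one <- function(word) {
  w <- tolower(word)
  if (nchar(w) <= 2L) return(w)
  l <- strsplit(w, "", fixed = TRUE)[[1L]]

  # step 1a: plurals
  if (.pt_ends(l, "sses")) {
    l <- .pt_replace(l, "sses", "ss")
  } else if (.pt_ends(l, "ies")) {
    l <- .pt_replace(l, "ies", "i")
  } else if (!.pt_ends(l, "ss") && .pt_ends(l, "s")) {
    l <- .pt_chop(l, "s")
  }

  # step 1b: -ed / -ing
  cleanup <- FALSE
  if (.pt_ends(l, "eed")) {
    if (.pt_m(.pt_chop(l, "eed")) > 0L) l <- .pt_chop(l, "d")
  } else if (.pt_ends(l, "ed") && .pt_has_vowel(.pt_chop(l, "ed"))) {
    l <- .pt_chop(l, "ed")
    cleanup <- TRUE
  } else if (.pt_ends(l, "ing") && .pt_has_vowel(.pt_chop(l, "ing"))) {
    l <- .pt_chop(l, "ing")
    cleanup <- TRUE
  }
  if (cleanup) {
    if (.pt_ends(l, "at") || .pt_ends(l, "bl") || .pt_ends(l, "iz")) {
      l <- c(l, "e")
    } else if (.pt_double_cons(l) && !(l[length(l)] %in% c("l", "s", "z"))) {
      l <- l[-length(l)]
    } else if (.pt_m(l) == 1L && .pt_cvc(l)) {
      l <- c(l, "e")
    }
  }

  # step 1c: terminal y -> i when the stem has a vowel
  if (.pt_ends(l, "y") && .pt_has_vowel(.pt_chop(l, "y"))) {
    l[length(l)] <- "i"
  }

  l <- .pt_rule_step(l, .pt_step2_rules, 0L)
  l <- .pt_rule_step(l, .pt_step3_rules, 0L)
  l <- .pt_rule_step(l, .pt_step4_rules, 1L)

  # step 5a: drop terminal e
  if (.pt_ends(l, "e")) {
    stem <- .pt_chop(l, "e")
    m <- .pt_m(stem)
    if (m > 1L || (m == 1L && !.pt_cvc(stem))) l <- stem
  }
  # step 5b: -ll -> -l when m > 1
  if (.pt_m(l) > 1L && .pt_double_cons(l) && l[length(l)] == "l") {
    l <- l[-length(l)]
  }

  paste(l, collapse = "")
}

#' Porter stems of English words
#'
#' Reduces each word to its Porter (1980) stem, e.g. `"products"` to
#' `"product"` and `"dairy"` to `"dairi"`. Stemming makes concept matching
#' robust to simple inflection: a dictionary key built from a concept label
#' and a text token only need share stems to match.
#'
#' @param words character vector of single words (no internal whitespace;
#'   already lower-cased input is not required, output is lower case).
#' @return character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("dairy", "products", "fermented", "kefir"))
#' @export
porter_stem <- function(words) {
  vapply(as.character(words), .pt_stem_one, character(1), USE.NAMES = FALSE)
}
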