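# Independent oracles and generators used across the suite.

# brute-force reflexive reachability under the child relation, derived
# directly from the terms' parent links (independent of kos_descendants)
bf_descendants <- function(kos, term_id) {
  ids <- names(kos$terms)
  parents <- lapply(kos$terms, `[[`, "parents")
  reach <- term_id
  repeat {
    grow <- ids[vapply(ids, function(v) {
      !(v %in% reach) && any(parents[[v]] %in% reach)
    }, logical(1))]
    if (!length(grow)) break
    reach <- c(reach, grow)
  }
  sort(reach)
}

# random DAG as a kos: each node may take parents among earlier nodes, so
# acyclicity holds by construction; labels are unique single tokens
random_dag_kos <- function(n, kos_id = "rnd") {
  terms <- lapply(seq_len(n), function(i) {
    parents <- if (i == 1L) character(0) else {
      k <- sample(0:min(2L, i - 1L), 1L)
      if (k) sprintf("T%03d", sample(i - 1L, k)) else character(0)
    }
    list(term_id = sprintf("T%03d", i), label = sprintf("zq%dx", i),
         parents = parents)
  })
  new_kos(kos_id, terms)
}

# brute-force concept matcher: tries every name of every term against every
# token window, then applies the stated dedup rule. Independent enumeration
# path from annotate_text (which goes through key maps).
bf_annotate <- function(kos, text, blacklist = character(0),
                        stopwords = c("of", "the", "a", "an", "and")) {
  norm <- function(phrase) {
    toks <- tokenize(phrase)
    if (!nrow(toks)) return(NULL)
    if (nrow(toks) > 1L) toks <- toks[!(toks$lower %in% stopwords), , drop = FALSE]
    if (!nrow(toks)) return(NULL)
    if (nrow(toks) == 1L && toks$lower %in% stopwords) return(NULL)
    toks$stem
  }
  bl <- character(0)
  for (b in blacklist) {
    s <- norm(b)
    if (!is.null(s)) bl <- c(bl, paste(s, collapse = " "),
                             paste(sort(s), collapse = " "))
  }
  # precompute each term's usable names (dropping unmatchable or
  # blacklisted ones) with their ordered/sorted stem keys
  entries <- list()
  max_name_len <- 0L
  for (t in kos$terms) {
    if (t$obsolete) next
    names_ <- c(t$label, t$synonyms)
    ok <- character(0); sk <- character(0); verbatim <- character(0)
    for (nm in names_) {
      max_name_len <- max(max_name_len, nrow(tokenize(nm)))
      ns <- norm(nm)
      if (is.null(ns)) next
      n_ok <- paste(ns, collapse = " ")
      n_sk <- paste(sort(ns), collapse = " ")
      if (n_ok %in% bl || n_sk %in% bl) next
      ok <- c(ok, n_ok); sk <- c(sk, n_sk); verbatim <- c(verbatim, tolower(nm))
    }
    if (length(ok)) {
      entries[[length(entries) + 1L]] <- list(term_id = t$term_id, ok = ok,
                                              sk = sk, verbatim = verbatim)
    }
  }

  toks <- tokenize(text)
  n <- nrow(toks)
  rows <- list()
  if (n && length(entries)) {
    is_stop <- toks$lower %in% stopwords
    cap <- max(max_name_len, 6L)
    for (i in seq_len(n)) {
      if (is_stop[i]) next
      for (j in i:min(n, i + cap - 1L)) {
        if (is_stop[j]) next
        sel <- setdiff(i:j, which(is_stop))
        stems <- toks$stem[sel]
        okey <- paste(stems, collapse = " ")
        skey <- paste(sort(stems), collapse = " ")
        if (okey %in% bl || skey %in% bl) next
        slice <- substr(text, toks$start[i] + 1L, toks$end[j])
        for (e in entries) {
          hit_o <- okey %in% e$ok
          hit_u <- skey %in% e$sk
          if (!hit_o && !hit_u) next
          kind <- if (tolower(slice) %in% e$verbatim) {
            "exact"
          } else if (hit_o) {
            "stemmed"
          } else {
            "rearranged"
          }
          rows[[length(rows) + 1L]] <- data.frame(
            term_id = e$term_id, start = toks$start[i], end = toks$end[j],
            matched_text = slice, kind = kind, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else data.frame(
    term_id = character(0), start = integer(0), end = integer(0),
    matched_text = character(0), kind = character(0), stringsAsFactors = FALSE
  )
  hits <- unique(hits)
  # dedup per term: longest span, then exact > stemmed > rearranged, then
  # earliest start; later overlapping spans for the same term drop
  rank <- c(exact = 1L, stemmed = 2L, rearranged = 3L)
  keep <- logical(nrow(hits))
  for (tid in unique(hits$term_id)) {
    idx <- which(hits$term_id == tid)
    ord <- idx[order(-(hits$end[idx] - hits$start[idx]), rank[hits$kind[idx]],
                     hits$start[idx])]
    ks <- integer(0); ke <- integer(0)
    for (i in ord) {
      if (any(hits$start[i] < ke & ks < hits$end[i])) next
      keep[i] <- TRUE
      ks <- c(ks, hits$start[i]); ke <- c(ke, hits$end[i])
    }
  }
  hits <- hits[keep, , drop = FALSE]
  hits <- hits[order(hits$start, hits$end, hits$term_id, method = "radix"), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# random matching fixtures: small vocabulary of real-ish words so that
# stems collide sometimes and multi-word names overlap
match_vocab <- c("alpha", "beta", "gamma", "delta", "stone", "river",
                 "green", "cloud", "leaf", "spore", "marsh", "dune")

random_match_kos <- function(n_terms, kos_id = "rk") {
  terms <- lapply(seq_len(n_terms), function(i) {
    k <- sample(1:3, 1L, prob = c(0.4, 0.4, 0.2))
    nm <- paste(sample(match_vocab, k), collapse = " ")
    syn <- if (stats::runif(1) < 0.3) {
      paste(sample(match_vocab, sample(1:2, 1L)), collapse = " ")
    } else {
      character(0)
    }
    list(term_id = sprintf("RK:%03d", i), label = nm, synonyms = syn)
  })
  # duplicate ids impossible; duplicate names allowed (ambiguity preserved)
  new_kos(kos_id, terms)
}

random_match_text <- function(n_tokens) {
  words <- sample(c(match_vocab, "the", "of", "and"), n_tokens, replace = TRUE)
  caps <- stats::runif(n_tokens) < 0.2
  words[caps] <- paste0(toupper(substr(words[caps], 1, 1)),
                        substr(words[caps], 2, nchar(words[caps])))
  seps <- sample(c(" ", ", ", " - ", "  "), max(n_tokens - 1L, 0L),
                 replace = TRUE, prob = c(0.7, 0.15, 0.05, 0.1))
  paste0(paste0(words[-n_tokens], seps, collapse = ""), words[n_tokens])
}

# in-memory index over one or more planted corpora (named by source id)
corpus_index <- function(kos_set, corpora) {
  sources <- lapply(names(corpora), function(sid) {
    cp <- corpora[[sid]]
    cfg <- cp$config
    cfg$source_id <- sid
    list(config = cfg, records = cp$records)
  })
  names(sources) <- names(corpora)
  index_from_records(kos_set, sources)
}

# a tiny in-code OBO file for error-path tests
write_obo_text <- function(lines) {
  path <- tempfile(fileext = ".obo")
  writeLines(lines, path)
  path
}
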