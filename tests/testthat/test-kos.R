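envo <- demo_kos()$envo

test_that("the miniature environment ontology loads with one root", {
  expect_s3_class(envo, "kos")
  expect_length(envo$terms, 9L)
  roots <- kos_roots(envo)
  expect_length(roots, 1L)
  expect_equal(kos_label(envo, roots), "environmental material")
})

test_that("cyclic or rootless OBO input is rejected", {
  cyc <- write_obo_text(c(
    "format-version: 1.2", "",
    "[Term]", "id: A", "name: a", "is_a: B", "",
    "[Term]", "id: B", "name: b", "is_a: A"
  ))
  expect_error(read_obo(cyc), "cycle")
  empty <- write_obo_text(c("format-version: 1.2", ""))
  expect_error(read_obo(empty), "no root")
  noid <- write_obo_text(c("[Term]", "name: orphan stanza"))
  expect_error(read_obo(noid), "without id")
})

test_that("roots are the parentless non-obsolete terms, sorted by label", {
  gaz <- demo_kos()$gaz
  expect_equal(kos_label(gaz, kos_roots(gaz)), "Earth")
  taxo <- demo_kos()$taxo
  expect_equal(kos_label(taxo, kos_roots(taxo)), "cellular organisms")
  flat <- new_kos("flat", list(
    list(term_id = "x", label = "xyl"),
    list(term_id = "y", label = "yew"),
    list(term_id = "z", label = "alder")
  ))
  expect_equal(kos_roots(flat), c("z", "x", "y")) # alder, xyl, yew
})

test_that("children are label-sorted and leaves are empty", {
  dairy <- kos_resolve(envo, "dairy product")
  expect_equal(kos_label(envo, kos_children(envo, dairy)),
               c("cheese", "fermented dairy product", "milk"))
  kefir <- kos_resolve(envo, "kefir")
  expect_length(kos_children(envo, kefir), 0L)
  expect_error(kos_children(envo, "ENVO:9999999"), "unknown term")
})

test_that("descendants form the reflexive transitive closure", {
  dairy <- kos_resolve(envo, "dairy product")
  expect_setequal(
    kos_label(envo, kos_descendants(envo, dairy)),
    c("dairy product", "cheese", "milk", "fermented dairy product", "kefir")
  )
  gaz <- demo_kos()$gaz
  stockholm <- kos_resolve(gaz, "Stockholm")
  expect_equal(kos_descendants(gaz, stockholm), stockholm)
  expect_error(kos_descendants(envo, "nope"), "unknown term")
})

test_that("a diamond DAG counts the shared descendant once", {
  diamond <- new_kos("dia", list(
    list(term_id = "A", label = "a"),
    list(term_id = "B", label = "b", parents = "A"),
    list(term_id = "C", label = "c", parents = "A"),
    list(term_id = "D", label = "d", parents = c("B", "C"))
  ))
  d <- kos_descendants(diamond, "A")
  expect_length(d, 4L)
  expect_equal(sum(d == "D"), 1L)
})

test_that("autocomplete ranks by match position, label length, label", {
  hits <- kos_autocomplete(envo, "dairy", 10L)
  expect_equal(vapply(hits, `[[`, character(1), "label"),
               c("dairy product", "fermented dairy product"))
  expect_length(kos_autocomplete(envo, "zzz", 5L), 0L)
  expect_identical(kos_autocomplete(envo, "DAIRY", 10L),
                   kos_autocomplete(envo, "dairy", 10L))
  expect_length(kos_autocomplete(envo, "", 5L), 0L)
  expect_length(kos_autocomplete(envo, "dairy", 1L), 1L)
})

test_that("obsolete terms load but are hidden from navigation and matching", {
  path <- write_obo_text(c(
    "[Term]", "id: R", "name: root", "",
    "[Term]", "id: O", "name: old leaf", "is_obsolete: true", "",
    "[Term]", "id: L", "name: leaf", "is_a: R"
  ))
  k <- read_obo(path)
  expect_length(k$terms, 3L)
  expect_equal(kos_roots(k), "R") # obsolete parentless term is not a root
  expect_equal(kos_children(k, "R"), "L")
  expect_length(kos_autocomplete(k, "old", 5L), 0L)
  dict <- build_dictionary(k)
  expect_equal(nrow(annotate_text(dict, "an old leaf")),
               1L) # only the live term matches
})

test_that("KOS JSON serialization round-trips to an identical term set", {
  for (kos in demo_kos()) {
    path <- tempfile(fileext = ".json")
    write_kos_json(kos, path)
    back <- read_kos_json(path)
    expect_identical(back$kos_id, kos$kos_id)
    expect_identical(names(back$terms), names(kos$terms))
    for (id in names(kos$terms)) {
      expect_identical(back$terms[[id]], kos$terms[[id]])
    }
  }
})

test_that("descendants agree with brute-force reachability on random DAGs", {
  set.seed(101)
  for (trial in 1:12) {
    k <- random_dag_kos(sample(5:50, 1))
    for (t in sample(names(k$terms), min(8L, length(k$terms)))) {
      expect_equal(kos_descendants(k, t), bf_descendants(k, t))
      expect_true(t %in% kos_descendants(k, t))
      expect_true(all(kos_children(k, t) %in% kos_descendants(k, t)))
    }
  }
})

test_that("adding an edge never shrinks any descendant set", {
  set.seed(202)
  for (trial in 1:8) {
    n <- sample(5:25, 1)
    k <- random_dag_kos(n)
    # add a forward edge (earlier node becomes parent of a later one):
    # acyclic by construction
    ij <- sort(sample(n, 2))
    terms2 <- lapply(k$terms, function(t) t)
    child <- sprintf("T%03d", ij[2]); parent <- sprintf("T%03d", ij[1])
    terms2[[child]]$parents <- unique(c(terms2[[child]]$parents, parent))
    k2 <- new_kos("rnd2", terms2)
    for (t in names(k$terms)) {
      expect_true(all(kos_descendants(k, t) %in% kos_descendants(k2, t)))
    }
  }
})
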