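# Shared data model: class expressions, axiom insertion, graph queries,
# structural validation.

test_that("class expression canonicalisation is idempotent and order-normalising", {
  e1 <- ce_and(ce_some("has_input", "CHEBI:16646"), ce_named("GO:0005488"))
  e2 <- ce_and(ce_named("GO:0005488"), ce_some("has_input", "CHEBI:16646"))
  expect_identical(ce_render(e1), ce_render(e2))
  expect_identical(ce_render(ce_canon(e1)), ce_render(e1))
  # duplicates collapse, nested intersections flatten
  e3 <- ce_and(ce_named("A:1"), ce_and(ce_named("A:1"), ce_named("B:2")))
  expect_identical(ce_render(e3), ce_render(ce_and(ce_named("B:2"), ce_named("A:1"))))
  # canon(canon(e)) = canon(e) over generated expressions
  set.seed(7)
  for (k in 1:25) {
    ids <- sprintf("T:%d", sample(1:6, 3, replace = TRUE))
    e <- ce_and(ce_some("r", ce_and(ce_named(ids[1]), ce_named("Z:9"))),
                ce_named(ids[2]), ce_named(ids[3]))
    expect_identical(ce_render(ce_canon(ce_canon(e))), ce_render(ce_canon(e)))
  }
})

test_that("expression rendering and parsing are mutually inverse", {
  exprs <- list(
    ce_named("CHEBI:16646"),
    ce_some("has_participant", "CHEBI:15318"),
    ce_some("has_input", ce_and(ce_named("A:1"), ce_named("B:2"))),
    ce_and(ce_named("GO:0008152"),
           ce_some("has_participant", "CHEBI:15318")))
  for (e in exprs) {
    expect_identical(ce_render(ce_parse(ce_render(e))), ce_render(e))
  }
  expect_error(ce_named("no-colon"), "CURIE")
  expect_error(ce_named("two:colons:here"), "CURIE")
})

test_that("trivial subclass axioms are rejected and equivalences ordered", {
  o <- ontology("t")
  o <- add_term(o, "A:1", "a")
  expect_error(add_axiom(o, "subclass_of", "A:1", "A:1"), "trivial")
  o <- add_term(o, "A:2", "b")
  o <- add_axiom(o, "equivalent_to", "A:2", "A:1")
  expect_identical(o$axioms$lhs, "A:1")
  expect_identical(o$axioms$rhs, "A:2")
})

test_that("ancestors walks the asserted acid-side chain of the fixture", {
  got <- onto_ancestors(bundle$mini_chebi, "FIX:C009")
  expect_setequal(got, c("FIX:C009", "FIX:C008", "FIX:C007", "FIX:C001"))
  # reflexivity for a parentless term
  expect_identical(onto_ancestors(bundle$mini_chebi, "FIX:C001"), "FIX:C001")
  # conjugate edges are walked per-relation, not via is_a
  expect_setequal(
    onto_ancestors(bundle$mini_chebi, "FIX:C012", "is_conjugate_acid_of"),
    c("FIX:C012", "FIX:C013", "FIX:C014", "FIX:C015"))
  expect_error(onto_ancestors(bundle$mini_chebi, "FIX:NOPE"), "unknown term")
})

test_that("ancestors agrees with a matrix-squaring closure oracle on random DAGs", {
  for (seed in 1:6) {
    o <- random_ontology(n_classes = 10, n_relations = 1, density = 0.5,
                         seed = seed)
    edges <- o$axioms[o$axioms$kind == "subclass_of" &
                        grepl("^RND:[0-9]+$", o$axioms$lhs) &
                        grepl("^RND:[0-9]+$", o$axioms$rhs), ]
    nodes <- o$terms$id[grepl("^RND:[0-9]+$", o$terms$id)]
    m <- closure_oracle(tibble::tibble(sub = edges$lhs, sup = edges$rhs), nodes)
    for (x in nodes) {
      expect_setequal(intersect(onto_ancestors(o, x), nodes),
                      nodes[m[x, ] > 0])
    }
  }
})

test_that("ancestors is monotone under axiom addition", {
  o <- random_ontology(n_classes = 12, n_relations = 1, density = 0.3, seed = 3)
  before <- lapply(o$terms$id, onto_ancestors, onto = o)
  names(before) <- o$terms$id
  o2 <- add_isa(o, "RND:0005", "RND:0002")
  for (x in o$terms$id) {
    expect_true(all(before[[x]] %in% onto_ancestors(o2, x)))
  }
})

test_that("validation reports cycles, duplicate labels and unresolved ids as data", {
  expect_identical(nrow(onto_validate(bundle$mini_go)), 0L)
  expect_identical(nrow(onto_validate(bundle$mini_chebi)), 0L)

  o <- ontology("bad")
  o <- add_term(o, "X:a", "alpha")
  o <- add_term(o, "X:b", "alpha")         # duplicate label
  o <- add_isa(o, "X:a", "X:b")
  o <- add_isa(o, "X:b", "X:a")            # cycle
  o <- add_axiom(o, "subclass_of", "X:a", ce_some("rel_q", "X:zz"))
  v <- onto_validate(o)
  expect_true("cycle" %in% v$rule)
  expect_true("duplicate_label" %in% v$rule)
  expect_true(any(v$rule == "unresolved_id" & v$entity == "X:zz"))
  expect_true(any(v$rule == "unresolved_relation" & v$entity == "rel_q"))
  cyc <- v[v$rule == "cycle", ]
  expect_match(cyc$entity, "X:a")
  expect_match(cyc$entity, "X:b")
})

test_that("obsolete terms with outgoing axioms are flagged", {
  o <- ontology("obs")
  o <- add_term(o, "X:a", "a", obsolete = TRUE)
  o <- add_term(o, "X:b", "b")
  o <- add_isa(o, "X:a", "X:b")
  expect_true("obsolete_axiom" %in% onto_validate(o)$rule)
})
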