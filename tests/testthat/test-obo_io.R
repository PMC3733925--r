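# OBO 1.2 subset reader/writer and the GCI sidecar.

test_that("intersection_of blocks parse into one equivalence axiom", {
  text <- c("format-version: 1.2", "",
            "[Term]",
            "id: GO:0046110",
            "name: xanthine metabolic process",
            "intersection_of: GO:0008152",
            "intersection_of: has_participant CHEBI:15318")
  o <- parse_obo(text)
  expect_identical(nrow(o$axioms), 1L)
  expect_identical(o$axioms$kind, "equivalent_to")
  expect_setequal(
    c(o$axioms$lhs, o$axioms$rhs),
    c("GO:0046110",
      "(GO:0008152 and has_participant some CHEBI:15318)"))
  # the filler and genus are registered as external references
  expect_true(all(c("GO:0008152", "CHEBI:15318") %in% o$external))
})

test_that("an empty document with a header parses to zero terms", {
  o <- parse_obo("format-version: 1.2\nontology: empty-test")
  expect_identical(nrow(o$terms), 0L)
  expect_identical(o$id, "empty-test")
  expect_error(parse_obo("ontology: x"), "format-version")
})

test_that("synonym scopes, defs, xrefs, obsolete flags and qualifiers survive parsing", {
  text <- c("format-version: 1.2", "",
            "[Term]",
            "id: X:1",
            "name: alpha",
            "def: \"a thing\" [PMID:1]",
            "synonym: \"first form\" EXACT []",
            "synonym: \"loose form\" []",
            "xref: Y:9",
            "is_a: X:2 {is_inferred=\"true\"} ! comment",
            "",
            "[Term]",
            "id: X:2",
            "name: beta",
            "is_obsolete: true")
  o <- parse_obo(text)
  expect_identical(o$synonyms$scope, c("EXACT", "RELATED"))
  expect_identical(o$terms$def[o$terms$id == "X:1"], "a thing")
  expect_identical(o$xrefs$xref, "Y:9")
  expect_true(o$terms$obsolete[o$terms$id == "X:2"])
  expect_identical(o$axioms$provenance, "inferred")
})

test_that("unknown tags land in the queryable ledger, malformed stanzas error", {
  text <- c("format-version: 1.2", "",
            "[Term]", "id: X:1", "name: a",
            "comment: free text kept verbatim")
  o <- parse_obo(text)
  expect_identical(o$unknown$line, "comment: free text kept verbatim")
  expect_error(parse_obo(c("format-version: 1.2", "", "[Term]", "name: anon")),
               "exactly one id")
  expect_error(parse_obo(c("format-version: 1.2", "", "[Term]", "id: X:1",
                           "name: a", "relationship: only_rel")),
               "relationship")
})

test_that("dangling is_a targets are registered external with a warning record", {
  o <- parse_obo(c("format-version: 1.2", "", "[Term]", "id: X:1",
                   "name: a", "is_a: X:404"))
  expect_true("X:404" %in% o$external)
  expect_match(attr(o, "parse_warnings"), "X:404")
})

test_that("write/parse round-trips the fixture bundle structurally and textually", {
  for (o in list(bundle$mini_go, bundle$mini_chebi)) {
    text <- write_obo(o)
    o2 <- parse_obo(text)
    o2$axioms <- dplyr::bind_rows(o2$axioms, sidecar_axioms(o))
    expect_true(onto_equal(o, o2))
    # parse(write(parse(text))) equals parse(text), byte-for-byte on re-write
    expect_identical(write_obo(parse_obo(text)), text)
  }
})

test_that("round-trip identity holds across 100 random ontologies", {
  for (seed in 1:100) {
    o <- random_ontology(n_classes = 3 + seed %% 12, n_relations = 1 + seed %% 3,
                         density = 0.1 + (seed %% 5) / 10, seed = seed,
                         conjugate_chain = seed %% 3)
    o2 <- parse_obo(write_obo(o))
    o2$axioms <- dplyr::bind_rows(o2$axioms, sidecar_axioms(o))
    expect_true(onto_equal(o, o2))
  }
})

test_that("the GCI sidecar round-trips bit-exactly and GCIs never enter stanzas", {
  biochebi <- build_biochebi(bundle$mini_chebi)
  side <- sidecar_axioms(biochebi)
  expect_true(all(side$provenance == "gci"))
  text <- write_gci_file(side)
  expect_identical(write_gci_file(read_gci_file(text = text)), text)
  # the OBO text itself carries no existential-equivalence lines
  expect_false(grepl(" some ", write_obo(biochebi), fixed = TRUE))
})

test_that("bridge axioms round-trip exactly through the bridge OBO", {
  bo <- as_bridge_ontology(bundle_bridge, bundle$mini_go)
  reparsed <- parse_obo(write_obo(bo))
  a <- bundle_bridge$bridge$axioms
  b <- reparsed$axioms
  expect_setequal(paste(a$kind, a$lhs, a$rhs, a$provenance),
                  paste(b$kind, b$lhs, b$rhs, b$provenance))
})

test_that("a logical definition with a complex existential filler is rejected", {
  o <- ontology("bad")
  o <- add_term(o, "X:1", "one")
  o <- add_relation(o, "r")
  o <- add_axiom(o, "equivalent_to", "X:1",
                 ce_and(ce_named("X:2"),
                        ce_some("r", ce_and(ce_named("X:3"), ce_named("X:4")))))
  o <- register_external(o, c("X:2", "X:3", "X:4"))
  expect_error(write_obo(o), "named class")
})
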