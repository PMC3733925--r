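# Implicit chemical ontology extraction, cross-family audit, reference diff.

test_that("extraction mirrors the hand-enumerated family edge multiset", {
  impl <- extract_implicit(bundle$mini_go, bundle_bridge$definitions)
  got <- paste(impl$edges$child, impl$edges$parent, impl$edges$family)
  expect_setequal(got, c(
    "FIX:C004 CHEBI:16646 transport",
    "FIX:C005 CHEBI:16646 transport",
    "FIX:C006 FIX:C004 transport",
    "FIX:C006 FIX:C005 transport",
    "FIX:C006 FIX:C005 transporter_activity",
    "FIX:C008 FIX:C007 metabolic",
    "FIX:C010 FIX:C008 metabolic"))
  # all definition fillers are carried as chemicals, even edge-less ones
  expect_true("GOCHE:0000001" %in% impl$chemicals)
})

test_that("extraction is independent of term iteration order", {
  go2 <- bundle$mini_go
  perm <- rev(seq_len(nrow(go2$terms)))
  go2$terms <- go2$terms[perm, ]
  go2$axioms <- go2$axioms[rev(seq_len(nrow(go2$axioms))), ]
  br2 <- bridge_ontologies(go2, bundle$mini_chebi)
  a <- extract_implicit(bundle$mini_go, bundle_bridge$definitions)
  b <- extract_implicit(go2, br2$definitions)
  expect_identical(a$edges, b$edges)
  expect_identical(a$chemicals, b$chemicals)
})

test_that("the audit reports exactly the transport/transporter asymmetry", {
  impl <- extract_implicit(bundle$mini_go, bundle_bridge$definitions)
  confl <- find_cross_family_conflicts(impl)
  expect_identical(nrow(confl), 1L)
  expect_identical(confl$child, bundle$expected$conflict$child)
  expect_identical(confl$parent, bundle$expected$conflict$parent)
  expect_identical(confl$supporting_families[[1]],
                   bundle$expected$conflict$supporting)
  expect_identical(confl$absent_families[[1]],
                   bundle$expected$conflict$absent)
})

test_that("deleting the offending edge clears the conflict; one family is silent", {
  go2 <- remove_axiom(bundle$mini_go, "subclass_of", "FIX:G001", "FIX:G002")
  br2 <- bridge_ontologies(go2, bundle$mini_chebi)
  impl2 <- extract_implicit(go2, br2$definitions)
  expect_identical(nrow(find_cross_family_conflicts(impl2)), 0L)
  # a single-family implicit ontology cannot conflict
  defs_one <- bundle_bridge$definitions
  defs_one <- defs_one[defs_one$family == "transport", ]
  impl_one <- extract_implicit(bundle$mini_go, defs_one)
  expect_identical(nrow(find_cross_family_conflicts(impl_one)), 0L)
})

test_that("the reference diff flags the G6P edge but not conjugate-entailed edges", {
  impl <- extract_implicit(bundle$mini_go, bundle_bridge$definitions)
  disc <- diff_against_reference(impl, bundle$mini_chebi, gcis = bundle_gcis)
  bad_edges <- disc[disc$kind == "edge_not_in_reference", ]
  expect_identical(nrow(bad_edges), 1L)
  expect_identical(bad_edges$child, "FIX:C006")
  expect_identical(bad_edges$parent, "FIX:C004")
  # the acid/base chain edge is entailed via conjugate identification
  expect_false(any(disc$child == "FIX:C010" & disc$parent == "FIX:C008" &
                     disc$kind == "edge_not_in_reference"))
  # the minted chemical is reported as absent from the reference
  expect_true(any(disc$kind == "chemical_not_in_reference" &
                    disc$child == "GOCHE:0000001"))
})

test_that("without the GCI overlay the acid/base edge is flagged too (monotone)", {
  impl <- extract_implicit(bundle$mini_go, bundle_bridge$definitions)
  disc0 <- diff_against_reference(impl, bundle$mini_chebi)
  disc1 <- diff_against_reference(impl, bundle$mini_chebi, gcis = bundle_gcis)
  e0 <- disc0[disc0$kind == "edge_not_in_reference", ]
  e1 <- disc1[disc1$kind == "edge_not_in_reference", ]
  expect_gte(nrow(e0), nrow(e1))
  expect_true(any(e0$child == "FIX:C010" & e0$parent == "FIX:C008"))
  # every edge flagged with the larger GCI set is flagged with the smaller
  expect_true(all(paste(e1$child, e1$parent) %in% paste(e0$child, e0$parent)))
})

test_that("an empty implicit ontology diffs and audits to empty reports", {
  empty <- extract_implicit(bundle$mini_go,
                            bundle_bridge$definitions[0, ])
  expect_identical(nrow(empty$edges), 0L)
  expect_identical(nrow(find_cross_family_conflicts(empty)), 0L)
  expect_identical(nrow(diff_against_reference(empty, bundle$mini_chebi)), 0L)
})

test_that("the DOT export names every chemical and family-tags every edge", {
  impl <- extract_implicit(bundle$mini_go, bundle_bridge$definitions)
  dot <- implicit_dot(impl)
  for (x in impl$chemicals) expect_match(dot, x, fixed = TRUE)
  expect_match(dot, "label=\"transport\"", fixed = TRUE)
})
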