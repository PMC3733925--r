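# EL normalisation, saturation, entailment queries, and agreement with the
# naive full-pass oracle.

test_that("normalisation leaves NF1 untouched and decomposes GCIs deterministically", {
  plain <- tibble::tibble(kind = "subclass_of", lhs = "A:1", rhs = "B:1",
                          provenance = "asserted")
  nf <- normalize_axioms(plain)
  expect_identical(nf$nf, "nf1")
  expect_identical(nf$c1, "A:1")
  expect_identical(nf$d, "B:1")

  gci <- tibble::tibble(kind = "equivalent_to",
                        lhs = "has_input some X:1",
                        rhs = "has_input some Y:1",
                        provenance = "gci")
  nfg <- normalize_axioms(gci)
  expect_setequal(unique(nfg$nf), c("nf1", "nf3", "nf4"))
  # both existentials get fresh names connected in both directions
  fresh <- unique(c(nfg$c1, nfg$d))
  fresh <- fresh[startsWith(fresh, "FRESH:")]
  expect_identical(length(fresh), 2L)
  expect_identical(normalize_axioms(gci), nfg) # deterministic

  bridge_shape <- tibble::tibble(
    kind = "equivalent_to", lhs = "T:1",
    rhs = "(G:1 and r some C:1)", provenance = "bridge")
  nfb <- normalize_axioms(bridge_shape)
  expect_true(any(nfb$nf == "nf2"))
  expect_true(any(nfb$nf == "nf3" & nfb$d == "C:1"))
  expect_true(any(nfb$nf == "nf4" & nfb$c1 == "C:1"))
})

test_that("an empty axiom set classifies to reflexive subsumptions only", {
  nf <- normalize_axioms(tibble::tibble(kind = character(), lhs = character(),
                                        rhs = character(),
                                        provenance = character()))
  res <- classify_nf(nf, extra_classes = "A:1")
  expect_setequal(res$S[["A:1"]], c("A:1", "owl:Thing"))
  expect_true(entails(res, "A:1", "A:1"))
  expect_identical(nrow(subsumption_table(res)), 0L)
})

test_that("the fixture entails the acid/base flip only with the GCI overlay", {
  res_without <- classify_axioms(bundle_axioms(gcis = NULL))
  res_with <- classify_axioms(bundle_axioms())
  expect_false(entails(res_without, "FIX:G010", "FIX:G008"))
  expect_true(entails(res_with, "FIX:G010", "FIX:G008"))
  # the chemical-side facts themselves stay put: G6P is never a glucose
  expect_false(entails(res_with, "FIX:C006", "FIX:C004"))
  expect_true(entails(res_with, "FIX:C006", "FIX:C005"))
})

test_that("definitions re-derive the process hierarchy through the genus", {
  res <- classify_axioms(bundle_axioms())
  # tricarboxylic acid metabolism under carboxylic acid metabolism via chemistry
  expect_true(entails(res, "FIX:G009", "FIX:G008"))
  # every defined metabolic-family term is a metabolic process
  expect_true(entails(res, "FIX:G010", "GO:0008152"))
  expect_true(entails(res, "GO:0030246", "GO:0005488"))
})

test_that("direct superclasses skip transitive hops and group equivalents", {
  chain <- tibble::tibble(kind = "subclass_of",
                          lhs = c("A:1", "B:1"), rhs = c("B:1", "C:1"),
                          provenance = "asserted")
  res <- classify_axioms(chain)
  expect_identical(direct_superclasses(res, "A:1"), "B:1")
  expect_identical(direct_superclasses(res, "B:1"), "C:1")
  # a class equivalent to its parent reports it as equivalent, not super
  eq <- tibble::tibble(kind = c("subclass_of", "equivalent_to"),
                       lhs = c("A:1", "A:1"), rhs = c("B:1", "B:1"),
                       provenance = "asserted")
  res2 <- classify_axioms(eq)
  expect_identical(equivalent_classes(res2, "A:1"), "B:1")
  expect_identical(direct_superclasses(res2, "A:1"), character(0))
})

test_that("worklist classification agrees with the naive oracle on random ontologies", {
  for (seed in 1:40) {
    o <- random_case(seed)
    ax <- assemble_axioms(go = o)
    expect_equal(subsumption_table(classify_axioms(ax)),
                 naive_oracle(ax), ignore_attr = TRUE,
                 info = paste("seed", seed))
  }
})

test_that("classification is monotone under axiom addition", {
  for (seed in 1:20) {
    o <- random_case(seed)
    ax <- assemble_axioms(go = o)
    half <- ax[seq_len(floor(nrow(ax) / 2)), ]
    attr(half, "relation_parents") <- attr(ax, "relation_parents")
    small <- classify_axioms(half)
    big <- classify_axioms(ax)
    for (cl in small$classes) {
      expect_true(all(small$S[[cl]] %in% big$S[[cl]]),
                  info = paste("seed", seed, "class", cl))
    }
  }
})

test_that("asserting all entailed subsumptions and re-classifying changes nothing", {
  for (seed in c(2, 9, 17)) {
    o <- random_case(seed)
    ax <- assemble_axioms(go = o)
    res <- classify_axioms(ax)
    tab <- subsumption_table(res)
    extra <- tibble::tibble(kind = "subclass_of", lhs = tab$sub, rhs = tab$sup,
                            provenance = "asserted")
    ax2 <- dplyr::bind_rows(ax, extra)
    attr(ax2, "relation_parents") <- attr(ax, "relation_parents")
    expect_equal(subsumption_table(classify_axioms(ax2)), tab,
                 ignore_attr = TRUE, info = paste("seed", seed))
  }
})
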