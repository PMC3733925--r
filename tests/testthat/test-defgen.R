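# Template rules, label parsing, logical-definition emission, renaming,
# term generation.

test_that("the core rule set maps each family to its conventional relation", {
  r <- default_rules()
  rel_of <- stats::setNames(r$relation, r$rule_id)
  expect_identical(unname(rel_of["metabolic"]), "has_participant")
  expect_identical(unname(rel_of["biosynthetic"]), "has_output")
  expect_identical(unname(rel_of["catabolic"]), "has_input")
  expect_identical(unname(rel_of["transport"]),
                   "transports_or_maintains_localization_of")
  expect_identical(unname(rel_of["response_to"]), "has_input")
  expect_identical(unname(rel_of["binding"]), "has_input")
  # extensions are flagged
  expect_true(all(r$extension[r$rule_id %in%
                                c("secretion", "homeostasis",
                                  "transporter_activity")]))
  # longer tails must win over substring tails
  pri <- stats::setNames(r$priority, r$rule_id)
  expect_lt(pri[["biosynthetic"]], pri[["metabolic"]])
  expect_lt(pri[["catabolic"]], pri[["metabolic"]])
  expect_lt(pri[["transporter_activity"]], pri[["transport"]])
})

test_that("rules round-trip through the YAML config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_rules(default_rules(), path)
  r2 <- read_rules(path)
  expect_equal(as.data.frame(r2), as.data.frame(default_rules()))
})

test_that("label parsing captures the chemical and skips out-of-scope labels", {
  p <- parse_label("xanthine biosynthetic process")
  expect_identical(p$rule_id, "biosynthetic")
  expect_identical(p$chemical_string, "xanthine")
  p2 <- parse_label("glucose-6-phosphate transport")
  expect_identical(p2$rule_id, "transport")
  expect_identical(p2$chemical_string, "glucose-6-phosphate")
  p3 <- parse_label("response to benzene")
  expect_identical(p3$rule_id, "response_to")
  expect_identical(p3$chemical_string, "benzene")
  expect_null(parse_label("binding"))
  expect_null(parse_label("transport"))
  expect_null(parse_label("regulation of xanthine biosynthetic process"))
  expect_null(parse_label("positive regulation of glucose transport"))
  # a biosynthetic label must not degrade to the metabolic rule
  expect_identical(parse_label("x biosynthetic process")$rule_id,
                   "biosynthetic")
})

test_that("parse and assemble are mutually inverse over all rules", {
  rules <- default_rules()
  chems <- c("xanthine", "glucose-6-phosphate", "citrate(1-)",
             "nitrilotriacetate")
  for (i in seq_len(nrow(rules))) {
    for (ch in chems) {
      lb <- sub("{X}", ch, rules$pattern[i], fixed = TRUE)
      p <- parse_label(lb, rules)
      expect_identical(p$rule_id, rules$rule_id[i], info = lb)
      expect_identical(p$chemical_string, ch, info = lb)
    }
  }
})

test_that("the carbohydrate-binding definition takes the genus-differentia form", {
  p <- parse_label("carbohydrate binding")
  ld <- make_logical_definition("GO:0030246", p, "CHEBI:16646")
  expect_setequal(c(ld$axiom$lhs, ld$axiom$rhs),
                  c("GO:0030246",
                    "(GO:0005488 and has_input some CHEBI:16646)"))
  expect_identical(ld$axiom$provenance, "bridge")
  expect_identical(ld$definition$genus, "GO:0005488")
  # temporary fillers propagate the temporary provenance
  ld2 <- make_logical_definition("FIX:G011",
                                 parse_label("aldoxime metabolic process"),
                                 "GOCHE:0000001")
  expect_identical(ld2$axiom$provenance, "temporary")
})

test_that("bridging the fixture defines every chemical-referencing term once", {
  br <- bundle_bridge
  expect_identical(anyDuplicated(br$definitions$defined), 0L)
  expect_identical(nrow(br$definitions), 19L)
  counts <- stats::setNames(br$family_counts$n, br$family_counts$family)
  expect_identical(counts[order(names(counts))],
                   bundle$expected$family_counts)
  expect_identical(br$unmatched$chemical_string,
                   bundle$expected$unmatched_chemicals)
  # each bridge axiom has exactly one genus and one chemical differentium
  for (i in seq_len(nrow(br$definitions))) {
    d <- br$definitions[i, ]
    expr <- ce_parse(paste0("(", d$genus, " and ", d$relation, " some ",
                            d$filler, ")"))
    expect_true(any(br$bridge$axioms$lhs == ce_render(expr) |
                      br$bridge$axioms$rhs == ce_render(expr)))
  }
})

test_that("bridging is deterministic: two runs are byte-identical", {
  a <- bridge_ontologies(bundle$mini_go, bundle$mini_chebi)
  b <- bridge_ontologies(bundle$mini_go, bundle$mini_chebi)
  expect_identical(write_gci_file(a$bridge$axioms),
                   write_gci_file(b$bridge$axioms))
  expect_identical(a$definitions, b$definitions)
  expect_identical(request_ledger(a$registry), request_ledger(b$registry))
})

test_that("CLASS-reading plural chemicals rename to X-containing compound", {
  expect_identical(containing_compound_rename("phenol metabolic process",
                                              "phenols"),
                   "phenol-containing compound metabolic process")
  expect_identical(containing_compound_rename("pyridine catabolic process",
                                              "pyridines"),
                   "pyridine-containing compound catabolic process")
  # EXACT readings pass through unchanged
  expect_identical(containing_compound_rename("benzene metabolic process",
                                              "benzene"),
                   "benzene metabolic process")
  expect_error(containing_compound_rename("glucose transport", "phenols"),
               "does not contain")
})

test_that("term generation builds label, synonyms, definition and placement", {
  rec <- generate_term("biosynthetic", "CHEBI:15318", bundle$mini_go,
                       bundle$mini_chebi, bridge = bundle_bridge,
                       gcis = bundle_gcis)
  expect_identical(rec$term$label, "xanthine biosynthetic process")
  expect_match(rec$term$def, "formation of xanthine")
  expect_identical(rec$synonyms$synonym,
                   "3,7-dihydro-1H-purine-2,6-dione biosynthetic process")
  expect_identical(rec$placement, "FIX:G014") # under purine biosynthesis
  expect_setequal(c(rec$axiom$lhs, rec$axiom$rhs),
                  c(rec$term$id,
                    "(GO:0009058 and has_output some CHEBI:15318)"))
})

test_that("term generation refuses missing chemicals and duplicate labels", {
  expect_error(generate_term("transport", "CHEBI:99999", bundle$mini_go,
                             bundle$mini_chebi, bridge = bundle_bridge),
               "request missing chemical")
  expect_error(generate_term("metabolic", "FIX:C010", bundle$mini_go,
                             bundle$mini_chebi, bridge = bundle_bridge),
               "duplicate term")
})
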