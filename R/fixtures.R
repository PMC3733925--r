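# Worked-example mini-ontologies and seeded random ontologies. The bundle
# embeds the canonical integration cases: the glucose-6-phosphate
# transport/transporter asymmetry, the nitrilotriacetate acid/base chain, the
# citric-acid conjugate ladder, the pyridine/pyridines and phenol CLASS
# readings, butyric/butanoic acid synonymy, xanthine generation, and the
# aldoxime/oxime coverage gap.

#' Build the worked-example fixture bundle
#'
#' Returns a mini chemical ontology and mini process ontology embedding every
#' worked example the package's audits and tests exercise, with deterministic
#' ids (well-known classes keep their real CURIEs, invented plumbing uses the
#' `FIX:` prefix), plus an `expected` ledger of known-answer facts that the
#' test suite re-derives from the bundle.
#'
#' @return list with elements `mini_go`, `mini_chebi` (ontologies) and
#'   `expected` (list of known-answer facts).
#' @export
example_bundle <- function() {
  chem <- ontology("mini-chebi", header = c(`format-version` = "1.2"))
  chem <- add_relation(chem, "is_conjugate_acid_of")
  chem <- add_relation(chem, "is_conjugate_base_of")
  chem <- add_relation(chem, "has_functional_parent")
  chem <- add_relation(chem, "has_role")
  chem <- add_relation(chem, "is_tautomer_of")
  ct <- function(onto, id, label, parents = character(0), synonyms = NULL,
                 obsolete = FALSE) {
    onto <- add_term(onto, id, label, namespace = "chebi_ontology",
                     obsolete = obsolete, synonyms = synonyms)
    for (p in parents) onto <- add_isa(onto, id, p)
    onto
  }
  chem <- ct(chem, "FIX:C001", "chemical entity")
  chem <- ct(chem, "CHEBI:16646", "carbohydrate", "FIX:C001")
  chem <- ct(chem, "FIX:C002", "monosaccharide", "CHEBI:16646")
  chem <- ct(chem, "FIX:C003", "hexose", "FIX:C002")
  chem <- ct(chem, "FIX:C004", "glucose", "FIX:C003")
  chem <- ct(chem, "FIX:C005", "hexose phosphate", "CHEBI:16646")
  chem <- ct(chem, "FIX:C006", "glucose-6-phosphate", "FIX:C005",
             synonyms = tibble::tibble(synonym = "D-glucose 6-phosphate",
                                       scope = "EXACT"))
  chem <- ct(chem, "FIX:C007", "carboxylic acid", "FIX:C001")
  chem <- ct(chem, "FIX:C008", "tricarboxylic acid", "FIX:C007")
  chem <- ct(chem, "FIX:C009", "nitrilotriacetic acid", "FIX:C008")
  chem <- ct(chem, "FIX:C011", "carboxylic acid anion", "FIX:C001")
  chem <- ct(chem, "FIX:C010", "nitrilotriacetate", "FIX:C011")
  chem <- add_axiom(chem, "subclass_of", ce_named("FIX:C010"),
                    ce_some("is_conjugate_base_of", ce_named("FIX:C009")))
  chem <- ct(chem, "FIX:C012", "citric acid", "FIX:C008")
  chem <- ct(chem, "FIX:C013", "citrate(1-)", "FIX:C011")
  chem <- ct(chem, "FIX:C014", "citrate(2-)", "FIX:C011")
  chem <- ct(chem, "FIX:C015", "citrate(3-)", "FIX:C011")
  chem <- add_axiom(chem, "subclass_of", ce_named("FIX:C012"),
                    ce_some("is_conjugate_acid_of", ce_named("FIX:C013")))
  # the first citrate link is asserted in both directions (dedup exercise)
  chem <- add_axiom(chem, "subclass_of", ce_named("FIX:C013"),
                    ce_some("is_conjugate_base_of", ce_named("FIX:C012")))
  chem <- add_axiom(chem, "subclass_of", ce_named("FIX:C013"),
                    ce_some("is_conjugate_acid_of", ce_named("FIX:C014")))
  chem <- add_axiom(chem, "subclass_of", ce_named("FIX:C014"),
                    ce_some("is_conjugate_acid_of", ce_named("FIX:C015")))
  chem <- ct(chem, "CHEBI:16227", "pyridine", "FIX:C001")
  chem <- ct(chem, "CHEBI:26421", "pyridines", "FIX:C001")
  chem <- ct(chem, "FIX:C016", "phenol", "FIX:C001")
  chem <- ct(chem, "FIX:C017", "phenols", "FIX:C001")
  chem <- ct(chem, "FIX:C018", "benzene", "FIX:C001")
  chem <- ct(chem, "CHEBI:30772", "butyric acid", "FIX:C007",
             synonyms = tibble::tibble(synonym = "butanoic acid",
                                       scope = "EXACT"))
  chem <- ct(chem, "FIX:C019", "purine", "FIX:C001")
  chem <- ct(chem, "CHEBI:15318", "xanthine", "FIX:C019",
             synonyms = tibble::tibble(
               synonym = "3,7-dihydro-1H-purine-2,6-dione", scope = "EXACT"))
  chem <- ct(chem, "FIX:C020", "oxime", "FIX:C001")
  chem <- ct(chem, "FIX:C021", "alkaloid", "FIX:C001")
  chem <- ct(chem, "FIX:C022", "retired chemical", obsolete = TRUE)

  go <- ontology("mini-go", header = c(`format-version` = "1.2"))
  for (r in c("has_participant", "has_input", "has_output",
              "transports_or_maintains_localization_of",
              "regulates_levels_of")) {
    go <- add_relation(go, r)
  }
  go <- add_relation(go, "transports",
                     parent = "transports_or_maintains_localization_of")
  gt <- function(onto, id, label, parents = character(0)) {
    onto <- add_term(onto, id, label, namespace = "biological_process")
    for (p in parents) onto <- add_isa(onto, id, p)
    onto
  }
  go <- gt(go, "GO:0008152", "metabolic process")
  go <- gt(go, "GO:0009058", "biosynthetic process", "GO:0008152")
  go <- gt(go, "GO:0009056", "catabolic process", "GO:0008152")
  go <- gt(go, "GO:0006810", "transport")
  go <- gt(go, "GO:0046903", "secretion", "GO:0006810")
  go <- gt(go, "GO:0005215", "transporter activity")
  go <- gt(go, "GO:0005488", "binding")
  go <- gt(go, "GO:0050896", "response to stimulus")
  go <- gt(go, "GO:0048878", "chemical homeostasis")
  # transport sub-ontology (the erroneous glucose edge included)
  go <- gt(go, "FIX:G004", "carbohydrate transport", "GO:0006810")
  go <- gt(go, "FIX:G002", "glucose transport", "FIX:G004")
  go <- gt(go, "FIX:G003", "hexose phosphate transport", "FIX:G004")
  go <- gt(go, "FIX:G001", "glucose-6-phosphate transport",
           c("FIX:G002", "FIX:G003"))
  # transporter sub-ontology (no glucose edge)
  go <- gt(go, "FIX:G005", "glucose transporter activity", "GO:0005215")
  go <- gt(go, "FIX:G006", "hexose phosphate transporter activity",
           "GO:0005215")
  go <- gt(go, "FIX:G007", "glucose-6-phosphate transporter activity",
           "FIX:G006")
  # acid/base metabolic chain
  go <- gt(go, "FIX:G008", "carboxylic acid metabolic process", "GO:0008152")
  go <- gt(go, "FIX:G009", "tricarboxylic acid metabolic process", "FIX:G008")
  go <- gt(go, "FIX:G010", "nitrilotriacetate metabolic process", "FIX:G009")
  # coverage gap and CLASS/EXACT readings
  go <- gt(go, "FIX:G011", "aldoxime metabolic process", "GO:0008152")
  go <- gt(go, "GO:0018958", "phenol metabolic process", "GO:0008152")
  go <- gt(go, "GO:0018910", "benzene metabolic process", "GO:0008152")
  go <- gt(go, "FIX:G012", "pyridine catabolic process", "GO:0009056")
  go <- gt(go, "FIX:G013", "butanoic acid metabolic process", "GO:0008152")
  go <- gt(go, "GO:0030246", "carbohydrate binding", "GO:0005488")
  go <- gt(go, "GO:0005975", "carbohydrate metabolic process", "GO:0008152")
  go <- gt(go, "FIX:G014", "purine biosynthetic process", "GO:0009058")
  go <- gt(go, "FIX:G015", "alkaloid biosynthetic process", "GO:0009058")

  expected <- list(
    conjugate_pair_count = 4L,
    conflict = list(child = "FIX:C006", parent = "FIX:C004",
                    supporting = "transport", absent = "transporter_activity"),
    unmatched_chemicals = "aldoxime",
    family_counts = c(binding = 1L, biosynthetic = 2L, catabolic = 1L,
                      metabolic = 8L, transport = 4L,
                      transporter_activity = 3L),
    butanoate_match = c(query = "butanoic acid", id = "CHEBI:30772",
                        kind = "exact_synonym"),
    flip = list(sub = "FIX:G010", sup = "FIX:G008")
  )
  list(mini_go = go, mini_chebi = chem, expected = expected)
}

#' Move xanthine to a new parent in the chemical ontology
#'
#' The release-update scenario the sync protocol handles: a chemical class is
#' re-parented upstream (here xanthine from purine to alkaloid), so inferred
#' placements depending on the old parent must be retracted and the new ones
#' asserted.
#' @param chem the bundle's `mini_chebi`.
#' @return the edited ontology.
#' @export
move_xanthine <- function(chem) {
  chem <- remove_axiom(chem, "subclass_of", "CHEBI:15318", "FIX:C019")
  add_isa(chem, "CHEBI:15318", "FIX:C021")
}

#' Generate a seeded random ontology
#'
#' Reproducible property-test input: an acyclic is_a core (each class may
#' attach to earlier classes with probability `density`), random
#' conjunction/existential axioms in the EL normal-form shapes, optional
#' logical definitions, and an optional conjugate acid/base chain. The
#' global RNG state is saved and restored.
#'
#' @param n_classes number of named classes (>= 1).
#' @param n_relations number of relation types.
#' @param density edge/axiom density in (0, 1].
#' @param seed integer seed.
#' @param conjugate_chain length of an optional conjugate chain (0 = none).
#' @return an [ontology()].
#' @export
random_ontology <- function(n_classes, n_relations = 2, density = 0.2,
                            seed = 1, conjugate_chain = 0) {
  stopifnot(n_classes >= 1, density > 0, density <= 1)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  onto <- ontology(sprintf("random-%d", seed))
  ids <- sprintf("RND:%04d", seq_len(n_classes))
  rels <- sprintf("r%d", seq_len(n_relations))
  for (r in rels) onto <- add_relation(onto, r)
  for (i in seq_len(n_classes)) {
    onto <- add_term(onto, ids[i], sprintf("random class %d", i))
  }
  if (n_classes >= 2) {
    for (i in 2:n_classes) {
      n_par <- stats::rbinom(1, 2, density)
      if (n_par > 0) {
        for (p in sample(seq_len(i - 1), min(n_par, i - 1))) {
          onto <- add_isa(onto, ids[i], ids[p])
        }
      }
    }
    n_extra <- round(density * n_classes)
    for (k in seq_len(n_extra)) {
      kind <- sample(c("conj", "exist_sup", "exist_sub"), 1)
      abc <- sample(ids, 3, replace = TRUE)
      r <- sample(rels, 1)
      if (kind == "conj" && abc[1] != abc[2]) {
        onto <- add_axiom(onto, "subclass_of",
                          ce_and(ce_named(abc[1]), ce_named(abc[2])),
                          ce_named(abc[3]))
      } else if (kind == "exist_sup" && abc[1] != abc[3]) {
        onto <- add_axiom(onto, "subclass_of", ce_named(abc[1]),
                          ce_some(r, ce_named(abc[2])))
      } else if (abc[1] != abc[3]) {
        onto <- add_axiom(onto, "subclass_of",
                          ce_some(r, ce_named(abc[2])), ce_named(abc[3]))
      }
    }
    n_eq <- if (n_classes >= 3) round(density * n_classes / 2) else 0L
    for (k in seq_len(n_eq)) {
      abc <- sample(ids, 3, replace = FALSE)
      r <- sample(rels, 1)
      onto <- add_axiom(onto, "equivalent_to", ce_named(abc[1]),
                        ce_and(ce_named(abc[2]), ce_some(r, ce_named(abc[3]))))
    }
  }
  if (conjugate_chain > 0) {
    onto <- add_relation(onto, "is_conjugate_acid_of")
    cids <- sprintf("RND:A%03d", seq_len(conjugate_chain + 1L))
    for (i in seq_along(cids)) {
      onto <- add_term(onto, cids[i], sprintf("conjugate form %d", i))
    }
    for (i in seq_len(conjugate_chain)) {
      onto <- add_axiom(onto, "subclass_of", ce_named(cids[i]),
                        ce_some("is_conjugate_acid_of", ce_named(cids[i + 1L])))
    }
  }
  onto
}
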