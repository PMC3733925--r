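# Genus-differentia definition generation: parse chemical-referencing
# process/function labels against template rules, emit equivalence axioms
# ("<class> EquivalentTo: <core class> and <relation> some <chemical>"),
# rename CLASS-reading plural chemicals to "X-containing compound", and
# generate new terms template-style with reasoner placement.

#' Default template rules
#'
#' The initial rule set for creating logical definitions of
#' chemical-referencing terms: each rule maps a label pattern with one `{X}`
#' placeholder to a genus class and a relation to the chemical. The core six
#' (metabolic/biosynthetic/catabolic process, transport, response to,
#' binding) are the field's canonical rule set; secretion, homeostasis and
#' transporter-activity are extension rules (relation chosen by analogy with
#' the transport and levels-regulation semantics) and are flagged
#' `extension = TRUE`.
#'
#' Priority (lower number wins) is fixed so longer, more specific tails beat
#' substring tails: catabolic > biosynthetic > metabolic > transporter
#' activity > transport > secretion > homeostasis > binding > response-to.
#'
#' @return tibble with columns `rule_id`, `pattern`, `family`, `genus`,
#'   `genus_label`, `relation`, `def_template`, `priority`, `extension`.
#' @export
default_rules <- function() {
  tibble::tribble(
    ~rule_id, ~pattern, ~family, ~genus, ~genus_label, ~relation, ~def_template, ~priority, ~extension,
    "catabolic", "{X} catabolic process", "catabolic", "GO:0009056", "catabolic process",
    "has_input", "The chemical reactions and pathways resulting in the breakdown of {X}.", 1L, FALSE,
    "biosynthetic", "{X} biosynthetic process", "biosynthetic", "GO:0009058", "biosynthetic process",
    "has_output", "The chemical reactions and pathways resulting in the formation of {X}.", 2L, FALSE,
    "metabolic", "{X} metabolic process", "metabolic", "GO:0008152", "metabolic process",
    "has_participant", "The chemical reactions and pathways involving {X}.", 3L, FALSE,
    "transporter_activity", "{X} transporter activity", "transporter_activity", "GO:0005215", "transporter activity",
    "transports_or_maintains_localization_of", "Enables the directed movement of {X} into, out of or within a cell, or between cells.", 4L, TRUE,
    "transport", "{X} transport", "transport", "GO:0006810", "transport",
    "transports_or_maintains_localization_of", "The directed movement of {X} into, out of or within a cell, or between cells.", 5L, FALSE,
    "secretion", "{X} secretion", "secretion", "GO:0046903", "secretion",
    "transports_or_maintains_localization_of", "The controlled release of {X} from a cell.", 6L, TRUE,
    "homeostasis", "{X} homeostasis", "homeostasis", "GO:0048878", "chemical homeostasis",
    "regulates_levels_of", "A homeostatic process involved in the maintenance of a steady state level of {X}.", 7L, TRUE,
    "binding", "{X} binding", "binding", "GO:0005488", "binding",
    "has_input", "Binding to {X}.", 8L, FALSE,
    "response_to", "response to {X}", "response_to", "GO:0050896", "response to stimulus",
    "has_input", "Any process that results in a change in state or activity of a cell or an organism as a result of a {X} stimulus.", 9L, FALSE
  )
}

#' Read template rules from a YAML config
#'
#' The rules file is a list of records with fields `rule_id`, `pattern`,
#' `family`, `genus`, `genus_label`, `relation`, `def_template`, `priority`
#' and optional `extension`.
#' @param path YAML file.
#' @return rules tibble as from [default_rules()].
#' @export
read_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  rules <- dplyr::bind_rows(lapply(raw, function(r) {
    tibble::tibble(rule_id = r$rule_id, pattern = r$pattern, family = r$family,
                   genus = r$genus, genus_label = r$genus_label %||% r$genus,
                   relation = r$relation, def_template = r$def_template,
                   priority = as.integer(r$priority),
                   extension = isTRUE(r$extension))
  }))
  rules[order(rules$priority), ]
}

#' Write template rules to a YAML config
#' @param rules rules tibble.
#' @param path output file.
#' @export
write_rules <- function(rules, path) {
  yaml::write_yaml(lapply(seq_len(nrow(rules)), function(i) as.list(rules[i, ])),
                   path)
  invisible(rules)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# substitute the chemical string into a pattern
assemble_label <- function(pattern, x) sub("{X}", x, pattern, fixed = TRUE)

#' Parse a term label against the template rules
#'
#' The first matching rule in priority order wins; the chemical string is the
#' maximal capture. Labels under the regulation sub-ontologies
#' (`regulation of ...`, `positive/negative regulation of ...`) are out of
#' scope and return no match, as is a label equal to a rule's genus label.
#'
#' @param label a term label.
#' @param rules rules tibble (priority-ordered).
#' @return one-row tibble (`rule_id`, `chemical_string`) or `NULL`.
#' @export
parse_label <- function(label, rules = default_rules()) {
  if (grepl("^(positive regulation of|negative regulation of|regulation of) ",
            label)) {
    return(NULL)
  }
  rules <- rules[order(rules$priority), ]
  if (label %in% rules$genus_label) return(NULL)
  for (i in seq_len(nrow(rules))) {
    pat <- rules$pattern[i]
    if (startsWith(pat, "{X} ")) {
      tail <- paste0(" ", sub("^\\{X\\} ", "", pat))
      if (endsWith(label, tail) && nchar(label) > nchar(tail)) {
        x <- substr(label, 1L, nchar(label) - nchar(tail))
        return(tibble::tibble(rule_id = rules$rule_id[i], chemical_string = x))
      }
    } else if (endsWith(pat, " {X}")) {
      head <- paste0(sub(" \\{X\\}$", "", pat), " ")
      if (startsWith(label, head) && nchar(label) > nchar(head)) {
        x <- substr(label, nchar(head) + 1L, nchar(label))
        return(tibble::tibble(rule_id = rules$rule_id[i], chemical_string = x))
      }
    } else {
      stop("rule pattern must be '{X} <tail>' or '<head> {X}': ", pat,
           call. = FALSE)
    }
  }
  NULL
}

#' Build the logical-definition equivalence axiom for a parsed label
#'
#' `EquivalentClasses(term, genus and relation some chemical)`. Provenance is
#' `bridge`, or `temporary` when the chemical filler is a minted GOCHE id.
#'
#' @param term the defined term's CURIE.
#' @param parsed one-row parse result from [parse_label()].
#' @param chemical CURIE of the matched (or minted) chemical.
#' @param rules rules tibble.
#' @return list with `definition` (one-row tibble: defined, genus, relation,
#'   filler, family, provenance) and `axiom` (one-row axiom tibble).
#' @export
make_logical_definition <- function(term, parsed, chemical,
                                    rules = default_rules()) {
  r <- rules[rules$rule_id == parsed$rule_id, ]
  stopifnot(nrow(r) == 1L)
  prov <- if (startsWith(chemical, "GOCHE:")) "temporary" else "bridge"
  expr <- ce_and(ce_named(r$genus), ce_some(r$relation, ce_named(chemical)))
  lhs <- term
  rhs <- ce_render(expr)
  if (lhs > rhs) { tmp <- lhs; lhs <- rhs; rhs <- tmp }
  list(
    definition = tibble::tibble(defined = term, genus = r$genus,
                                relation = r$relation, filler = chemical,
                                family = r$family, provenance = prov),
    axiom = tibble::tibble(kind = "equivalent_to", lhs = lhs, rhs = rhs,
                           provenance = prov)
  )
}

#' Bridge a process ontology to a chemical ontology
#'
#' Applies [parse_label()] + [match_chemical()] + [make_logical_definition()]
#' to every non-obsolete process term (rule-genus terms excluded), minting
#' temporary GOCHE chemicals for misses when `mint = TRUE`. Output order is
#' deterministic (terms visited in sorted-id order), so repeated runs are
#' byte-identical.
#'
#' @param go process/function [ontology()].
#' @param chem chemical [ontology()].
#' @param rules rules tibble.
#' @param registry a [goche_registry()] (carried across calls to keep minted
#'   ids stable).
#' @param mint mint temporary chemicals for unmatched names?
#' @return list with elements:
#'   `bridge` — an [ontology()] named `"bridge"` holding the equivalence
#'   axioms (provenance `bridge`/`temporary`) with all class ids registered
#'   external; `definitions` — tibble of logical definitions; `unmatched`,
#'   `ambiguous` — review ledgers; `family_counts` — per-rule-family tallies;
#'   `registry` — the updated GOCHE registry.
#' @export
bridge_ontologies <- function(go, chem, rules = default_rules(),
                              registry = goche_registry(), mint = TRUE) {
  index <- build_index(chem)
  bridge <- ontology("bridge")
  defs <- list(); unmatched <- list(); ambiguous <- list()
  live <- go$terms[!go$terms$obsolete, ]
  live <- live[order(live$id, method = "radix"), ]
  for (i in seq_len(nrow(live))) {
    tid <- live$id[i]
    if (tid %in% rules$genus) next
    parsed <- parse_label(live$label[i], rules)
    if (is.null(parsed)) next
    m <- match_chemical(parsed$chemical_string, index)
    chem_id <- m$matched
    if (is.na(chem_id) && length(m$ambiguous_with[[1]]) > 0) {
      ambiguous[[length(ambiguous) + 1L]] <- tibble::tibble(
        term = tid, chemical_string = parsed$chemical_string,
        candidates = list(m$ambiguous_with[[1]]))
      next
    }
    if (is.na(chem_id)) {
      unmatched[[length(unmatched) + 1L]] <- tibble::tibble(
        term = tid, label = live$label[i],
        chemical_string = parsed$chemical_string)
      if (!mint) next
      minted <- mint_temporary(registry, parsed$chemical_string,
                               source_term = tid)
      registry <- minted$registry
      chem_id <- minted$id
    }
    ld <- make_logical_definition(tid, parsed, chem_id, rules)
    defs[[length(defs) + 1L]] <- ld$definition
    bridge$axioms <- dplyr::bind_rows(bridge$axioms, ld$axiom)
  }
  definitions <- if (length(defs) > 0) dplyr::bind_rows(defs) else
    tibble::tibble(defined = character(), genus = character(),
                   relation = character(), filler = character(),
                   family = character(), provenance = character())
  bridge <- register_external(bridge, unique(c(
    definitions$defined, definitions$genus, definitions$filler)))
  for (r in unique(definitions$relation)) bridge <- add_relation(bridge, r)
  fam <- dplyr::count(definitions, .data$family, name = "n")
  list(
    bridge = bridge,
    definitions = definitions,
    unmatched = if (length(unmatched) > 0) dplyr::bind_rows(unmatched) else
      tibble::tibble(term = character(), label = character(),
                     chemical_string = character()),
    ambiguous = if (length(ambiguous) > 0) dplyr::bind_rows(ambiguous) else
      tibble::tibble(term = character(), chemical_string = character(),
                     candidates = list()),
    family_counts = fam,
    registry = registry
  )
}

# crude English plural test used as the CLASS-reading marker when the
# chemical ontology carries no explicit annotation
is_plural_label <- function(label) {
  grepl("[a-z]s$", label) && !grepl("(ss|us|is)$", label)
}

#' Rename a CLASS-reading chemical term label
#'
#' Plural chemical-family names (CLASS readings, e.g. `phenols`) referenced by
#' singular process labels are renamed to the `"X-containing compound"`
#' convention: `phenol metabolic process` becomes
#' `phenol-containing compound metabolic process`. EXACT-reading chemicals
#' (singular molecule names such as `benzene`) pass through unchanged.
#'
#' @param term_label the process-term label.
#' @param chemical_label the matched chemical's label (the plural form for
#'   CLASS readings).
#' @param class_reading is the chemical a CLASS-reading structural family?
#'   Defaults to a plural-label marker; override from curation config.
#' @return the (possibly renamed) label.
#' @export
containing_compound_rename <- function(term_label, chemical_label,
                                       class_reading = is_plural_label(chemical_label)) {
  if (!class_reading) return(term_label)
  singular <- sub("s$", "", chemical_label)
  for (token in unique(c(singular, chemical_label))) {
    pat <- paste0("\\b", token, "\\b")
    if (grepl(pat, term_label)) {
      return(sub(pat, paste0(singular, "-containing compound"), term_label))
    }
  }
  stop("label '", term_label, "' does not contain the chemical token '",
       singular, "'", call. = FALSE)
}

#' Generate a new defined term, template-style
#'
#' Builds a term from a template rule and a chemical: the label from the
#' pattern, EXACT synonyms by substituting each EXACT chemical synonym into
#' the pattern, the textual definition from the rule's template, the logical
#' definition axiom, and the placement (direct superclasses among process
#' terms) computed by the reasoner over the process hierarchy, the existing
#' bridge definitions, the chemical ontology and any GCI overlay.
#'
#' @param rule_id a rule id from `rules`.
#' @param chemical chemical CURIE; must exist (non-obsolete) in `chem`,
#'   otherwise a request-needed error mirrors the ask-the-chemical-ontology
#'   workflow.
#' @param go,chem ontologies.
#' @param bridge optional precomputed [bridge_ontologies()] result; computed
#'   on the fly when `NULL`.
#' @param gcis optional GCI axiom tibble (from [generate_gcis()]).
#' @param rules rules tibble.
#' @param new_id CURIE for the new term; default mints `NEW:<n>`.
#' @return list with `term` (one-row tibble), `synonyms` (tibble),
#'   `definition` (logical definition tibble), `axiom` (axiom tibble) and
#'   `placement` (character vector of direct superclass CURIEs).
#' @export
generate_term <- function(rule_id, chemical, go, chem, bridge = NULL,
                          gcis = NULL, rules = default_rules(),
                          new_id = NULL) {
  r <- rules[rules$rule_id == rule_id, ]
  stopifnot(nrow(r) == 1L)
  live <- chem$terms[!chem$terms$obsolete, ]
  if (!chemical %in% live$id) {
    stop("request missing chemical: '", chemical,
         "' is not in the chemical ontology; request it upstream before ",
         "generating the term", call. = FALSE)
  }
  chem_label <- live$label[live$id == chemical]
  label <- assemble_label(r$pattern, chem_label)
  if (label %in% go$terms$label[!go$terms$obsolete]) {
    stop("duplicate term: label '", label, "' already exists", call. = FALSE)
  }
  if (is.null(new_id)) {
    n_new <- sum(startsWith(go$terms$id, "NEW:"))
    new_id <- sprintf("NEW:%07d", n_new + 1L)
  }
  exact <- chem$synonyms[chem$synonyms$id == chemical &
                           chem$synonyms$scope == "EXACT", ]
  syns <- tibble::tibble(synonym = vapply(exact$synonym, assemble_label,
                                          character(1), pattern = r$pattern,
                                          USE.NAMES = FALSE),
                         scope = rep("EXACT", nrow(exact)))
  parsed <- tibble::tibble(rule_id = rule_id, chemical_string = chem_label)
  ld <- make_logical_definition(new_id, parsed, chemical, rules)
  if (is.null(bridge)) bridge <- bridge_ontologies(go, chem, rules)
  axioms <- dplyr::bind_rows(
    assemble_axioms(go, chem, bridge$bridge$axioms, gcis,
                    defined = bridge$definitions$defined,
                    include_asserted = "all"),
    ld$axiom)
  res <- classify_axioms(axioms)
  placement <- direct_superclasses(res, new_id,
                                   restrict_to = go$terms$id)
  list(
    term = tibble::tibble(id = new_id, label = label,
                          def = assemble_label(r$def_template, chem_label)),
    synonyms = syns,
    definition = ld$definition,
    axiom = ld$axiom,
    placement = placement
  )
}
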