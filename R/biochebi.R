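# Conjugate acid/base handling: detect asserted conjugate pairs, emit the
# per-pair general concept inclusions equating processes over an acid with
# processes over its conjugate base, and build the overlay ontology plus the
# used-subset import.

#' The pseudocode GCI relation list
#'
#' `has_participant`, `transports`, `has_input`, `has_output` — exactly the
#' four relations of the generation rule. `transports` is registered as a
#' sub-relation of `transports_or_maintains_localization_of` by
#' [build_biochebi()], which by default also adds GCIs over the longer
#' relation so transport-family definitions profit from the equivalence.
#' @return character vector of relation ids.
#' @export
default_gci_relations <- function() {
  c("has_participant", "transports", "has_input", "has_output")
}

#' Find asserted conjugate acid/base pairs
#'
#' Scans asserted `SubClassOf(Named, is_conjugate_acid_of some Named)` and
#' the `is_conjugate_base_of` counterpart. Pairs are unordered: a chemical
#' ontology asserting both directions yields one pair with both evidence
#' flags.
#'
#' @param chem chemical [ontology()].
#' @return tibble with columns `a`, `b` (sorted within the pair),
#'   `acid_of_asserted`, `base_of_asserted`.
#' @export
find_conjugate_pairs <- function(chem) {
  acid <- existential_edges(chem, "is_conjugate_acid_of")
  base <- existential_edges(chem, "is_conjugate_base_of")
  acid <- acid[acid$provenance == "asserted", ]
  base <- base[base$provenance == "asserted", ]
  mk <- function(df, flag) {
    if (nrow(df) == 0) {
      return(tibble::tibble(a = character(), b = character(), ev = character()))
    }
    a <- pmin(df$sub, df$filler)
    b <- pmax(df$sub, df$filler)
    tibble::tibble(a = a, b = b, ev = flag)
  }
  both <- dplyr::bind_rows(mk(acid, "acid_of_asserted"),
                           mk(base, "base_of_asserted"))
  both <- both[both$a != both$b, ]
  if (nrow(both) == 0) {
    return(tibble::tibble(a = character(), b = character(),
                          acid_of_asserted = logical(),
                          base_of_asserted = logical()))
  }
  out <- dplyr::summarise(dplyr::group_by(both, .data$a, .data$b),
                          acid_of_asserted = any(.data$ev == "acid_of_asserted"),
                          base_of_asserted = any(.data$ev == "base_of_asserted"),
                          .groups = "drop")
  out[order(out$a, out$b, method = "radix"), ]
}

#' Generate conjugate-equivalence GCIs
#'
#' One `EquivalentClasses(R some a, R some b)` per (pair, relation), with
#' provenance `gci`. Operands are canonicalised, so the output is invariant
#' under swapping pair orientation; count = pairs x relations.
#'
#' @param pairs tibble from [find_conjugate_pairs()].
#' @param relations relation ids; defaults to the four pseudocode relations.
#' @param known_relations optional registry; supplying it turns an unknown
#'   relation id into a configuration error.
#' @return axiom tibble (provenance `gci`).
#' @export
generate_gcis <- function(pairs, relations = default_gci_relations(),
                          known_relations = NULL) {
  if (!is.null(known_relations)) {
    bad <- setdiff(relations, known_relations)
    if (length(bad) > 0) {
      stop("unknown GCI relation id(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    for (r in relations) {
      l <- ce_render(ce_some(r, ce_named(pairs$a[i])))
      rr <- ce_render(ce_some(r, ce_named(pairs$b[i])))
      if (l > rr) { tmp <- l; l <- rr; rr <- tmp }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        kind = "equivalent_to", lhs = l, rhs = rr, provenance = "gci")
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(kind = character(), lhs = character(),
                          rhs = character(), provenance = character()))
  }
  out <- dplyr::distinct(dplyr::bind_rows(rows))
  out[order(out$lhs, out$rhs, method = "radix"), ]
}

#' Build the BioChEBI overlay
#'
#' Returns the chemical ontology with the conjugate-equivalence GCIs attached
#' (provenance `gci`); original axioms are untouched, so stripping the `gci`
#' provenance recovers the input exactly. Also registers `transports` under
#' `transports_or_maintains_localization_of` in the relation hierarchy.
#'
#' @param chem chemical [ontology()].
#' @param relations GCI relation list; the default extends the four
#'   pseudocode relations with `transports_or_maintains_localization_of` so
#'   that transport definitions written with the longer relation share the
#'   equivalence.
#' @return the overlay [ontology()].
#' @export
build_biochebi <- function(chem,
                           relations = c(default_gci_relations(),
                                         "transports_or_maintains_localization_of")) {
  pairs <- find_conjugate_pairs(chem)
  out <- chem
  if (nrow(pairs) > 0) {
    for (r in relations) out <- ensure_relation(out, r)
    if (all(c("transports", "transports_or_maintains_localization_of") %in%
              out$relations$id)) {
      i <- which(out$relations$id == "transports")
      if (is.na(out$relations$parent[i])) {
        out$relations$parent[i] <- "transports_or_maintains_localization_of"
      }
    }
    gcis <- generate_gcis(pairs, relations)
    out$axioms <- dplyr::bind_rows(out$axioms, gcis)
  }
  out
}

# conjugate partner map: id -> partners (one hop)
conjugate_partners <- function(pairs, ids) {
  unique(c(pairs$b[pairs$a %in% ids], pairs$a[pairs$b %in% ids]))
}

#' Extract the used-subset import of a chemical ontology
#'
#' The release subset: the chemical classes used by the process ontology
#' together with their descendant classes, closed under the is_a ancestors
#' needed to keep the hierarchy connected and under conjugate partners of
#' included classes (so the GCIs remain meaningful); GCIs over included
#' classes are retained. Idempotent.
#'
#' @param chem chemical [ontology()] (typically a [build_biochebi()] overlay).
#' @param used character vector of chemical CURIEs referenced by definitions.
#' @return the subset [ontology()].
#' @export
import_subset <- function(chem, used) {
  unknown <- setdiff(used, c(chem$terms$id, chem$external))
  if (length(unknown) > 0) {
    stop("unknown used id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  subset_id <- if (endsWith(chem$id, "-import")) chem$id else
    paste0(chem$id, "-import")
  if (length(used) == 0) {
    out <- ontology(subset_id)
    out$relations <- chem$relations
    return(out)
  }
  pairs <- find_conjugate_pairs(chem)
  keep <- unique(unlist(lapply(used, onto_descendants, onto = chem)))
  repeat {
    grown <- unique(c(
      keep,
      unlist(lapply(keep, onto_ancestors, onto = chem)),
      conjugate_partners(pairs, keep)))
    if (length(grown) == length(keep)) break
    keep <- grown
  }
  keep <- sort(keep, method = "radix")
  out <- ontology(subset_id)
  out$header <- chem$header
  out$terms <- chem$terms[chem$terms$id %in% keep, ]
  out$synonyms <- chem$synonyms[chem$synonyms$id %in% keep, ]
  out$xrefs <- chem$xrefs[chem$xrefs$id %in% keep, ]
  out$relations <- chem$relations
  ax <- chem$axioms
  ok <- vapply(seq_len(nrow(ax)), function(i) {
    ids <- unique(c(ce_named_ids(ce_parse(ax$lhs[i])),
                    ce_named_ids(ce_parse(ax$rhs[i]))))
    all(ids %in% keep)
  }, logical(1))
  out$axioms <- ax[ok, ]
  out$external <- intersect(chem$external, keep)
  out
}
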