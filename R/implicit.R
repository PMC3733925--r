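# Reconstruction of the chemical ontology implicit in a process/function
# ontology: the union, over the chemical-referencing sub-ontology families,
# of the inter-chemical is_a relationships that the process hierarchy
# implies; cross-family consistency audit; and diff against the reference
# chemical ontology.

#' Extract the implicit chemical ontology
#'
#' For every asserted is_a edge between two logically defined terms that
#' share a rule family, emits an edge between their chemical fillers tagged
#' with that family; the result is the union over families. Chemicals are all
#' definition fillers, so even edge-less chemicals (e.g. freshly minted
#' temporaries) are carried for the reference diff. Output is independent of
#' term iteration order.
#'
#' @param go process [ontology()].
#' @param defs logical-definition tibble from [bridge_ontologies()] (columns
#'   `defined`, `genus`, `relation`, `filler`, `family`).
#' @return an object of class `implicit_chem`: list with `chemicals`
#'   (character), `edges` (tibble `child`, `parent`, `family`) and
#'   `membership` (tibble `chemical`, `family`: which families reference
#'   which chemicals).
#' @export
extract_implicit <- function(go, defs) {
  edges <- subclass_edges(go, provenance = "asserted")
  fam_of <- stats::setNames(defs$family, defs$defined)
  chem_of <- stats::setNames(defs$filler, defs$defined)
  sel <- edges$sub %in% defs$defined & edges$sup %in% defs$defined &
    fam_of[edges$sub] == fam_of[edges$sup]
  e <- edges[sel, ]
  out <- tibble::tibble(child = unname(chem_of[e$sub]),
                        parent = unname(chem_of[e$sup]),
                        family = unname(fam_of[e$sub]))
  out <- dplyr::distinct(out)
  out <- out[out$child != out$parent, ]
  out <- out[order(out$child, out$parent, out$family, method = "radix"), ]
  membership <- dplyr::distinct(tibble::tibble(chemical = defs$filler,
                                               family = defs$family))
  membership <- membership[order(membership$chemical, membership$family,
                                 method = "radix"), ]
  structure(list(chemicals = sort(unique(defs$filler), method = "radix"),
                 edges = out,
                 membership = membership),
            class = "implicit_chem")
}

#' @export
print.implicit_chem <- function(x, ...) {
  cat("<implicit chemical ontology> ", length(x$chemicals), " chemicals, ",
      nrow(x$edges), " family-tagged edges\n", sep = "")
  invisible(x)
}

# transitive closure of an edge list; returns tibble(child, parent)
edge_closure <- function(child, parent) {
  pairs <- unique(paste(child, parent, sep = "\r"))
  repeat {
    df <- do.call(rbind, strsplit(pairs, "\r", fixed = TRUE))
    new <- character(0)
    for (i in seq_len(nrow(df))) {
      nxt <- df[df[, 1] == df[i, 2], 2]
      if (length(nxt) > 0) new <- c(new, paste(df[i, 1], nxt, sep = "\r"))
    }
    grown <- union(pairs, new)
    if (length(grown) == length(pairs)) break
    pairs <- grown
  }
  df <- do.call(rbind, strsplit(pairs, "\r", fixed = TRUE))
  tibble::tibble(child = df[, 1], parent = df[, 2])
}

#' Detect cross-family chemical inconsistencies
#'
#' A conflict is a chemical pair entailed (after transitive closure) in at
#' least one family while at least one other family mentions both chemicals
#' but does not entail the edge — the situation where one sub-ontology says a
#' chemical is a kind of another and a sibling sub-ontology, speaking about
#' both, is silent. Absence with only one endpoint mentioned is vacuous, not
#' conflicting.
#'
#' @param impl an [extract_implicit()] result.
#' @return tibble with columns `child`, `parent`, `supporting_families`,
#'   `absent_families` (list columns).
#' @export
find_cross_family_conflicts <- function(impl) {
  e <- impl$edges
  if (nrow(e) == 0) {
    return(tibble::tibble(child = character(), parent = character(),
                          supporting_families = list(),
                          absent_families = list()))
  }
  fams <- sort(unique(c(e$family, impl$membership$family)), method = "radix")
  closures <- lapply(fams, function(f) {
    ef <- e[e$family == f, ]
    if (nrow(ef) == 0) return(tibble::tibble(child = character(),
                                             parent = character()))
    edge_closure(ef$child, ef$parent)
  })
  names(closures) <- fams
  # a family mentions a chemical when any defined term of that family uses it
  mentioned <- lapply(fams, function(f) {
    unique(impl$membership$chemical[impl$membership$family == f])
  })
  names(mentioned) <- fams
  cand <- dplyr::distinct(e[, c("child", "parent")])
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    ch <- cand$child[i]; pa <- cand$parent[i]
    has_edge <- vapply(fams, function(f) {
      any(closures[[f]]$child == ch & closures[[f]]$parent == pa)
    }, logical(1))
    mentions <- vapply(fams, function(f) {
      ch %in% mentioned[[f]] && pa %in% mentioned[[f]]
    }, logical(1))
    supporting <- fams[has_edge]
    absent <- fams[mentions & !has_edge]
    if (length(supporting) > 0 && length(absent) > 0) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        child = ch, parent = pa,
        supporting_families = list(supporting),
        absent_families = list(absent))
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(child = character(), parent = character(),
                          supporting_families = list(),
                          absent_families = list()))
  }
  dplyr::bind_rows(rows)
}

#' Diff the implicit chemical ontology against the reference
#'
#' Every implicit edge is checked against reasoner entailment over the
#' reference chemical ontology plus the conjugate-equivalence GCIs: the edge
#' `child is_a parent` passes when the reference entails it directly or after
#' conjugate acid/base identification (probed as
#' `has_participant some child` being subsumed by
#' `has_participant some parent`, which the GCIs make insensitive to
#' protonation state). Chemicals absent from the reference are flagged (these
#' feed temporary-term minting), and reference-entailed edges between
#' implicit chemicals that no family asserts are reported in the reverse
#' direction. Supplying a superset of GCIs never increases the number of
#' `edge_not_in_reference` findings.
#'
#' @param impl an [extract_implicit()] result.
#' @param chem reference chemical [ontology()].
#' @param gcis GCI axiom tibble (e.g. from [generate_gcis()]); may be empty.
#' @return tibble with columns `kind`
#'   (`edge_not_in_reference`, `chemical_not_in_reference`,
#'   `reference_edge_missing_in_implicit`), `child`, `parent`
#'   (`NA` for chemical findings), `entailment_checked`.
#' @export
diff_against_reference <- function(impl, chem,
                                   gcis = tibble::tibble(
                                     kind = character(), lhs = character(),
                                     rhs = character(),
                                     provenance = character())) {
  known <- c(chem$terms$id[!chem$terms$obsolete], chem$external)
  probe_rel <- "has_participant"
  ax <- assemble_axioms(chem = chem, gcis = gcis)
  # probe: T_c <= Er.c for every implicit chemical present in the reference,
  # plus Er.p <= P_p; then edge entailment is P_p in S(T_c).
  present <- intersect(impl$chemicals, known)
  probe_id <- function(side, x) {
    paste0("PROBE:", side, "-", gsub(":", "_", x, fixed = TRUE))
  }
  probes <- list()
  for (x in present) {
    probes[[length(probes) + 1L]] <- tibble::tibble(
      kind = "subclass_of",
      lhs = probe_id("sub", x),
      rhs = ce_render(ce_some(probe_rel, ce_named(x))),
      provenance = "asserted")
    probes[[length(probes) + 1L]] <- tibble::tibble(
      kind = "subclass_of",
      lhs = ce_render(ce_some(probe_rel, ce_named(x))),
      rhs = probe_id("sup", x),
      provenance = "asserted")
  }
  axp <- dplyr::bind_rows(c(list(ax), probes))
  attr(axp, "relation_parents") <- attr(ax, "relation_parents")
  res <- classify_axioms(axp)
  edge_entailed <- function(ch, pa) {
    if (!(ch %in% present) || !(pa %in% present)) return(FALSE)
    entails(res, probe_id("sub", ch), probe_id("sup", pa))
  }
  rows <- list()
  for (x in sort(setdiff(impl$chemicals, known), method = "radix")) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      kind = "chemical_not_in_reference", child = x, parent = NA_character_,
      entailment_checked = FALSE)
  }
  uedges <- dplyr::distinct(impl$edges[, c("child", "parent")])
  for (i in seq_len(nrow(uedges))) {
    ch <- uedges$child[i]; pa <- uedges$parent[i]
    if (!edge_entailed(ch, pa)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        kind = "edge_not_in_reference", child = ch, parent = pa,
        entailment_checked = TRUE)
    }
  }
  # reference edges among implicit chemicals that no family asserts
  if (nrow(uedges) > 0) {
    cl <- edge_closure(uedges$child, uedges$parent)
  } else {
    cl <- tibble::tibble(child = character(), parent = character())
  }
  for (ch in present) {
    for (pa in setdiff(present, ch)) {
      if (edge_entailed(ch, pa) &&
          !any(cl$child == ch & cl$parent == pa)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          kind = "reference_edge_missing_in_implicit", child = ch,
          parent = pa, entailment_checked = TRUE)
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(kind = character(), child = character(),
                          parent = character(), entailment_checked = logical()))
  }
  dplyr::bind_rows(rows)
}

#' Export the implicit chemical ontology as DOT
#'
#' For visual inspection of the family-tagged graph (the manual curation
#' view).
#' @param impl an [extract_implicit()] result.
#' @param path optional output file.
#' @param labels optional named character vector (CURIE -> label).
#' @return DOT text (invisibly when `path` given).
#' @export
implicit_dot <- function(impl, path = NULL, labels = NULL) {
  lb <- function(id) {
    if (!is.null(labels) && id %in% names(labels)) labels[[id]] else id
  }
  lines <- c("digraph implicit_chemical_ontology {",
             "  rankdir=BT;")
  for (x in impl$chemicals) {
    lines <- c(lines, sprintf("  \"%s\" [label=\"%s\"];", x, lb(x)))
  }
  for (i in seq_len(nrow(impl$edges))) {
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\" [label=\"%s\"];",
                              impl$edges$child[i], impl$edges$parent[i],
                              impl$edges$family[i]))
  }
  lines <- c(lines, "}")
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(text, path, sep = "", useBytes = TRUE)
    return(invisible(text))
  }
  text
}
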