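# The shared in-memory ontology container: terms, relation types and axioms
# with provenance. One container serves GO-like, ChEBI-like, bridge and
# GOCHE-like graphs alike.

PROVENANCES <- c("asserted", "bridge", "gci", "inferred", "temporary")
SYN_SCOPES <- c("EXACT", "BROAD", "NARROW", "RELATED")

#' Create an empty ontology
#'
#' An ontology holds terms (with labels, synonyms, cross-references and an
#' obsolete flag), a simple relation-type hierarchy rooted implicitly in the
#' built-in `is_a`, and a table of axioms (SubClassOf / EquivalentClasses over
#' class expressions), each tagged with a provenance in
#' `asserted | bridge | gci | inferred | temporary`.
#'
#' @param id ontology identifier (e.g. `"mini-go"`).
#' @param header named character vector of OBO header tag/values kept for
#'   round-tripping.
#' @return an object of class `ontology`.
#' @export
ontology <- function(id = "ontology", header = character(0)) {
  structure(list(
    id = id,
    header = header,
    terms = tibble::tibble(id = character(), label = character(),
                           namespace = character(), def = character(),
                           obsolete = logical()),
    synonyms = tibble::tibble(id = character(), synonym = character(),
                              scope = character()),
    xrefs = tibble::tibble(id = character(), xref = character()),
    relations = tibble::tibble(id = character(), label = character(),
                               parent = character(), is_transitive = logical()),
    axioms = tibble::tibble(kind = character(), lhs = character(),
                            rhs = character(), provenance = character()),
    external = character(0),
    unknown = tibble::tibble(stanza = character(), line = character())
  ), class = "ontology")
}

#' @export
print.ontology <- function(x, ...) {
  cat("<ontology> ", x$id, ": ", nrow(x$terms), " terms, ",
      nrow(x$relations), " relations, ", nrow(x$axioms), " axioms\n", sep = "")
  invisible(x)
}

#' Add a term to an ontology
#'
#' @param onto an [ontology()].
#' @param id term CURIE.
#' @param label human-readable label (unique among non-obsolete terms).
#' @param namespace,def optional namespace / textual definition.
#' @param obsolete logical; obsolete terms are excluded from matching,
#'   reasoning and extraction.
#' @param synonyms either a character vector (scope defaults to RELATED) or a
#'   data frame with columns `synonym` and `scope`.
#' @param xrefs character vector of cross-referenced CURIEs.
#' @return the updated ontology.
#' @export
add_term <- function(onto, id, label, namespace = NA_character_,
                     def = NA_character_, obsolete = FALSE,
                     synonyms = NULL, xrefs = NULL) {
  stopifnot(inherits(onto, "ontology"))
  if (!is_curie(id)) stop("term id is not a CURIE: '", id, "'", call. = FALSE)
  if (id %in% onto$terms$id) stop("duplicate term id: ", id, call. = FALSE)
  onto$terms <- dplyr::bind_rows(onto$terms, tibble::tibble(
    id = id, label = label, namespace = namespace, def = def,
    obsolete = isTRUE(obsolete)))
  if (!is.null(synonyms)) {
    if (is.character(synonyms)) {
      synonyms <- tibble::tibble(synonym = synonyms, scope = "RELATED")
    }
    onto$synonyms <- dplyr::bind_rows(
      onto$synonyms,
      tibble::tibble(id = id, synonym = synonyms$synonym, scope = synonyms$scope))
  }
  if (!is.null(xrefs)) {
    onto$xrefs <- dplyr::bind_rows(onto$xrefs, tibble::tibble(id = id, xref = xrefs))
  }
  onto
}

#' Register a relation type
#'
#' `is_a` is built in and never registered. The relation hierarchy is a simple
#' acyclic parent pointer (e.g. `transports` under
#' `transports_or_maintains_localization_of`).
#'
#' @param onto an [ontology()].
#' @param id relation identifier.
#' @param label display label.
#' @param parent optional parent relation id.
#' @param is_transitive logical OBO flag (kept for round-trip).
#' @return the updated ontology.
#' @export
add_relation <- function(onto, id, label = id, parent = NA_character_,
                         is_transitive = FALSE) {
  stopifnot(inherits(onto, "ontology"))
  if (identical(id, "is_a")) stop("is_a is built-in", call. = FALSE)
  if (id %in% onto$relations$id) return(onto)
  onto$relations <- dplyr::bind_rows(onto$relations, tibble::tibble(
    id = id, label = label, parent = parent, is_transitive = isTRUE(is_transitive)))
  onto
}

#' Register external class identifiers
#'
#' Ids that axioms may reference without a local term (e.g. chemical ids in a
#' bridge ontology).
#' @param onto an [ontology()].
#' @param ids character vector of CURIEs.
#' @return the updated ontology.
#' @export
register_external <- function(onto, ids) {
  onto$external <- union(onto$external, ids)
  onto
}

#' Add an axiom
#'
#' Operands are canonicalised before insertion; a SubClassOf axiom with equal
#' operands is rejected; exact duplicates are ignored. EquivalentClasses
#' operands are stored in canonical (lexicographic) order.
#'
#' @param onto an [ontology()].
#' @param kind `"subclass_of"` or `"equivalent_to"`.
#' @param lhs,rhs class expressions (or rendering strings).
#' @param provenance one of asserted, bridge, gci, inferred, temporary.
#' @return the updated ontology.
#' @export
add_axiom <- function(onto, kind, lhs, rhs, provenance = "asserted") {
  stopifnot(inherits(onto, "ontology"))
  kind <- match.arg(kind, c("subclass_of", "equivalent_to"))
  provenance <- match.arg(provenance, PROVENANCES)
  l <- ce_render(as_ce(lhs))
  r <- ce_render(as_ce(rhs))
  if (identical(l, r)) {
    if (kind == "subclass_of") {
      stop("rejected trivial SubClassOf axiom: ", l, " <= ", r, call. = FALSE)
    }
    return(onto)
  }
  if (kind == "equivalent_to" && l > r) { tmp <- l; l <- r; r <- tmp }
  dup <- onto$axioms$kind == kind & onto$axioms$lhs == l & onto$axioms$rhs == r &
    onto$axioms$provenance == provenance
  if (any(dup)) return(onto)
  onto$axioms <- dplyr::bind_rows(onto$axioms, tibble::tibble(
    kind = kind, lhs = l, rhs = r, provenance = provenance))
  onto
}

#' @rdname add_axiom
#' @param sub,sup named-class CURIEs for the common `sub is_a sup` case.
#' @export
add_isa <- function(onto, sub, sup, provenance = "asserted") {
  add_axiom(onto, "subclass_of", ce_named(sub), ce_named(sup), provenance)
}

#' Remove matching axioms
#'
#' @inheritParams add_axiom
#' @param provenance optional filter; `NULL` removes regardless of provenance.
#' @return the updated ontology.
#' @export
remove_axiom <- function(onto, kind, lhs, rhs, provenance = NULL) {
  l <- ce_render(as_ce(lhs)); r <- ce_render(as_ce(rhs))
  if (kind == "equivalent_to" && l > r) { tmp <- l; l <- r; r <- tmp }
  keep <- !(onto$axioms$kind == kind & onto$axioms$lhs == l & onto$axioms$rhs == r &
              (if (is.null(provenance)) TRUE else onto$axioms$provenance %in% provenance))
  onto$axioms <- onto$axioms[keep, ]
  onto
}

#' Axioms as a tibble
#'
#' @param onto an [ontology()].
#' @param provenance optional provenance filter.
#' @return tibble with columns kind, lhs, rhs, provenance (lhs/rhs canonical
#'   renderings; bare CURIEs for named classes).
#' @export
axiom_table <- function(onto, provenance = NULL) {
  ax <- onto$axioms
  if (!is.null(provenance)) ax <- ax[ax$provenance %in% provenance, ]
  ax
}

#' The named-to-named subclass edges (the is_a graph)
#'
#' @param onto an [ontology()].
#' @param provenance optional provenance filter.
#' @return tibble with columns `sub`, `sup`, `provenance`.
#' @export
subclass_edges <- function(onto, provenance = NULL) {
  ax <- axiom_table(onto, provenance)
  ax <- ax[ax$kind == "subclass_of" & is_curie(ax$lhs) & is_curie(ax$rhs), ]
  tibble::tibble(sub = ax$lhs, sup = ax$rhs, provenance = ax$provenance)
}

# edges sub -[rel]-> filler from SubClassOf(Named, rel some Named)
existential_edges <- function(onto, relation) {
  ax <- onto$axioms
  pref <- paste0(relation, " some ")
  sel <- ax$kind == "subclass_of" & is_curie(ax$lhs) &
    startsWith(ax$rhs, pref) & is_curie(substring(ax$rhs, nchar(pref) + 1L))
  tibble::tibble(sub = ax$lhs[sel],
                 filler = substring(ax$rhs[sel], nchar(pref) + 1L),
                 provenance = ax$provenance[sel])
}

#' Reflexive-transitive ancestors of a term
#'
#' Walks the asserted graph: for `is_a`, SubClassOf edges between named
#' classes; for any other relation, SubClassOf(named, relation some named)
#' edges. The result always contains `start` (reflexivity) and is returned in
#' sorted order for determinism.
#'
#' @param onto an [ontology()].
#' @param start term CURIE.
#' @param relation `"is_a"` (default) or a registered relation id.
#' @return sorted character vector of ancestor CURIEs (including `start`).
#' @export
onto_ancestors <- function(onto, start, relation = "is_a") {
  if (!(start %in% onto$terms$id || start %in% onto$external)) {
    stop("unknown term id: ", start, call. = FALSE)
  }
  if (!identical(relation, "is_a") && !(relation %in% onto$relations$id)) {
    stop("unknown relation: ", relation, call. = FALSE)
  }
  edges <- if (identical(relation, "is_a")) {
    e <- subclass_edges(onto); tibble::tibble(from = e$sub, to = e$sup)
  } else {
    e <- existential_edges(onto, relation); tibble::tibble(from = e$sub, to = e$filler)
  }
  seen <- start
  frontier <- start
  while (length(frontier) > 0) {
    nxt <- unique(edges$to[edges$from %in% frontier])
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  sort(seen, method = "radix")
}

#' @rdname onto_ancestors
#' @export
onto_descendants <- function(onto, start, relation = "is_a") {
  if (!(start %in% onto$terms$id || start %in% onto$external)) {
    stop("unknown term id: ", start, call. = FALSE)
  }
  edges <- if (identical(relation, "is_a")) {
    e <- subclass_edges(onto); tibble::tibble(from = e$sub, to = e$sup)
  } else {
    e <- existential_edges(onto, relation); tibble::tibble(from = e$sub, to = e$filler)
  }
  seen <- start
  frontier <- start
  while (length(frontier) > 0) {
    nxt <- unique(edges$from[edges$to %in% frontier])
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  sort(seen, method = "radix")
}

#' Structural validation
#'
#' Checks every container invariant: CURIE shape, synonym scopes, duplicate
#' non-obsolete labels, acyclicity of the asserted is_a graph and of the
#' relation hierarchy, axioms on obsolete terms, and resolution of every named
#' class / relation referenced by an axiom. Violations are returned as data,
#' never raised.
#'
#' @param onto an [ontology()].
#' @return tibble with columns `rule`, `entity`, `detail`; zero rows iff the
#'   ontology is well-formed.
#' @export
onto_validate <- function(onto) {
  v <- list()
  bad_id <- onto$terms$id[!is_curie(onto$terms$id)]
  for (id in bad_id) v[[length(v) + 1L]] <- c("curie", id, "term id is not PREFIX:LOCAL")
  bad_scope <- onto$synonyms[!(onto$synonyms$scope %in% SYN_SCOPES), ]
  for (i in seq_len(nrow(bad_scope))) {
    v[[length(v) + 1L]] <- c("synonym_scope", bad_scope$id[i],
                             paste0("scope '", bad_scope$scope[i], "'"))
  }
  live <- onto$terms[!onto$terms$obsolete, ]
  dup <- live$label[duplicated(live$label)]
  for (lb in unique(dup)) {
    ids <- live$id[live$label == lb]
    v[[length(v) + 1L]] <- c("duplicate_label", paste(ids, collapse = ","),
                             paste0("label '", lb, "'"))
  }
  # obsolete terms must carry no outgoing axioms
  obs <- onto$terms$id[onto$terms$obsolete]
  if (length(obs) > 0) {
    out <- onto$axioms$lhs %in% obs |
      (onto$axioms$kind == "equivalent_to" & onto$axioms$rhs %in% obs)
    for (i in which(out)) {
      v[[length(v) + 1L]] <- c("obsolete_axiom", onto$axioms$lhs[i],
                               "obsolete term carries an axiom")
    }
  }
  # is_a cycles over named classes
  cyc <- find_cycle(subclass_edges(onto))
  if (!is.null(cyc)) {
    v[[length(v) + 1L]] <- c("cycle", paste(sort(cyc), collapse = ","),
                             "asserted is_a cycle")
  }
  # relation hierarchy acyclic
  rel <- onto$relations[!is.na(onto$relations$parent), ]
  rcyc <- find_cycle(tibble::tibble(sub = rel$id, sup = rel$parent))
  if (!is.null(rcyc)) {
    v[[length(v) + 1L]] <- c("relation_cycle", paste(sort(rcyc), collapse = ","),
                             "relation hierarchy cycle")
  }
  # every named id referenced by an axiom resolves
  known <- c(onto$terms$id, onto$external)
  rels <- c("is_a", onto$relations$id)
  for (i in seq_len(nrow(onto$axioms))) {
    for (side in c(onto$axioms$lhs[i], onto$axioms$rhs[i])) {
      e <- ce_parse(side)
      miss <- setdiff(ce_named_ids(e), known)
      for (m in miss) v[[length(v) + 1L]] <- c("unresolved_id", m,
                                               paste0("referenced by axiom '", side, "'"))
      rmiss <- setdiff(ce_relations(e), rels)
      for (m in rmiss) v[[length(v) + 1L]] <- c("unresolved_relation", m,
                                                paste0("referenced by axiom '", side, "'"))
    }
  }
  if (length(v) == 0) {
    return(tibble::tibble(rule = character(), entity = character(), detail = character()))
  }
  m <- do.call(rbind, v)
  tibble::tibble(rule = m[, 1], entity = m[, 2], detail = m[, 3])
}

# returns NULL or the ids on some cycle
find_cycle <- function(edges) {
  nodes <- unique(c(edges$sub, edges$sup))
  if (length(nodes) == 0) return(NULL)
  adj <- split(edges$sup, factor(edges$sub, levels = nodes))
  state <- stats::setNames(rep(0L, length(nodes)), nodes) # 0 new, 1 open, 2 done
  stack <- character(0)
  cyc <- NULL
  visit <- function(n) {
    if (!is.null(cyc)) return()
    if (state[[n]] == 1L) { cyc <<- stack[which(stack == n)[1]:length(stack)]; return() }
    if (state[[n]] == 2L) return()
    state[[n]] <<- 1L
    stack <<- c(stack, n)
    for (m in adj[[n]]) if (m %in% nodes) visit(m)
    stack <<- stack[-length(stack)]
    state[[n]] <<- 2L
  }
  for (n in nodes) visit(n)
  cyc
}

#' Terms as a tibble
#' @param onto an [ontology()].
#' @param include_obsolete keep obsolete terms?
#' @return the `terms` tibble.
#' @export
term_table <- function(onto, include_obsolete = TRUE) {
  t <- onto$terms
  if (!include_obsolete) t <- t[!t$obsolete, ]
  t
}

# label lookup helper
term_label <- function(onto, id) {
  i <- match(id, onto$terms$id)
  ifelse(is.na(i), id, onto$terms$label[i])
}
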