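# EL completion-rule reasoner. Axioms (including general concept inclusions
# between complex expressions) are normalised to the standard EL normal forms
# NF1 A <= B, NF2 A1 ^ A2 <= B, NF3 A <= Er.B, NF4 Er.A <= B, with
# deterministic fresh names for complex subexpressions, then saturated to the
# least fixpoint of the completion rules. A naive full-pass saturator serves
# as the independent test oracle.

EL_TOP <- "owl:Thing"
FRESH_PREFIX <- "FRESH:"

fresh_name <- function(render) {
  paste0(FRESH_PREFIX, utils::URLencode(render, reserved = TRUE))
}

is_fresh <- function(id) startsWith(id, FRESH_PREFIX)

#' Normalise axioms to EL normal forms
#'
#' EquivalentClasses axioms are split into two SubClassOf axioms; every
#' complex subexpression is replaced by a fresh named class that is a
#' deterministic function of the expression's canonical rendering, and the
#' fresh class is fully defined (axioms in both polarities), so the
#' saturation over the normal forms entails exactly the original
#' subsumptions between user classes. Deterministic across runs.
#'
#' @param axioms axiom tibble (`kind`, `lhs`, `rhs`; renderings as produced by
#'   [ce_render()] / [axiom_table()]).
#' @return tibble of normal-form axioms with columns `nf`
#'   (`"nf1"|"nf2"|"nf3"|"nf4"`), `c1`, `c2` (NF2 only), `r` (NF3/NF4 only),
#'   `d`.
#' @export
normalize_axioms <- function(axioms) {
  out <- new.env(parent = emptyenv())
  out$rows <- vector("list", 0L)
  out$memo <- new.env(parent = emptyenv())
  emit <- function(nf, c1, c2 = NA_character_, r = NA_character_, d) {
    out$rows[[length(out$rows) + 1L]] <- c(nf, c1, c2, r, d)
  }
  define_expr <- function(e) {
    if (e$type == "named") return(e$id)
    key <- ce_render(e)
    if (!is.null(out$memo[[key]])) return(out$memo[[key]])
    name <- fresh_name(key)
    out$memo[[key]] <- name
    if (e$type == "some") {
      b <- define_expr(e$filler)
      emit("nf3", name, r = e$relation, d = b)
      emit("nf4", b, r = e$relation, d = name)
    } else { # and
      ids <- vapply(e$parts, define_expr, character(1))
      for (id in ids) emit("nf1", name, d = id)
      if (length(ids) == 2L) {
        emit("nf2", ids[1], ids[2], d = name)
      } else {
        prefix <- define_expr(do.call(ce_and, e$parts[seq_len(length(ids) - 1L)]))
        emit("nf2", prefix, ids[length(ids)], d = name)
      }
    }
    name
  }
  for (i in seq_len(nrow(axioms))) {
    l <- define_expr(ce_parse(axioms$lhs[i]))
    r <- define_expr(ce_parse(axioms$rhs[i]))
    if (identical(l, r)) next
    emit("nf1", l, d = r)
    if (axioms$kind[i] == "equivalent_to") emit("nf1", r, d = l)
  }
  if (length(out$rows) == 0) {
    nf <- tibble::tibble(nf = character(), c1 = character(), c2 = character(),
                         r = character(), d = character())
  } else {
    m <- do.call(rbind, out$rows)
    nf <- tibble::tibble(nf = m[, 1], c1 = m[, 2], c2 = m[, 3], r = m[, 4],
                         d = m[, 5])
    nf <- dplyr::distinct(nf)
  }
  mentioned <- unlist(lapply(seq_len(nrow(axioms)), function(i) {
    c(ce_named_ids(ce_parse(axioms$lhs[i])),
      ce_named_ids(ce_parse(axioms$rhs[i])))
  }))
  if (is.null(mentioned)) mentioned <- character(0)
  attr(nf, "mentioned") <- sort(unique(mentioned), method = "radix")
  nf
}

rel_closure <- function(relation_parents) {
  # named character vector rel -> parent; returns list rel -> c(rel, ancestors)
  if (is.null(relation_parents) || length(relation_parents) == 0) return(list())
  rels <- unique(c(names(relation_parents), unname(relation_parents)))
  rels <- rels[!is.na(rels)]
  out <- list()
  for (r in rels) {
    chain <- r
    cur <- r
    while (cur %in% names(relation_parents) &&
           !is.na(relation_parents[[cur]]) &&
           !(relation_parents[[cur]] %in% chain)) {
      cur <- relation_parents[[cur]]
      chain <- c(chain, cur)
    }
    out[[r]] <- chain
  }
  out
}

#' Classify: saturate the completion rules to a fixpoint
#'
#' Computes the least fixpoint of the EL completion rules over the normal
#' forms: subsumer propagation, conjunction introduction, existential
#' introduction and propagation over role edges, and role-hierarchy lifting.
#' Terminating (the state space is bounded by classes x classes and
#' relations x classes x classes).
#'
#' @param nf normal-form tibble from [normalize_axioms()].
#' @param relation_parents named character vector mapping a relation id to its
#'   parent relation (simple relation hierarchy), or `NULL`.
#' @param extra_classes additional named classes to seed (so classes that
#'   appear in no axiom still get reflexive entries).
#' @return an object of class `el_classification`: list with `S` (named list:
#'   class -> sorted subsumer vector, fresh helper classes included),
#'   `classes` (user classes), `fixpoint = TRUE`.
#' @export
classify_nf <- function(nf, relation_parents = NULL, extra_classes = character(0)) {
  classes <- sort(unique(c(nf$c1, nf$c2[!is.na(nf$c2)], nf$d,
                           attr(nf, "mentioned"), extra_classes)),
                  method = "radix")
  classes <- classes[!is.na(classes)]
  nf1 <- new.env(parent = emptyenv())
  nf2 <- new.env(parent = emptyenv())
  nf3 <- new.env(parent = emptyenv())
  nf4 <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(nf))) {
    row <- nf[i, ]
    if (row$nf == "nf1") {
      nf1[[row$c1]] <- c(nf1[[row$c1]], row$d)
    } else if (row$nf == "nf2") {
      nf2[[row$c1]] <- c(nf2[[row$c1]], list(c(row$c2, row$d)))
      nf2[[row$c2]] <- c(nf2[[row$c2]], list(c(row$c1, row$d)))
    } else if (row$nf == "nf3") {
      nf3[[row$c1]] <- c(nf3[[row$c1]], list(c(row$r, row$d)))
    } else {
      key <- paste(row$r, row$c1)
      nf4[[key]] <- c(nf4[[key]], row$d)
    }
  }
  rsup <- rel_closure(relation_parents)
  rels_used <- unique(c(nf$r[!is.na(nf$r)], names(rsup)))
  S <- new.env(parent = emptyenv())
  preds <- new.env(parent = emptyenv())   # "rel target" -> sources
  edges <- new.env(parent = emptyenv())   # "rel src dst" -> TRUE
  queue <- vector("list", 0L)
  qhead <- 0L
  addS <- function(c, d) {
    cur <- S[[c]]
    if (d %in% cur) return(invisible())
    S[[c]] <- c(cur, d)
    queue[[length(queue) + 1L]] <<- c("S", c, d)
  }
  addR <- function(r, c, d) {
    for (s in (rsup[[r]] %||% r)) {
      key <- paste(s, c, d)
      if (is.null(edges[[key]])) {
        edges[[key]] <- TRUE
        pk <- paste(s, d)
        preds[[pk]] <- c(preds[[pk]], c)
        queue[[length(queue) + 1L]] <<- c("R", s, c, d)
      }
    }
  }
  for (a in classes) { addS(a, a); addS(a, EL_TOP) }
  while (qhead < length(queue)) {
    qhead <- qhead + 1L
    it <- queue[[qhead]]
    if (it[1] == "S") {
      c <- it[2]; d <- it[3]
      for (b in nf1[[d]]) addS(c, b)
      for (p in nf2[[d]]) if (p[1] %in% S[[c]]) addS(c, p[2])
      for (p in nf3[[d]]) addR(p[1], c, p[2])
      for (r in rels_used) {
        for (x in preds[[paste(r, c)]]) {
          for (e in nf4[[paste(r, d)]]) addS(x, e)
        }
      }
    } else {
      r <- it[2]; c <- it[3]; d <- it[4]
      for (dp in S[[d]]) {
        for (e in nf4[[paste(r, dp)]]) addS(c, e)
      }
    }
  }
  allS <- as.list(S)
  allS <- lapply(allS, function(v) sort(v, method = "radix"))
  structure(list(S = allS,
                 classes = classes[!is_fresh(classes)],
                 fixpoint = TRUE),
            class = "el_classification")
}

#' @export
print.el_classification <- function(x, ...) {
  cat("<el_classification> ", length(x$classes), " user classes at fixpoint\n",
      sep = "")
  invisible(x)
}

#' Assemble the axiom set for reasoning over the integrated ontologies
#'
#' Pools the process-ontology hierarchy, the chemical ontology, the bridge
#' definitions and (optionally) the conjugate acid/base GCI overlay into one
#' axiom tibble, and attaches the merged relation hierarchy as the
#' `relation_parents` attribute consumed by [classify_axioms()].
#'
#' `include_asserted` controls which asserted process-ontology is_a links
#' enter the reasoning input: `"all"`, `"undefined_only"` (drop named-to-named
#' is_a links whose subclass has a logical definition — the recapitulation
#' check: can reasoning re-derive the curated links?), or `"none"`.
#' Inferred-tagged links are excluded unless `include_inferred = TRUE`, so
#' stale inferences are never self-justifying.
#'
#' @param go,chem ontologies (either may be `NULL`).
#' @param bridge_axioms,gcis axiom tibbles (or `NULL`).
#' @param defined CURIEs of logically defined terms (required for
#'   `"undefined_only"`).
#' @param include_asserted see above.
#' @param include_inferred keep inferred-provenance links?
#' @return axiom tibble with attribute `relation_parents`.
#' @export
assemble_axioms <- function(go = NULL, chem = NULL, bridge_axioms = NULL,
                            gcis = NULL, defined = character(0),
                            include_asserted = c("all", "undefined_only", "none"),
                            include_inferred = FALSE) {
  include_asserted <- match.arg(include_asserted)
  parts <- list()
  rel_parents <- character(0)
  grab_rels <- function(onto) {
    rl <- onto$relations[!is.na(onto$relations$parent), ]
    stats::setNames(rl$parent, rl$id)
  }
  if (!is.null(go)) {
    ax <- go$axioms
    if (!include_inferred) ax <- ax[ax$provenance != "inferred", ]
    if (include_asserted == "none") {
      ax <- ax[!(ax$kind == "subclass_of" & is_curie(ax$lhs) & is_curie(ax$rhs)), ]
    } else if (include_asserted == "undefined_only") {
      drop <- ax$kind == "subclass_of" & is_curie(ax$lhs) & is_curie(ax$rhs) &
        ax$lhs %in% defined
      ax <- ax[!drop, ]
    }
    parts[[length(parts) + 1L]] <- ax
    rel_parents <- c(rel_parents, grab_rels(go))
  }
  if (!is.null(chem)) {
    parts[[length(parts) + 1L]] <- chem$axioms
    rel_parents <- c(rel_parents, grab_rels(chem))
  }
  if (!is.null(bridge_axioms)) parts[[length(parts) + 1L]] <- bridge_axioms
  if (!is.null(gcis)) parts[[length(parts) + 1L]] <- gcis
  ax <- dplyr::distinct(dplyr::bind_rows(parts))
  attr(ax, "relation_parents") <- rel_parents[!duplicated(names(rel_parents))]
  ax
}

#' Normalise and classify an axiom tibble in one step
#'
#' @param axioms axiom tibble; a `relation_parents` attribute (as set by
#'   [assemble_axioms()]) supplies the relation hierarchy.
#' @param relation_parents optional explicit named character vector
#'   (rel -> parent) overriding the attribute.
#' @param extra_classes named classes to seed even if absent from axioms.
#' @return an `el_classification`.
#' @export
classify_axioms <- function(axioms, relation_parents = NULL,
                            extra_classes = character(0)) {
  if (is.null(relation_parents)) {
    relation_parents <- attr(axioms, "relation_parents")
  }
  classify_nf(normalize_axioms(axioms), relation_parents, extra_classes)
}

#' Is a subsumption entailed?
#'
#' @param res an `el_classification` at fixpoint.
#' @param sub,super class CURIEs.
#' @return logical: `TRUE` iff `super` is in the saturated subsumer set of
#'   `sub` (reflexivity and the top class always hold).
#' @export
entails <- function(res, sub, super) {
  stopifnot(inherits(res, "el_classification"), isTRUE(res$fixpoint))
  if (identical(sub, super) || identical(super, EL_TOP)) return(TRUE)
  super %in% res$S[[sub]]
}

#' Classes equivalent to a class
#' @inheritParams entails
#' @param c a class CURIE.
#' @return character vector of equivalent user classes (excluding `c`).
#' @export
equivalent_classes <- function(res, c) {
  subs <- setdiff(res$S[[c]] %||% character(0), c(c, EL_TOP))
  eq <- subs[vapply(subs, function(d) c %in% (res$S[[d]] %||% character(0)),
                    logical(1))]
  eq[!is_fresh(eq)]
}

#' Most specific entailed superclasses
#'
#' Subsumers of `c` with no strictly intermediate subsumer; classes
#' equivalent to `c` and fresh helper classes are excluded, and mutually
#' equivalent direct superclasses are reported together.
#'
#' @inheritParams equivalent_classes
#' @param restrict_to optional universe of classes to place within (e.g. the
#'   process ontology's term ids).
#' @return sorted character vector of direct superclass CURIEs.
#' @export
direct_superclasses <- function(res, c, restrict_to = NULL) {
  stopifnot(inherits(res, "el_classification"))
  subs <- res$S[[c]] %||% character(0)
  eq <- c(c, equivalent_classes(res, c))
  strict <- setdiff(subs, c(eq, EL_TOP))
  strict <- strict[!is_fresh(strict)]
  if (!is.null(restrict_to)) strict <- intersect(strict, restrict_to)
  direct <- vapply(strict, function(d) {
    !any(vapply(strict, function(e) {
      # e strictly between c and d: d subsumes e but e does not subsume d
      !identical(e, d) && d %in% (res$S[[e]] %||% character(0)) &&
        !(e %in% (res$S[[d]] %||% character(0)))
    }, logical(1)))
  }, logical(1))
  sort(strict[direct], method = "radix")
}

#' All entailed subsumptions between user classes
#'
#' @param res an `el_classification`.
#' @param reflexive keep the reflexive pairs?
#' @return tibble (`sub`, `sup`), sorted, fresh classes and top excluded.
#' @export
subsumption_table <- function(res, reflexive = FALSE) {
  rows <- lapply(res$classes, function(c) {
    sups <- setdiff(res$S[[c]] %||% c, EL_TOP)
    sups <- sups[!is_fresh(sups)]
    if (!reflexive) sups <- setdiff(sups, c)
    if (length(sups) == 0) return(NULL)
    tibble::tibble(sub = c, sup = sups)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(sub = character(), sup = character()))
  }
  out[order(out$sub, out$sup, method = "radix"), ]
}

#' Naive saturation oracle
#'
#' An unoptimised reference implementation: recomputes every completion rule
#' over every class pair in full passes until nothing changes. Shares only
#' the normal forms with [classify_nf()]; the saturation machinery is
#' independent (no worklist, no incremental indexes). Intended for small
#' inputs in tests.
#'
#' @param axioms axiom tibble.
#' @param relation_parents named character vector (rel -> parent) or `NULL`.
#' @return tibble (`sub`, `sup`) of entailed non-reflexive subsumptions
#'   between user classes.
#' @export
naive_oracle <- function(axioms, relation_parents = NULL) {
  if (is.null(relation_parents)) {
    relation_parents <- attr(axioms, "relation_parents")
  }
  nf <- normalize_axioms(axioms)
  classes <- sort(unique(c(nf$c1, nf$c2[!is.na(nf$c2)], nf$d,
                           attr(nf, "mentioned"))), method = "radix")
  classes <- classes[!is.na(classes)]
  rsup <- rel_closure(relation_parents)
  rels <- unique(c(nf$r[!is.na(nf$r)], names(rsup)))
  S <- lapply(stats::setNames(classes, classes), function(a) c(a, EL_TOP))
  E <- expand.grid(r = character(0), c = character(0), d = character(0),
                   stringsAsFactors = FALSE)
  repeat {
    changed <- FALSE
    add_s <- function(c, d) {
      if (!(d %in% S[[c]])) { S[[c]] <<- c(S[[c]], d); changed <<- TRUE }
    }
    nf1 <- nf[nf$nf == "nf1", ]; nf2 <- nf[nf$nf == "nf2", ]
    nf3 <- nf[nf$nf == "nf3", ]; nf4 <- nf[nf$nf == "nf4", ]
    for (c in classes) {
      for (i in seq_len(nrow(nf1))) {
        if (nf1$c1[i] %in% S[[c]]) add_s(c, nf1$d[i])
      }
      for (i in seq_len(nrow(nf2))) {
        if (nf2$c1[i] %in% S[[c]] && nf2$c2[i] %in% S[[c]]) add_s(c, nf2$d[i])
      }
      for (i in seq_len(nrow(nf3))) {
        if (nf3$c1[i] %in% S[[c]]) {
          for (s in (rsup[[nf3$r[i]]] %||% nf3$r[i])) {
            if (!any(E$r == s & E$c == c & E$d == nf3$d[i])) {
              E <- rbind(E, data.frame(r = s, c = c, d = nf3$d[i],
                                       stringsAsFactors = FALSE))
              changed <- TRUE
            }
          }
        }
      }
    }
    for (j in seq_len(nrow(E))) {
      for (dp in S[[E$d[j]]]) {
        hits <- nf4$d[nf4$r == E$r[j] & nf4$c1 == dp]
        for (e in hits) add_s(E$c[j], e)
      }
    }
    if (!changed) break
  }
  rows <- lapply(classes[!is_fresh(classes)], function(c) {
    sups <- setdiff(S[[c]], c(c, EL_TOP))
    sups <- sups[!is_fresh(sups)]
    if (length(sups) == 0) return(NULL)
    tibble::tibble(sub = c, sup = sups)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(sub = character(), sup = character()))
  }
  out[order(out$sub, out$sup, method = "radix"), ]
}

#' Classification dump
#'
#' One row per user class with its direct superclasses, TSV-friendly.
#' @param res an `el_classification`.
#' @param restrict_to optional class universe.
#' @return tibble (`class`, `direct_superclasses` collapsed with `|`).
#' @export
classification_dump <- function(res, restrict_to = NULL) {
  tibble::tibble(
    class = res$classes,
    direct_superclasses = vapply(res$classes, function(c) {
      paste(direct_superclasses(res, c, restrict_to), collapse = "|")
    }, character(1), USE.NAMES = FALSE))
}
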