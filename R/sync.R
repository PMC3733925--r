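# Keeping the asserted process hierarchy in sync with the reasoner: newly
# inferred direct placements are asserted with an inferred-provenance tag
# (serialised as an {is_inferred="true"} qualifier), previously tagged links
# that are no longer valid inferences are retracted, and both sets are
# reported. Curator-asserted links are never touched.

#' Compute the hierarchy synchronisation report
#'
#' The target state is: for every logically defined term, the inferred-tagged
#' is_a links are exactly its direct entailed superclasses within the process
#' ontology that are not already covered by curator-asserted links (directly
#' or transitively). `to_add` lists target links not currently asserted;
#' `to_remove` lists inferred-tagged links outside the target (no longer a
#' valid inference, or no longer direct). Curator-asserted links the
#' reasoner cannot recapitulate are reported as warnings, never removed.
#'
#' The classification must be computed with previously inferred-tagged links
#' excluded (see [assemble_axioms()] with `include_inferred = FALSE`),
#' otherwise stale links would justify themselves.
#'
#' @param go process [ontology()].
#' @param res `el_classification` covering the process ontology, bridge
#'   definitions, chemical ontology and GCI overlay.
#' @param defined CURIEs of the logically defined terms to sync.
#' @return an object of class `sync_report`: list of tibbles `to_add`,
#'   `to_remove` (columns `sub`, `sup`), `warnings` (non-recapitulated
#'   asserted links) and `unchanged` count.
#' @export
compute_sync <- function(go, res, defined) {
  stopifnot(inherits(res, "el_classification"))
  if (!isTRUE(res$fixpoint)) {
    stop("stale input: classification is not at fixpoint", call. = FALSE)
  }
  edges <- subclass_edges(go)
  asserted <- edges[edges$provenance == "asserted", ]
  tagged <- edges[edges$provenance == "inferred", ]
  go_ids <- go$terms$id
  # asserted-only reachability for "already asserted directly or transitively"
  asserted_reach <- function(from) {
    seen <- from; frontier <- from
    while (length(frontier) > 0) {
      nxt <- unique(asserted$sup[asserted$sub %in% frontier])
      frontier <- setdiff(nxt, seen)
      seen <- c(seen, frontier)
    }
    setdiff(seen, from)
  }
  target <- list(); warn <- list()
  for (t in intersect(defined, go_ids)) {
    direct <- direct_superclasses(res, t, restrict_to = go_ids)
    covered <- asserted_reach(t)
    want <- setdiff(direct, covered)
    if (length(want) > 0) {
      target[[length(target) + 1L]] <- tibble::tibble(sub = t, sup = want)
    }
    # curator-asserted links the reasoner cannot recapitulate
    for (p in asserted$sup[asserted$sub == t]) {
      if (!entails(res, t, p)) {
        warn[[length(warn) + 1L]] <- tibble::tibble(
          sub = t, sup = p,
          note = "asserted link not recapitulated by reasoning; retained for curator review")
      }
    }
  }
  target <- if (length(target) > 0) dplyr::bind_rows(target) else
    tibble::tibble(sub = character(), sup = character())
  tagged_keys <- paste(tagged$sub, tagged$sup)
  target_keys <- paste(target$sub, target$sup)
  to_add <- target[!(target_keys %in% tagged_keys), ]
  to_remove <- tagged[!(tagged_keys %in% target_keys), c("sub", "sup")]
  structure(list(
    to_add = to_add[order(to_add$sub, to_add$sup, method = "radix"), ],
    to_remove = to_remove[order(to_remove$sub, to_remove$sup,
                                method = "radix"), ],
    warnings = if (length(warn) > 0) dplyr::bind_rows(warn) else
      tibble::tibble(sub = character(), sup = character(), note = character()),
    unchanged = sum(tagged_keys %in% target_keys)
  ), class = "sync_report")
}

#' @export
print.sync_report <- function(x, ...) {
  cat("<sync report> +", nrow(x$to_add), " / -", nrow(x$to_remove),
      " (", x$unchanged, " unchanged",
      if (nrow(x$warnings) > 0) paste0(", ", nrow(x$warnings), " warnings"),
      ")\n", sep = "")
  invisible(x)
}

#' Apply a synchronisation report
#'
#' Adds each `to_add` link with provenance `inferred` and removes each
#' `to_remove` link, which must currently be inferred-tagged —
#' curator-asserted axioms are never deleted. A report computed against a
#' different ontology state raises a conflict error.
#'
#' @param go process [ontology()].
#' @param report a [compute_sync()] result.
#' @return the updated ontology.
#' @export
apply_sync <- function(go, report) {
  stopifnot(inherits(report, "sync_report"))
  edges <- subclass_edges(go)
  for (i in seq_len(nrow(report$to_remove))) {
    sub <- report$to_remove$sub[i]; sup <- report$to_remove$sup[i]
    hit <- edges[edges$sub == sub & edges$sup == sup, ]
    if (nrow(hit) == 0 || !all(hit$provenance == "inferred")) {
      stop("report/state conflict: ", sub, " is_a ", sup,
           " is not an inferred-tagged link in this ontology", call. = FALSE)
    }
    go <- remove_axiom(go, "subclass_of", sub, sup, provenance = "inferred")
  }
  for (i in seq_len(nrow(report$to_add))) {
    sub <- report$to_add$sub[i]; sup <- report$to_add$sup[i]
    if (any(edges$sub == sub & edges$sup == sup)) {
      stop("report/state conflict: ", sub, " is_a ", sup,
           " is already asserted", call. = FALSE)
    }
    go <- add_isa(go, sub, sup, provenance = "inferred")
  }
  go
}

#' Serialise a sync report
#'
#' @param report a [compute_sync()] result.
#' @param path_tsv,path_json optional output files.
#' @return tibble of all report rows (`action`, `sub`, `sup`, `note`).
#' @export
write_sync_report <- function(report, path_tsv = NULL, path_json = NULL) {
  tb <- dplyr::bind_rows(
    if (nrow(report$to_add) > 0)
      tibble::tibble(action = "add", sub = report$to_add$sub,
                     sup = report$to_add$sup, note = NA_character_),
    if (nrow(report$to_remove) > 0)
      tibble::tibble(action = "remove", sub = report$to_remove$sub,
                     sup = report$to_remove$sup, note = NA_character_),
    if (nrow(report$warnings) > 0)
      tibble::tibble(action = "warn", sub = report$warnings$sub,
                     sup = report$warnings$sup, note = report$warnings$note))
  if (is.null(tb)) {
    tb <- tibble::tibble(action = character(), sub = character(),
                         sup = character(), note = character())
  }
  if (!is.null(path_tsv)) {
    utils::write.table(tb, path_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(tb, path_json, dataframe = "rows", na = "null",
                         pretty = TRUE)
  }
  tb
}
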