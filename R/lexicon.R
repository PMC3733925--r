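# Chemical-name matching: normalisation, label/synonym indexing, tiered
# lookup, and minting of temporary GOCHE terms for chemicals the reference
# ontology does not yet carry.

#' Greek-letter spelling map
#'
#' Maps Greek letters to their spelled-out names for name normalisation
#' (a common source of naming differences between process-ontology labels and
#' chemical-ontology labels, e.g. \eqn{\beta}-alanine vs beta-alanine).
#' Editable: pass a modified copy to [normalize_name()].
#' @return named character vector (letter -> name).
#' @export
greek_map <- function() {
  c("α" = "alpha", "β" = "beta", "γ" = "gamma",
    "δ" = "delta", "ε" = "epsilon", "ζ" = "zeta",
    "η" = "eta", "θ" = "theta", "ι" = "iota",
    "κ" = "kappa", "λ" = "lambda", "μ" = "mu",
    "ν" = "nu", "ξ" = "xi", "π" = "pi",
    "ρ" = "rho", "σ" = "sigma", "τ" = "tau",
    "φ" = "phi", "χ" = "chi", "ψ" = "psi",
    "ω" = "omega",
    "Α" = "alpha", "Β" = "beta", "Γ" = "gamma",
    "Δ" = "delta", "Ω" = "omega")
}

#' Normalise a chemical name
#'
#' Case-folds, collapses runs of whitespace, removes spaces around hyphens,
#' and maps Greek letters to spelled-out names. Locant commas are preserved.
#' Deliberately performs **no** plural stemming: singular vs plural
#' distinguishes a specific molecule (EXACT reading) from a structural family
#' (CLASS reading), e.g. `pyridine` vs `pyridines`, so collapsing them would
#' be a correctness bug. Idempotent.
#'
#' @param s character vector of names.
#' @param greek named character vector mapping Greek letters to names.
#' @return normalised character vector.
#' @export
normalize_name <- function(s, greek = greek_map()) {
  out <- tolower(trimws(s))
  for (g in names(greek)) {
    out <- gsub(g, tolower(greek[[g]]), out, fixed = TRUE)
  }
  out <- gsub("[[:space:]]+", " ", out)
  out <- gsub(" ?- ?", "-", out)
  out
}

# secondary key for hyphen/space-insensitive fallback matching
dehyphen_key <- function(s) gsub("-", " ", s, fixed = TRUE)

#' Build a chemical name index
#'
#' Indexes every non-obsolete label and synonym of the chemical ontology under
#' its normalised form, recording the source tier (`label`, `exact_synonym`,
#' `other_synonym`).
#'
#' @param chem a chemical [ontology()].
#' @return a tibble of class `name_index` with columns `key`, `id`, `source`.
#' @export
build_index <- function(chem) {
  live <- chem$terms[!chem$terms$obsolete, ]
  lab <- tibble::tibble(key = normalize_name(live$label), id = live$id,
                        source = "label")
  syn <- chem$synonyms[chem$synonyms$id %in% live$id, ]
  syn_tb <- tibble::tibble(
    key = normalize_name(syn$synonym), id = syn$id,
    source = as.character(ifelse(syn$scope == "EXACT", "exact_synonym",
                                 "other_synonym")))
  idx <- dplyr::distinct(dplyr::bind_rows(lab, syn_tb))
  idx <- idx[order(idx$key, idx$source, idx$id, method = "radix"), ]
  class(idx) <- c("name_index", class(idx))
  idx
}

#' Match a chemical name against the index
#'
#' Tier precedence is label > EXACT synonym > other synonym. A unique hit in
#' the winning tier is returned; multiple hits in that tier yield
#' `match_kind = "none"` with `ambiguous_with` populated — ambiguity is a
#' manual-review signal and is never auto-resolved. When the normalised query
#' misses entirely, a hyphen/space-insensitive fallback key is tried.
#'
#' @param query chemical name string(s).
#' @param index a [build_index()] result.
#' @return tibble with columns `query`, `matched` (CURIE or `NA`),
#'   `match_kind` (`label`, `exact_synonym`, `other_synonym`, `none`) and
#'   `ambiguous_with` (list column of CURIEs).
#' @export
match_chemical <- function(query, index) {
  res <- lapply(query, function(q) {
    key <- normalize_name(q)
    hits <- index[index$key == key, ]
    if (nrow(hits) == 0) {
      hits <- index[dehyphen_key(index$key) == dehyphen_key(key), ]
    }
    for (tier in c("label", "exact_synonym", "other_synonym")) {
      th <- unique(hits$id[hits$source == tier])
      if (length(th) == 1L) {
        return(tibble::tibble(query = q, matched = th, match_kind = tier,
                              ambiguous_with = list(character(0))))
      }
      if (length(th) > 1L) {
        return(tibble::tibble(query = q, matched = NA_character_,
                              match_kind = "none",
                              ambiguous_with = list(sort(th, method = "radix"))))
      }
    }
    tibble::tibble(query = q, matched = NA_character_, match_kind = "none",
                   ambiguous_with = list(character(0)))
  })
  dplyr::bind_rows(res)
}

#' Create an empty temporary-chemical registry
#'
#' Temporary chemicals are minted under the `GOCHE` prefix with sequential
#' local ids, keeping provisional chemistry separable from real reference
#' ids. The registry is itself an ontology (id `"goche"`) plus a request
#' ledger for downstream submission to the chemical ontology.
#' @return an [ontology()] with an empty `request_ledger` attribute.
#' @export
goche_registry <- function() {
  reg <- ontology("goche")
  attr(reg, "request_ledger") <- tibble::tibble(
    query = character(), normalized = character(), minted_id = character(),
    first_seen_in = character())
  reg
}

#' Mint (or fetch) a temporary chemical term
#'
#' Re-minting the same normalised query returns the existing temporary term —
#' no duplicates. Each first mint is appended to the request ledger.
#'
#' @param registry a [goche_registry()].
#' @param query the unmatched chemical string.
#' @param source_term id of the process term that first needed the chemical.
#' @return list with elements `registry` (updated) and `id` (GOCHE CURIE).
#' @export
mint_temporary <- function(registry, query, source_term = NA_character_) {
  key <- normalize_name(query)
  ledger <- attr(registry, "request_ledger")
  hit <- ledger$minted_id[ledger$normalized == key]
  if (length(hit) > 0) {
    return(list(registry = registry, id = hit[[1]]))
  }
  id <- sprintf("GOCHE:%07d", nrow(ledger) + 1L)
  registry <- add_term(registry, id, label = query)
  ledger <- dplyr::bind_rows(ledger, tibble::tibble(
    query = query, normalized = key, minted_id = id,
    first_seen_in = source_term))
  attr(registry, "request_ledger") <- ledger
  list(registry = registry, id = id)
}

#' The temporary-term request ledger
#' @param registry a [goche_registry()].
#' @return tibble (query, normalized, minted_id, first_seen_in).
#' @export
request_ledger <- function(registry) attr(registry, "request_ledger")

#' Write the request ledger as TSV
#' @param registry a [goche_registry()].
#' @param path output file.
#' @return the ledger tibble, invisibly.
#' @export
write_request_ledger <- function(registry, path) {
  ledger <- request_ledger(registry)
  utils::write.table(ledger, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(ledger)
}
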