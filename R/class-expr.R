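# Class expressions for the EL fragment used throughout: named classes,
# existential restrictions and intersections. Every expression has a unique
# canonical rendering which doubles as its identity (equality, hashing,
# deterministic file output).

#' Class expression constructors
#'
#' The package works in the EL description-logic fragment: a class expression
#' is a named class (a CURIE such as `CHEBI:16646`), an existential
#' restriction `ce_some(relation, filler)`, or an intersection
#' `ce_and(...)` of two or more expressions. Intersections are flattened,
#' de-duplicated and order-normalised so that structurally equal expressions
#' have identical canonical renderings (see [ce_render()]).
#'
#' @param id CURIE of a named class, `PREFIX:LOCAL`.
#' @param relation relation (property) identifier, e.g. `"has_input"`.
#' @param filler a class expression (or CURIE string) inside the restriction.
#' @param ... two or more class expressions (or CURIE strings) to intersect.
#' @return an object of class `ce` (a list with a `type` field).
#' @examples
#' ce_and(ce_named("GO:0008152"), ce_some("has_participant", "CHEBI:15318"))
#' @export
ce_named <- function(id) {
  stopifnot(is.character(id), length(id) == 1L)
  if (!is_curie(id)) {
    stop("not a CURIE of form PREFIX:LOCAL: '", id, "'", call. = FALSE)
  }
  structure(list(type = "named", id = id), class = "ce")
}

#' @rdname ce_named
#' @export
ce_some <- function(relation, filler) {
  stopifnot(is.character(relation), length(relation) == 1L, nzchar(relation))
  structure(list(type = "some", relation = relation, filler = as_ce(filler)),
            class = "ce")
}

#' @rdname ce_named
#' @export
ce_and <- function(...) {
  parts <- lapply(list(...), as_ce)
  # flatten nested intersections
  flat <- list()
  for (p in parts) {
    if (p$type == "and") flat <- c(flat, p$parts) else flat <- c(flat, list(p))
  }
  keys <- vapply(flat, ce_render, character(1))
  flat <- flat[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  flat <- flat[order(keys, method = "radix")]
  if (length(flat) == 1L) return(flat[[1L]])
  if (length(flat) < 2L) stop("intersection needs at least 2 distinct parts", call. = FALSE)
  structure(list(type = "and", parts = flat), class = "ce")
}

#' Coerce to a class expression
#'
#' Strings are parsed with [ce_parse()] (a bare CURIE yields a named class);
#' `ce` objects are re-canonicalised.
#'
#' @param x a `ce` object or a character rendering.
#' @return a canonical `ce` object.
#' @export
as_ce <- function(x) {
  if (inherits(x, "ce")) return(ce_canon(x))
  if (is.character(x) && length(x) == 1L) return(ce_parse(x))
  stop("cannot coerce to class expression: ", class(x)[1], call. = FALSE)
}

#' Canonicalise a class expression
#'
#' Idempotent: flattens/sorts/dedupes intersections recursively.
#' @param x a `ce` object.
#' @return canonical `ce`.
#' @export
ce_canon <- function(x) {
  switch(x$type,
    named = ce_named(x$id),
    some  = ce_some(x$relation, ce_canon(x$filler)),
    and   = do.call(ce_and, lapply(x$parts, ce_canon)),
    stop("unknown expression type: ", x$type, call. = FALSE)
  )
}

#' Render a class expression canonically
#'
#' The grammar is unambiguous and invertible by [ce_parse()]:
#' named classes render as their CURIE, restrictions as
#' `rel some filler` (non-named fillers parenthesised), intersections as
#' `(a and b and ...)` with operands in canonical order.
#'
#' @param x a `ce` object.
#' @return a single string.
#' @export
ce_render <- function(x) {
  switch(x$type,
    named = x$id,
    some  = paste0(x$relation, " some ",
                   if (x$filler$type == "named") ce_render(x$filler)
                   else paste0("(", ce_render_inner(x$filler), ")")),
    and   = paste0("(", ce_render_inner(x), ")"),
    stop("unknown expression type: ", x$type, call. = FALSE)
  )
}

ce_render_inner <- function(x) {
  if (x$type == "and") {
    paste(vapply(x$parts, function(p) {
      if (p$type == "and") paste0("(", ce_render_inner(p), ")") else ce_render(p)
    }, character(1)), collapse = " and ")
  } else {
    ce_render(x)
  }
}

#' Parse the canonical class-expression rendering
#'
#' Inverse of [ce_render()]; used for the GCI sidecar files.
#' @param text a single string.
#' @return a `ce` object.
#' @export
ce_parse <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- ce_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  expr <- ce_parse_and(st)
  if (st$pos <= length(st$toks)) {
    stop("trailing tokens in expression: '", text, "'", call. = FALSE)
  }
  ce_canon(expr)
}

ce_tokenize <- function(text) {
  # tokens: "(" ")" "and" "some" identifiers (CURIEs / relation ids)
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1) stop("empty expression", call. = FALSE)
  regmatches(text, list(m))[[1]]
}

ce_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[[st$pos]] else NA_character_
ce_next <- function(st) { t <- ce_peek(st); st$pos <- st$pos + 1L; t }

ce_parse_and <- function(st) {
  parts <- list(ce_parse_some(st))
  while (!is.na(ce_peek(st)) && ce_peek(st) == "and") {
    ce_next(st)
    parts <- c(parts, list(ce_parse_some(st)))
  }
  if (length(parts) == 1L) parts[[1L]] else do.call(ce_and, parts)
}

ce_parse_some <- function(st) {
  tok <- ce_peek(st)
  if (is.na(tok)) stop("unexpected end of expression", call. = FALSE)
  if (tok == "(") return(ce_parse_primary(st))
  # lookahead: "<id> some <primary>" vs bare CURIE
  if (st$pos + 1L <= length(st$toks) && st$toks[[st$pos + 1L]] == "some") {
    rel <- ce_next(st)
    ce_next(st) # 'some'
    ce_some(rel, ce_parse_primary(st))
  } else {
    ce_parse_primary(st)
  }
}

ce_parse_primary <- function(st) {
  tok <- ce_next(st)
  if (is.na(tok)) stop("unexpected end of expression", call. = FALSE)
  if (tok == "(") {
    inner <- ce_parse_and(st)
    if (!identical(ce_next(st), ")")) stop("expected ')'", call. = FALSE)
    inner
  } else {
    ce_named(tok)
  }
}

#' @export
print.ce <- function(x, ...) {
  cat("<class expression> ", ce_render(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.ce <- function(x, ...) ce_render(x)

is_curie <- function(x) {
  grepl("^[^:[:space:]()]+:[^:[:space:]()]+$", x)
}

#' Named classes mentioned in a class expression
#' @param x a `ce` object.
#' @return character vector of CURIEs.
#' @export
ce_named_ids <- function(x) {
  switch(x$type,
    named = x$id,
    some  = ce_named_ids(x$filler),
    and   = unique(unlist(lapply(x$parts, ce_named_ids)))
  )
}

#' Relations mentioned in a class expression
#' @param x a `ce` object.
#' @return character vector of relation ids.
#' @export
ce_relations <- function(x) {
  switch(x$type,
    named = character(0),
    some  = unique(c(x$relation, ce_relations(x$filler))),
    and   = unique(unlist(lapply(x$parts, ce_relations)))
  )
}
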