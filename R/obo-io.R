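# OBO 1.2 flat-file subset reader/writer. Covers the tags GO/ChEBI-style
# content needs: id, name, namespace, def, synonym (scoped), xref, is_a,
# relationship, intersection_of, is_obsolete, plus [Typedef] id/name/is_a/
# is_transitive. Axioms OBO cannot host (GCIs, equivalences between unnamed
# expressions) live in a plain-text sidecar, one canonical rendering per line.

#' Parse an OBO 1.2 document
#'
#' Supported tags are mapped onto the ontology model; a paired block of
#' `intersection_of` lines (one genus, one or more relation-filler lines)
#' yields one EquivalentClasses axiom between the term and the intersection,
#' read as a full logical definition. Unknown tags are tolerated and kept in
#' an `unknown`-tag ledger for round-tripping. `is_a` targets that never get a
#' stanza are registered as external ids and reported in the
#' `parse_warnings` attribute.
#'
#' Trailing qualifier blocks are honoured: `{is_inferred="true"}` marks an
#' inferred-provenance edge, `{provenance="..."}` carries any other
#' non-asserted provenance through a round-trip.
#'
#' @param text the document as a single string or character vector of lines.
#' @param id fallback ontology id when the header has none.
#' @return an [ontology()]; attribute `parse_warnings` holds a character
#'   vector of dangling-reference warnings.
#' @export
parse_obo <- function(text, id = "ontology") {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else as.character(text)
  lines <- sub("\r$", "", lines)

  onto <- ontology(id)
  warnings <- character(0)
  header <- character(0)
  n <- length(lines)
  i <- 1L
  # ---- header ----
  while (i <= n && !grepl("^\\[", lines[i])) {
    ln <- lines[i]
    if (nzchar(trimws(ln))) {
      kv <- split_tag(ln, i)
      header[kv$tag] <- kv$value
    }
    i <- i + 1L
  }
  if (!"format-version" %in% names(header)) {
    stop("OBO parse error: header declares no format-version", call. = FALSE)
  }
  if ("ontology" %in% names(header)) onto$id <- unname(header[["ontology"]])
  onto$header <- header

  referenced <- character(0)
  # ---- stanzas ----
  while (i <= n) {
    stanza_type <- trimws(lines[i])
    if (!stanza_type %in% c("[Term]", "[Typedef]")) {
      # unknown stanza type: preserve verbatim
      j <- i + 1L
      while (j <= n && !grepl("^\\[", lines[j])) j <- j + 1L
      onto$unknown <- dplyr::bind_rows(onto$unknown, tibble::tibble(
        stanza = stanza_type, line = lines[i:(j - 1L)]))
      i <- j
      next
    }
    first_line <- i
    i <- i + 1L
    tags <- list()
    while (i <= n && !grepl("^\\[", lines[i])) {
      ln <- lines[i]
      if (nzchar(trimws(ln))) {
        kv <- split_tag(ln, i)
        kv$lineno <- i
        tags[[length(tags) + 1L]] <- kv
      }
      i <- i + 1L
    }
    tagn <- vapply(tags, `[[`, character(1), "tag")
    idv <- tags[tagn == "id"]
    if (length(idv) != 1L) {
      stop("OBO parse error at line ", first_line,
           ": stanza must have exactly one id", call. = FALSE)
    }
    sid <- strip_qualifier(idv[[1]]$value)$value
    if (stanza_type == "[Typedef]") {
      nm <- pick_tag(tags, tagn, "name", sid)
      par <- pick_tag(tags, tagn, "is_a", NA_character_)
      if (!is.na(par)) par <- strip_qualifier(par)$value
      trans <- identical(pick_tag(tags, tagn, "is_transitive", "false"), "true")
      if (!identical(sid, "is_a")) {
        onto <- add_relation(onto, sid, label = nm, parent = par,
                             is_transitive = trans)
      }
      for (k in seq_along(tags)) {
        if (!tagn[k] %in% c("id", "name", "is_a", "is_transitive")) {
          onto$unknown <- dplyr::bind_rows(onto$unknown, tibble::tibble(
            stanza = sid, line = paste0(tagn[k], ": ", tags[[k]]$value)))
        }
      }
      next
    }
    # ---- [Term] ----
    label <- pick_tag(tags, tagn, "name", sid)
    namespace <- pick_tag(tags, tagn, "namespace", NA_character_)
    obsolete <- identical(pick_tag(tags, tagn, "is_obsolete", "false"), "true")
    defv <- pick_tag(tags, tagn, "def", NA_character_)
    if (!is.na(defv)) defv <- extract_quoted(defv, "def")
    syns <- list()
    xr <- character(0)
    isa <- list()
    relships <- list()
    ints <- list()
    for (k in seq_along(tags)) {
      tg <- tagn[k]; val <- tags[[k]]$value; lineno <- tags[[k]]$lineno
      if (tg == "synonym") {
        q <- extract_quoted(val, "synonym")
        rest <- trimws(sub_first_quoted(val))
        scope <- regmatches(rest, regexpr("^(EXACT|BROAD|NARROW|RELATED)", rest))
        scope <- if (length(scope) == 1L) scope else "RELATED"
        syns[[length(syns) + 1L]] <- c(q, scope)
      } else if (tg == "xref") {
        xr <- c(xr, trimws(strip_qualifier(val)$value))
      } else if (tg == "is_a") {
        sq <- strip_qualifier(val)
        isa[[length(isa) + 1L]] <- list(target = trimws(sq$value),
                                        provenance = qualifier_provenance(sq$qualifier))
      } else if (tg == "relationship") {
        sq <- strip_qualifier(val)
        parts <- strsplit(trimws(sq$value), "[[:space:]]+")[[1]]
        if (length(parts) != 2L) {
          stop("OBO parse error at line ", lineno,
               ": relationship needs '<relation> <target>'", call. = FALSE)
        }
        relships[[length(relships) + 1L]] <- list(
          rel = parts[1], target = parts[2],
          provenance = qualifier_provenance(sq$qualifier))
      } else if (tg == "intersection_of") {
        sq <- strip_qualifier(val)
        parts <- strsplit(trimws(sq$value), "[[:space:]]+")[[1]]
        if (!length(parts) %in% 1:2) {
          stop("OBO parse error at line ", lineno,
               ": malformed intersection_of", call. = FALSE)
        }
        ints[[length(ints) + 1L]] <- list(parts = parts,
                                          provenance = qualifier_provenance(sq$qualifier))
      } else if (!tg %in% c("id", "name", "namespace", "def", "is_obsolete")) {
        onto$unknown <- dplyr::bind_rows(onto$unknown, tibble::tibble(
          stanza = sid, line = paste0(tg, ": ", val)))
      }
    }
    syn_df <- if (length(syns) > 0) {
      m <- do.call(rbind, syns)
      tibble::tibble(synonym = m[, 1], scope = m[, 2])
    } else NULL
    onto <- add_term(onto, sid, label, namespace = namespace, def = defv,
                     obsolete = obsolete, synonyms = syn_df,
                     xrefs = if (length(xr) > 0) xr else NULL)
    for (e in isa) {
      onto <- add_axiom(onto, "subclass_of", ce_named(sid), ce_named(e$target),
                        provenance = e$provenance)
      referenced <- c(referenced, e$target)
    }
    for (e in relships) {
      onto <- ensure_relation(onto, e$rel)
      onto <- add_axiom(onto, "subclass_of", ce_named(sid),
                        ce_some(e$rel, ce_named(e$target)),
                        provenance = e$provenance)
      referenced <- c(referenced, e$target)
    }
    if (length(ints) > 0) {
      if (length(ints) < 2L) {
        stop("OBO parse error: term ", sid,
             " has a single intersection_of line", call. = FALSE)
      }
      parts <- list()
      prov <- "asserted"
      for (e in ints) {
        if (!identical(e$provenance, "asserted")) prov <- e$provenance
        if (length(e$parts) == 1L) {
          parts[[length(parts) + 1L]] <- ce_named(e$parts[1])
          referenced <- c(referenced, e$parts[1])
        } else {
          onto <- ensure_relation(onto, e$parts[1])
          parts[[length(parts) + 1L]] <- ce_some(e$parts[1], ce_named(e$parts[2]))
          referenced <- c(referenced, e$parts[2])
        }
      }
      onto <- add_axiom(onto, "equivalent_to", ce_named(sid),
                        do.call(ce_and, parts), provenance = prov)
    }
  }
  dangling <- setdiff(unique(referenced), onto$terms$id)
  if (length(dangling) > 0) {
    onto <- register_external(onto, dangling)
    warnings <- c(warnings, paste0("dangling reference registered as external: ",
                                   dangling))
  }
  attr(onto, "parse_warnings") <- warnings
  onto
}

ensure_relation <- function(onto, rel) {
  if (!identical(rel, "is_a") && !(rel %in% onto$relations$id)) {
    onto <- add_relation(onto, rel)
  }
  onto
}

# Decide once which axioms the OBO stanzas can host (everything else goes to
# the sidecar): named-to-named is_a, named-to-existential relationship lines,
# and at most one intersection_of logical definition per term. Returns a
# logical mask plus, for equivalence axioms, the hosting term id.
obo_hosted <- function(onto) {
  ax <- onto$axioms
  n <- nrow(ax)
  mask <- logical(n)
  host <- rep(NA_character_, n)
  term_ids <- onto$terms$id
  eq_done <- character(0)
  for (k in seq_len(n)) {
    l <- ax$lhs[k]; r <- ax$rhs[k]
    if (ax$kind[k] == "subclass_of" && l %in% term_ids) {
      rhs <- ce_parse(r)
      if (rhs$type == "named" ||
          (rhs$type == "some" && rhs$filler$type == "named")) {
        mask[k] <- TRUE
        host[k] <- l
      }
    } else if (ax$kind[k] == "equivalent_to") {
      tid <- if (l %in% term_ids && !(l %in% eq_done) && !is_curie(r)) l
      else if (r %in% term_ids && !(r %in% eq_done) && !is_curie(l)) r
      else NA_character_
      if (is.na(tid)) next
      other <- if (identical(tid, l)) r else l
      oe <- ce_parse(other)
      if (oe$type == "and") {
        bad <- vapply(oe$parts, function(p) {
          p$type == "some" && p$filler$type != "named"
        }, logical(1))
        if (any(bad)) {
          stop("cannot serialise the logical definition of ", tid,
               ": an existential filler is a complex expression; introduce ",
               "a named class for it", call. = FALSE)
        }
        if (all(vapply(oe$parts, function(p) {
          p$type == "named" || p$type == "some"
        }, logical(1)))) {
          mask[k] <- TRUE
          host[k] <- tid
          eq_done <- c(eq_done, tid)
        }
      }
    }
  }
  list(mask = mask, host = host)
}

pick_tag <- function(tags, tagn, tag, default) {
  hits <- which(tagn == tag)
  if (length(hits) == 0) return(default)
  tags[[hits[1]]]$value
}

qualifier_provenance <- function(q) {
  if (is.na(q) || !nzchar(q)) return("asserted")
  if (grepl("is_inferred=\"true\"", q, fixed = TRUE)) return("inferred")
  m <- regmatches(q, regexpr("provenance=\"[^\"]+\"", q))
  if (length(m) == 1L) return(sub("provenance=\"([^\"]+)\"", "\\1", m))
  "asserted"
}

# split "tag: value", strip trailing unquoted comment
split_tag <- function(line, lineno) {
  pos <- regexpr(":", line, fixed = TRUE)
  if (pos < 1) {
    stop("OBO parse error at line ", lineno, ": expected 'tag: value'",
         call. = FALSE)
  }
  tag <- trimws(substr(line, 1L, pos - 1L))
  value <- trimws(substr(line, pos + 1L, nchar(line)))
  value <- strip_comment(value)
  list(tag = tag, value = value)
}

strip_comment <- function(value) {
  inq <- FALSE
  chars <- strsplit(value, "", fixed = TRUE)[[1]]
  esc <- FALSE
  for (k in seq_along(chars)) {
    ch <- chars[k]
    if (esc) { esc <- FALSE; next }
    if (ch == "\\") { esc <- TRUE; next }
    if (ch == '"') inq <- !inq
    if (ch == "!" && !inq) return(trimws(substr(value, 1L, k - 1L)))
  }
  value
}

# separate a trailing {...} qualifier block
strip_qualifier <- function(value) {
  m <- regexpr("\\{[^{}]*\\}[[:space:]]*$", value)
  if (m > 0) {
    list(value = trimws(substr(value, 1L, m - 1L)),
         qualifier = trimws(regmatches(value, m)))
  } else {
    list(value = trimws(value), qualifier = NA_character_)
  }
}

extract_quoted <- function(value, tag) {
  m <- regmatches(value, regexpr('"(\\\\.|[^"\\\\])*"', value))
  if (length(m) != 1L) {
    stop("OBO parse error: ", tag, " value has no quoted string", call. = FALSE)
  }
  inner <- substr(m, 2L, nchar(m) - 1L)
  gsub('\\\\(.)', "\\1", inner)
}

sub_first_quoted <- function(value) {
  sub('"(\\\\.|[^"\\\\])*"', "", value)
}

#' Serialise an ontology to OBO 1.2 text
#'
#' Stanzas are sorted by id and tags written in a fixed canonical order, so
#' output is byte-deterministic. Named-to-named SubClassOf axioms become
#' `is_a` lines (inferred provenance marked `{is_inferred="true"}`, other
#' non-asserted provenance `{provenance="..."}`); SubClassOf to an existential
#' becomes a `relationship` line; an EquivalentClasses between a term and an
#' intersection becomes paired `intersection_of` lines. Everything else (GCIs,
#' axioms between unnamed expressions) is returned by [sidecar_axioms()] and
#' belongs in the `*.gci.txt` sidecar written by [write_gci_file()].
#'
#' @param onto an [ontology()].
#' @param path optional file to write (UTF-8, LF endings).
#' @return the document text as a single string (invisibly when `path` given).
#' @export
write_obo <- function(onto, path = NULL) {
  out <- character(0)
  header <- onto$header
  if (!"format-version" %in% names(header)) {
    header <- c(`format-version` = "1.2", header)
  }
  if (!"ontology" %in% names(header)) header[["ontology"]] <- onto$id
  ord <- c("format-version", setdiff(sort(names(header)), "format-version"))
  for (h in ord) out <- c(out, paste0(h, ": ", header[[h]]))

  ax <- onto$axioms
  hosted <- obo_hosted(onto)

  for (tid in sort(onto$terms$id, method = "radix")) {
    row <- onto$terms[onto$terms$id == tid, ]
    st <- c("", "[Term]", paste0("id: ", tid), paste0("name: ", row$label))
    if (!is.na(row$namespace)) st <- c(st, paste0("namespace: ", row$namespace))
    if (!is.na(row$def)) st <- c(st, paste0("def: \"", escape_obo(row$def), "\" []"))
    syn <- onto$synonyms[onto$synonyms$id == tid, ]
    if (nrow(syn) > 0) {
      syn <- syn[order(syn$synonym, syn$scope, method = "radix"), ]
      st <- c(st, paste0("synonym: \"", escape_obo(syn$synonym), "\" ",
                         syn$scope, " []"))
    }
    xr <- sort(onto$xrefs$xref[onto$xrefs$id == tid], method = "radix")
    if (length(xr) > 0) st <- c(st, paste0("xref: ", xr))
    if (row$obsolete) st <- c(st, "is_obsolete: true")

    sel <- which(hosted$mask & ax$kind == "subclass_of" & hosted$host == tid)
    isa_lines <- character(0); rel_lines <- character(0)
    for (k in sel) {
      rhs <- ce_parse(ax$rhs[k])
      if (rhs$type == "named") {
        isa_lines <- c(isa_lines, paste0("is_a: ", rhs$id,
                                         provenance_qualifier(ax$provenance[k])))
      } else {
        rel_lines <- c(rel_lines, paste0("relationship: ", rhs$relation, " ",
                                         rhs$filler$id,
                                         provenance_qualifier(ax$provenance[k])))
      }
    }
    st <- c(st, sort(isa_lines, method = "radix"))

    eqs <- which(hosted$mask & ax$kind == "equivalent_to" & hosted$host == tid)
    int_lines <- character(0)
    if (length(eqs) > 0) {
      k <- eqs[1]
      other <- if (ax$lhs[k] == tid) ax$rhs[k] else ax$lhs[k]
      oe <- ce_parse(other)
      lines <- vapply(oe$parts, function(p) {
        if (p$type == "named") paste0("intersection_of: ", p$id)
        else paste0("intersection_of: ", p$relation, " ", p$filler$id)
      }, character(1))
      # genus lines first, then relational differentia, each group sorted
      genus <- sort(lines[!grepl("^intersection_of: [^ ]+ [^ ]+$", lines)],
                    method = "radix")
      diffs <- sort(setdiff(lines, genus), method = "radix")
      if (length(genus) > 0 && !identical(ax$provenance[k], "asserted")) {
        genus[1] <- paste0(genus[1], " {provenance=\"", ax$provenance[k], "\"}")
      }
      int_lines <- c(genus, diffs)
    }
    st <- c(st, int_lines, sort(rel_lines, method = "radix"))
    out <- c(out, st)
  }

  if (nrow(onto$relations) > 0) {
    rels <- onto$relations[order(onto$relations$id, method = "radix"), ]
    for (k in seq_len(nrow(rels))) {
      st <- c("", "[Typedef]", paste0("id: ", rels$id[k]),
              paste0("name: ", rels$label[k]))
      if (!is.na(rels$parent[k])) st <- c(st, paste0("is_a: ", rels$parent[k]))
      if (rels$is_transitive[k]) st <- c(st, "is_transitive: true")
      out <- c(out, st)
    }
  }
  text <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(text, path, sep = "", useBytes = TRUE)
    return(invisible(text))
  }
  text
}

provenance_qualifier <- function(p) {
  if (identical(p, "asserted")) return("")
  if (identical(p, "inferred")) return(" {is_inferred=\"true\"}")
  paste0(" {provenance=\"", p, "\"}")
}

escape_obo <- function(x) gsub('"', '\\\\"', x)

#' Axioms that OBO 1.2 cannot host
#'
#' GCIs and other axioms between unnamed class expressions, destined for the
#' sidecar dump.
#' @param onto an [ontology()].
#' @return axiom tibble (kind, lhs, rhs, provenance).
#' @export
sidecar_axioms <- function(onto) {
  onto$axioms[!obo_hosted(onto)$mask, ]
}

#' Write / read the GCI sidecar dump
#'
#' One axiom per line, tab-separated canonical rendering
#' (`kind<TAB>lhs<TAB>rhs<TAB>provenance`), UTF-8, LF endings; round-trips
#' bit-exactly.
#'
#' @param axioms an axiom tibble (e.g. from [sidecar_axioms()] or
#'   [axiom_table()]).
#' @param path file path (conventionally `*.gci.txt`).
#' @return `write_gci_file` the text invisibly; `read_gci_file` an axiom
#'   tibble.
#' @export
write_gci_file <- function(axioms, path = NULL) {
  ax <- axioms[order(axioms$kind, axioms$lhs, axioms$rhs, axioms$provenance,
                     method = "radix"), ]
  lines <- paste(ax$kind, ax$lhs, ax$rhs, ax$provenance, sep = "\t")
  text <- if (length(lines) > 0) paste0(paste(lines, collapse = "\n"), "\n") else ""
  if (!is.null(path)) {
    writeLines(text, path, sep = "", useBytes = TRUE)
    return(invisible(text))
  }
  text
}

#' @rdname write_gci_file
#' @param text alternative to `path`: the dump as a string.
#' @export
read_gci_file <- function(path = NULL, text = NULL) {
  if (is.null(text)) text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(kind = character(), lhs = character(),
                          rhs = character(), provenance = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 4L)
  if (length(bad) > 0) {
    stop("malformed sidecar line ", bad[1], call. = FALSE)
  }
  m <- do.call(rbind, parts)
  tibble::tibble(kind = m[, 1], lhs = m[, 2], rhs = m[, 3], provenance = m[, 4])
}

#' Structural ontology equality
#'
#' Compares terms, synonyms, xrefs, relations and axioms up to row order;
#' header and unknown-tag ledgers are ignored. Used by the round-trip tests.
#' @param a,b ontologies.
#' @return logical.
#' @export
onto_equal <- function(a, b) {
  srt <- function(df) df[do.call(order, c(as.list(df), method = "radix")), ,
                         drop = FALSE]
  isTRUE(all.equal(srt(a$terms), srt(b$terms), check.attributes = FALSE)) &&
    isTRUE(all.equal(srt(a$synonyms), srt(b$synonyms), check.attributes = FALSE)) &&
    isTRUE(all.equal(srt(a$xrefs), srt(b$xrefs), check.attributes = FALSE)) &&
    isTRUE(all.equal(srt(a$relations), srt(b$relations), check.attributes = FALSE)) &&
    isTRUE(all.equal(srt(a$axioms), srt(b$axioms), check.attributes = FALSE))
}
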