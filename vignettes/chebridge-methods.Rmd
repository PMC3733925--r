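---
title: "Methods: logical definitions, conjugate-base equivalence, and EL classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: logical definitions, conjugate-base equivalence, and EL classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chebridge)
```

# The integration model

`chebridge` treats a process/function ontology and a chemical ontology as
two views of the same chemistry. The bridge between them is a set of
equivalence axioms in genus–differentia form,

$$ T \equiv G \sqcap \exists R.\,C $$

where $T$ is a chemical-referencing process/function term, $G$ a generic
genus class from the process ontology, $R$ a relation, and $C$ a chemical
class. Everything else in the package — the implicit-ontology audit, the
conjugate acid/base overlay, term generation, hierarchy sync — consumes
these definitions.

## Template rules

`default_rules()` maps label patterns with one `{X}` placeholder to a
(genus, relation) pair. The core six families use the conventional
relations: metabolic processes relate to their chemical through
`has_participant` (the chemical may be consumed, produced or merely
transformed), biosynthesis through `has_output`, catabolism through
`has_input`, transport through `transports_or_maintains_localization_of`,
and binding and response-to through `has_input`. Curation practice has at
times defined metabolic-process terms through `has_input` instead; both
conventions appear in circulating definition sets. We fix
`has_participant` for the metabolic family — a metabolic process does not
necessarily consume its chemical — and do not attempt to auto-detect the
other convention; a different choice is one row in a YAML rules file
(`read_rules()` / `write_rules()`).

Secretion, homeostasis and transporter-activity rules are marked
`extension = TRUE`: their families demonstrably carry chemical-referencing
terms, but no single published relation convention exists. We chose
`transports_or_maintains_localization_of` for secretion and transporter
activity (they move chemicals) and `regulates_levels_of` for homeostasis
(it maintains amounts, not locations). These defaults are deliberately
visible in the rules config rather than hard-coded conventions.

Rule priority is fixed so longer, more specific tails win: catabolic >
biosynthetic > metabolic > transporter activity > transport > secretion >
homeostasis > binding > response-to. Without this, *"x biosynthetic
process"* would parse under the metabolic rule with the nonsense capture
*"x biosynthetic"*. Labels under `regulation of` (and positive/negative
variants) are out of scope and never parsed, as are labels equal to a
rule's genus label (otherwise *response to stimulus* would mint a
"stimulus" chemical).

## Name matching

`normalize_name()` case-folds, collapses whitespace, removes spaces around
hyphens, and spells out Greek letters (the Greek map ships as an editable
table, since naming drift is open-ended). Two deliberate non-features:

- **No plural stemming.** Singular vs plural distinguishes a specific
  molecule (EXACT reading, *pyridine*) from a structural family (CLASS
  reading, *pyridines*). Collapsing them would be a correctness bug, so
  the two index keys stay distinct and the CLASS/EXACT decision is left to
  curation (`containing_compound_rename()` implements the
  "X-containing compound" renaming convention for CLASS readings, keyed on
  a plural-label marker that curation config can override).
- **Hyphen handling.** Normalisation preserves hyphens (they are
  structural in locants like *glucose-6-phosphate*); only when a query
  misses entirely does `match_chemical()` retry under a
  hyphen/space-insensitive key.

Matching is tiered — label, then EXACT synonym, then any other synonym —
and a tie within the winning tier is returned as *ambiguous*, never
auto-resolved: ambiguity is a curation signal. Misses can be minted as
sequential `GOCHE:` temporaries; re-minting the same normalised string is
idempotent, and every first mint is appended to a TSV request ledger for
upstream submission to the chemical ontology.

## Conjugate acid/base equivalence

Biological usage is largely blind to protonation state, while structural
chemistry separates an acid from each of its conjugate bases.
`find_conjugate_pairs()` scans asserted
`SubClassOf(X, ∃is_conjugate_acid_of.Y)` (and the base-of counterpart) and
deduplicates unordered pairs; `generate_gcis()` then emits, per pair and
per relation in `{has_participant, transports, has_input, has_output}`,

$$ \exists R.\,X \equiv \exists R.\,Y $$

as general concept inclusions with provenance `gci`. Only *asserted*
conjugate links generate pairs; equivalence along longer chains (citric
acid through citrate(3−)) is left to the reasoner, which derives it by
transitivity of the equivalences (property-tested for chains up to
length 5). `is_tautomer_of` is intentionally not equated — tautomer
confusion has not been an observed failure mode — and stereoisomers and
salts are untouched.

One relation-naming wrinkle: transport *definitions* use the long relation
`transports_or_maintains_localization_of`, while the GCI convention uses
the shorter `transports`. `build_biochebi()` keeps both readings: it
registers `transports` as a sub-relation of the long form and, by default,
also emits GCIs over the long relation so transport-family definitions
profit from the equivalence. `generate_gcis()` alone defaults to the
four-relation list.

## The EL reasoner

The axioms live comfortably in EL: named classes, conjunction, existential
restriction, GCIs between complex expressions, and a simple (parent-only)
relation hierarchy. Nothing in scope needs role composition, disjointness
or nominals, so unsatisfiability cannot arise and is not detected —
modelling conflicts surface through the implicit-ontology audits instead.

`normalize_axioms()` rewrites every axiom into the standard normal forms
(NF1 $A \sqsubseteq B$, NF2 $A_1 \sqcap A_2 \sqsubseteq B$, NF3
$A \sqsubseteq \exists r.B$, NF4 $\exists r.A \sqsubseteq B$). Every
complex subexpression is replaced by a fresh class whose name is a
deterministic URL-encoding of the expression's canonical rendering, so
normalisation is reproducible across runs and the same expression shares
one name everywhere; fresh classes are defined in both polarities, which
keeps the saturation complete for subsumptions between user classes.
Canonical rendering itself (intersections flattened, de-duplicated,
operands sorted lexicographically) is the package-wide equality and
tie-break device: axiom tables, GCI sidecar files and OBO output are all
byte-deterministic because of it.

`classify_nf()` saturates the completion rules with a worklist;
`naive_oracle()` recomputes every rule over every class pair in full
passes until fixpoint, sharing only the normal forms. The worklist
strategy is an implementation choice; the contract is the least fixpoint,
and the test suite holds the two implementations equal on 200 seeded
random ontologies (up to 40 classes, up to 3 relations, axiom density swept
over 0.1–0.5), with monotonicity and idempotence property suites of 100
cases each. These sizes keep the whole suite comfortably in interactive
time while being an order of magnitude above the worked-example bundle.

Entailment queries that mention complex expressions (e.g. "is
$\exists R.c$ subsumed by $\exists R.p$ after conjugate identification?")
are answered by *probe classes*: fresh named classes pinned under/over the
expressions, classified along with everything else. This keeps the
reference diff monotone in the GCI set by construction.

`direct_superclasses()` filters fresh helpers and the top class, groups
mutually equivalent classes (a class equivalent to its parent reports the
parent as an equivalence, not a superclass), and can restrict placement to
a universe such as the process ontology's ids.

## Implicit-ontology audit semantics

`extract_implicit()` emits a chemical edge for each asserted `is_a` edge
between two defined terms *of the same family*; the family tag derives
from the definition's genus, not from label suffixes, so renames do not
corrupt the audit. A cross-family conflict requires two things: some
family entails the chemical pair (transitive closure within the family),
and another family *mentions both chemicals* yet does not entail the pair.
Absence with only one endpoint present is vacuous silence, not conflict —
this is what makes the glucose-6-phosphate transport/transporter
asymmetry exactly one finding rather than a flood.

The reference diff judges an implicit edge missing only when the
reference chemistry plus the GCI overlay fails to entail it (so
acid/base-conflated edges pass), reports chemicals absent from the
reference (feeding temporary minting), and lists reference-entailed edges
between implicit chemicals that no family asserts.

## Sync semantics

`compute_sync()` aims the inferred-tagged link set at a target state: for
each defined term, its direct entailed superclasses within the process
ontology that curator-asserted links do not already cover directly or
transitively. Two deliberate choices:

- The classification input **excludes previously inferred-tagged links**
  (`assemble_axioms(include_inferred = FALSE)`) — otherwise a stale link
  would justify itself forever — and, in the shipped pipeline, asserted
  `is_a` links among defined terms (`include_asserted = "undefined_only"`),
  so reasoning is genuinely re-deriving the hierarchy rather than reading
  it back.
- Curator-asserted links are **never deleted**. Asserted links the
  reasoner cannot recapitulate (the fixture's glucose-6-phosphate
  transport edge is one) are listed in a warnings section for curator
  discussion; warnings never change an exit status.

`apply_sync()` is transactional against the state the report was computed
for, and apply-then-recompute is a fixpoint (property-tested).

## What the fixtures emulate — and what they do not

`example_bundle()` embeds the canonical integration cases in ~30 terms per
side: the transport/transporter G6P asymmetry, the nitrilotriacetate
acid/base conflation, the citric-acid conjugate ladder, CLASS vs EXACT
plural readings, a synonym-mediated match (butyric/butanoic acid), a
coverage gap in each direction (aldoxime vs oxime), and a re-parenting
scenario (xanthine) for the sync protocol. `random_ontology()` adds
seeded, validity-guaranteed inputs with an acyclic `is_a` core, random
NF2/NF3/NF4-shaped axioms, occasional logical definitions and optional
conjugate chains.

What passing on these fixtures shows: the algorithms implement their
contracts — template conformance, GCI counts, entailment flips, exact
audit findings, sync deltas, round-trip identity, oracle agreement. What
it does not show: behaviour at the scale and messiness of full public
releases (tens of thousands of classes, inconsistent synonym quality,
multi-genus definitions, cross-namespace xrefs). Headline counts reported
for any real release pair depend on the release snapshots and are not
reproducible from fixtures; the package therefore ships property-based
acceptance checks rather than snapshot counts.

## Known limitations

- Regulation-of terms, reaction-level (multi-chemical) definitions and
  role-axis classification (`has_role`) are out of scope by design.
- OBO 1.2 subset only; no OWL serialisation (the GCI sidecar is the
  persistence format for what OBO cannot host).
- The plural marker for CLASS readings is a heuristic (`-s` suffix with
  common exceptions); authoritative CLASS/EXACT decisions belong in
  curation config.
- The EL fragment omits disjointness, so contradictory chemistry cannot be
  *proved* inconsistent — it is surfaced by the audits instead.
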