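# chebridge

Tools for dovetailing a GO-style process/function ontology with a
ChEBI-style chemical ontology.

Thousands of biological-process and molecular-function terms are really
statements about chemistry: *xanthine biosynthetic process*,
*glucose-6-phosphate transport*, *carbohydrate binding*. As long as those
chemical references live only inside term labels, the chemistry they imply
cannot be checked against a real chemical ontology, and the process
hierarchy has to be curated edge by edge. `chebridge` is aimed at ontology
engineers and biocurators who maintain such resources. It:

- parses chemical-referencing labels into **genus–differentia logical
  definitions**

  ```
  Term  EquivalentTo:  Genus  and  Relation some Chemical
  e.g.  'xanthine biosynthetic process' ≡
            'biosynthetic process' ⊓ ∃has_output.'xanthine'
  ```

  using a priority-ordered template rule set (metabolic → `has_participant`,
  biosynthetic → `has_output`, catabolic → `has_input`, transport →
  `transports_or_maintains_localization_of`, binding / response-to →
  `has_input`, plus flagged extension rules for secretion, homeostasis and
  transporter activity);
- matches chemical name strings against chemical-ontology labels and
  synonyms (tiered: label > EXACT synonym > other synonym; ambiguity is
  surfaced for curation, never auto-resolved) and mints temporary
  `GOCHE:` terms for chemicals the reference does not yet carry;
- reconstructs the **implicit chemical ontology** embedded in the process
  hierarchy — for every within-family `is_a` edge between two defined terms
  it emits `chemical(child) is_a chemical(parent)` tagged with the family —
  then audits it for cross-family inconsistencies and diffs it against the
  reference chemistry;
- equates protonation states for in-vivo semantics with **general concept
  inclusions** over conjugate acid/base pairs:

  ```
  ∃R.acid ≡ ∃R.base      for R ∈ {has_participant, transports,
                                   has_input, has_output}
  ```

  so a process over *nitrilotriacetate* classifies with processes over
  *nitrilotriacetic acid* without inventing grouping classes;
- classifies terms with an **EL completion-rule reasoner** (conjunction +
  existential restriction + GCIs + a simple relation hierarchy, saturated to
  a least fixpoint) and places newly generated terms under their most
  specific entailed superclasses;
- keeps asserted and inferred hierarchies in sync: inferred direct
  placements are asserted with an `{is_inferred="true"}` tag, stale tagged
  links are retracted, and curator-asserted links are only ever *reported*,
  never deleted.

OBO 1.2 flat files are read and written directly (round-trip stable);
axioms OBO cannot host (the GCIs) live in a deterministic plain-text
sidecar (`*.gci.txt`).

## Worked example

The package ships a worked-example bundle (`example_bundle()`): a mini
chemical ontology (glucose/hexose-phosphate chemistry, the citric-acid
conjugate ladder, nitrilotriacetic acid and its conjugate base, butyric
acid with its "butanoic acid" synonym, pyridine vs pyridines, xanthine,
oxime) and a mini process ontology exercising six template families.

```r
library(chebridge)
fx <- example_bundle()
br <- bridge_ontologies(fx$mini_go, fx$mini_chebi)
br$family_counts
#   family                   n
# 1 binding                  1
# 2 biosynthetic             2
# 3 catabolic                1
# 4 metabolic                8
# 5 transport                4
# 6 transporter_activity     3
```

Nineteen chemical-referencing terms each receive exactly one equivalence
axiom; *aldoxime metabolic process* lands in the unmatched ledger and gets
the temporary chemical `GOCHE:0000001`. The definition of
*carbohydrate binding* (GO:0030246) comes out as
`GO:0005488 ⊓ ∃has_input.CHEBI:16646` — binding ⊓ ∃has_input.carbohydrate.

The cross-family audit reproduces the glucose-6-phosphate inconsistency:
the transport family says G6P is a glucose *and* a hexose phosphate, the
transporter-activity family only a hexose phosphate:

```r
impl <- extract_implicit(fx$mini_go, br$definitions)
find_cross_family_conflicts(impl)
#   child    parent   supporting_families absent_families
# 1 FIX:C006 FIX:C004 transport           transporter_activity
```

The conjugate-equivalence overlay flips an entailment that pure structural
chemistry refuses: *nitrilotriacetate metabolic process* is a
*carboxylic acid metabolic process* only once acids and their conjugate
bases are identified:

```r
gcis <- axiom_table(build_biochebi(fx$mini_chebi), provenance = "gci")
ax0 <- assemble_axioms(fx$mini_go, fx$mini_chebi, br$bridge$axioms,
                       defined = br$definitions$defined,
                       include_asserted = "undefined_only")
ax1 <- assemble_axioms(fx$mini_go, fx$mini_chebi, br$bridge$axioms,
                       gcis = gcis, defined = br$definitions$defined,
                       include_asserted = "undefined_only")
entails(classify_axioms(ax0), "FIX:G010", "FIX:G008")  # FALSE
entails(classify_axioms(ax1), "FIX:G010", "FIX:G008")  # TRUE
```

Template-driven term generation builds the label, EXACT synonyms, textual
definition and reasoner placement in one call:

```r
rec <- generate_term("biosynthetic", "CHEBI:15318", fx$mini_go,
                     fx$mini_chebi, bridge = br, gcis = gcis)
rec$term$label   # "xanthine biosynthetic process"
rec$placement    # "FIX:G014"  (purine biosynthetic process)
```

A shell entry point wrapping the same functions is installed at
`inst/cli/chebridge.R` with subcommands `bridge`, `implicit`, `audit`,
`gci`, `classify`, `sync`, `termgen` and `fixtures`.

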