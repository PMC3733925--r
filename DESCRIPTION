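Package: chebridge
Title: Bridging Process Ontologies to Chemical Ontologies with Logical Definitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrating a GO-style process/function ontology with a
    ChEBI-style chemical ontology. Parses chemical-referencing term labels into
    genus-differentia logical definitions, matches chemical names against labels
    and synonyms, extracts and audits the implicit chemical ontology embedded in
    process terms, generates conjugate acid/base bridging axioms (general concept
    inclusions), classifies terms with an EL-style completion-rule reasoner, and
    synchronizes asserted hierarchies with inferred placements. Reads and writes
    the OBO 1.2 flat-file subset used by these ontologies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    tibble,
    jsonlite,
    yaml,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
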