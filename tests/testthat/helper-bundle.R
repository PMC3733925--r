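# Shared fixtures, computed once per test session.

bundle <- example_bundle()

bundle_bridge <- bridge_ontologies(bundle$mini_go, bundle$mini_chebi)

bundle_gcis <- axiom_table(build_biochebi(bundle$mini_chebi),
                           provenance = "gci")

# classification input over the logical definitions (asserted links among
# defined terms dropped so reasoning is doing the work)
bundle_axioms <- function(gcis = bundle_gcis, go = bundle$mini_go,
                          chem = bundle$mini_chebi,
                          bridge = bundle_bridge,
                          include_asserted = "undefined_only") {
  assemble_axioms(go, chem, bridge$bridge$axioms, gcis = gcis,
                  defined = bridge$definitions$defined,
                  include_asserted = include_asserted)
}

# brute-force reflexive-transitive closure by boolean matrix squaring
closure_oracle <- function(edges, nodes) {
  m <- diag(length(nodes))
  rownames(m) <- colnames(m) <- nodes
  for (i in seq_len(nrow(edges))) m[edges$sub[i], edges$sup[i]] <- 1
  repeat {
    m2 <- (m %*% m > 0) + 0
    if (identical(m2, m)) break
    m <- m2
  }
  m
}

random_case <- function(seed) {
  set.seed(seed)
  random_ontology(n_classes = sample(3:40, 1),
                  n_relations = sample(1:3, 1),
                  density = stats::runif(1, 0.05, 0.6),
                  seed = seed,
                  conjugate_chain = seed %% 4)
}
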