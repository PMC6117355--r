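Package: cea
Title: Combination-Based Gene Set Enrichment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Functional enrichment analysis of gene lists that scores
    combinations of annotation terms rather than single terms. Each term
    combination is collapsed into a pseudo composite term (the union of its
    gene sets) and assessed with the one-sided Fisher (hypergeometric) test.
    Enriched combinations are found with a randomized greedy search over a
    multi-objective enrichment-set-cover model, pooling near-optimal
    solutions across repeated runs into a coverage/p-value landscape with a
    Pareto front. Includes exact brute-force oracles for small instances,
    redundancy evaluation via graph-based (Wang) semantic similarity with a
    resampled background, ontology level computation, active-list derivation
    from two-group expression matrices, and synthetic planted benchmarks.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
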