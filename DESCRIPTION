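Package: galswitch
Title: Hybrid Stochastic-Deterministic Modeling of GAL Regulatory Network
    Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the yeast galactose-utilization (GAL) genetic switch
    with a hybrid algorithm that couples Gillespie-sampled protein synthesis
    and degradation to a deterministically equilibrated signal-transduction
    layer, using statistical-mechanical promoter occupancy models.  Enumerates
    the 33 regulatory network configurations linking a pre-whole-genome-
    duplication ancestor carrying the bi-functional GAL1/3 gene to the extant
    S. cerevisiae network, computes induction-response behavior and three
    quantitative network features (repression strength, induction strength,
    switch effectiveness), scores all 120 orderings of the five
    post-duplication regulatory events, and assesses robustness of the path
    ranking under random parameter perturbations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve
Config/testthat/edition: 3
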