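Package: aquassembly
Title: Diversity, Ordination and Null-Model Assembly Analysis for Aquatic
    Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing bacterial community composition along
    salinity and nutrient gradients in lake and river ecosystems: OTU-table
    preprocessing (low-abundance filtering, taxonomy exclusion, rarefaction),
    alpha- and beta-diversity, UPGMA clustering, redundancy analysis with
    permutation-based forward selection and collinearity pruning, PCNM
    spatial eigenfunctions, three-set variation partitioning by partial
    redundancy analysis, distance-decay regression, permutation tests on
    distance matrices (Mantel, ANOSIM, PERMANOVA), non-parametric group
    comparisons, FAPROTAX-style functional profiling, and an abundance-based
    null model yielding a per-group stochasticity ratio for community
    assembly inference.  Includes a niche/neutral community simulator with a
    tunable deterministic-versus-stochastic assembly mixture for validating
    the pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vegan,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
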