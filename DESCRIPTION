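Package: kinflux
Title: Kinetome-Constrained Genome-Scale Metabolic Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based metabolic modeling with enzyme-kinetic flux
    bounds. Converts transcript abundance into enzyme concentrations under a
    steady-state synthesis/degradation model, caps each reaction at
    Vmax = Kcat x [E] through gene-protein-reaction rule aggregation, reduces
    a generic genome-scale model to its kinetically covered core with a
    GIMME-style linear program, prunes per-sample models by flux variability
    analysis, samples steady-state flux distributions with an
    artificial-centering hit-and-run walker, and extracts group-specific
    metabolic signatures with dual linear models and bootstrapped
    differential-abundance scores. Includes in silico knock-out/knock-in and
    quantitative inhibition/activation screens, a benchmarking harness with
    multiplicative expression noise, and deterministic toy-model and
    synthetic-cohort generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
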