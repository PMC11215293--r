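Package: ecoscore
Title: Multi-Objective Community Metabolic Modeling and Interaction Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles genome-scale metabolic models of several organisms into a
    single ecosystem model that shares metabolites through a pool compartment,
    enumerates the Pareto front between the organisms' growth/maintenance
    objectives by multi-objective linear programming, and summarizes the front
    as an ecosystem interaction score (area under the normalized front in two
    dimensions, convex-hull hypervolume in higher dimensions), a categorical
    interaction type, organism-removal score decompositions, and cross-feeding
    driver reports obtained by sampling flux distributions along the front.
    Includes flux balance and flux variability analysis on the assembled
    ecosystem, SBML (Level 3, fbc) and tabular model input/output, diet/media
    constraint handling, and a generator of small synthetic models with known
    competition, neutralism, and cross-feeding structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    boot,
    pracma,
    optparse
Config/testthat/edition: 3
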