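Package: kivflux
Title: Constraint-Based Strain Design and Batch Kinetics for
    2-Ketoisovalerate Overproduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for in-silico design of 2-ketoisovalerate (2-KIV)
    overproducing Escherichia coli strains and for the analysis of batch
    fermentation kinetics.  Implements flux balance analysis on
    genome-scale metabolic models (read from SBML Level 3 + FBC or a
    plain-text native dialect), gene knockouts through
    gene-protein-reaction rule evaluation, augmentation of a model with a
    secretion route for a cytosolic metabolite, flux variability
    analysis, and artificially-centered hit-and-run Monte Carlo sampling
    of the steady-state flux polytope.  Companion kinetics tools estimate
    the maximum specific growth rate by log-linear regression over an
    automatically detected exponential phase, compute yield coefficients
    from batch endpoint deltas, convert optical density to dry cell
    weight, and compare condition groups with Duncan's multiple range
    test.  A synthetic-data module generates an analytically solvable
    toy central-carbon network and batch growth curves with known
    parameters for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
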