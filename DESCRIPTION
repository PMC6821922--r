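Package: mastSync
Title: Phase Synchronisation and Bifurcation Analysis of Masting Tree Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of population-level synchronisation of
    annual seed production (masting) in tree populations. Implements the
    resource budget model coupled globally through pollen availability, with
    common (Moran-effect) and individual noise channels; Hilbert-transform
    instantaneous phases with phase- and amplitude-based on-year flags; the
    fraction-of-period-Q composition statistic and the pairwise in-phase
    synchrony fraction; and a border-collision bifurcation toolkit (iterated
    maps, tangency finding, periodic-window edges, density bifurcation
    diagrams and two-parameter sweeps) for the reduced one-dimensional map of
    the fully synchronised population. A synthetic ordinal survey generator
    emulates field census data with dominant period-3 cycling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, graphics, grDevices, jsonlite, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'rbm.R'
    'phase.R'
    'period.R'
    'bifurcation.R'
    'survey.R'
    'io.R'
    'pipeline.R'
    'mastSync-package.R'
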