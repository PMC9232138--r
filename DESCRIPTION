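Package: yeastcyc
Title: Multivalued Logical Modeling of the Budding Yeast Cell Cycle
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A multivalued (0-3 level) logical model of the Saccharomyces
    cerevisiae cell cycle with a generic synchronous, unit-step simulation
    engine. Provides rule evaluation, trajectory simulation with attractor
    detection, exhaustive state-transition-graph enumeration for small
    models, a perturbation algebra (knockouts, overexpression, value ranges,
    clamped regulators, expression-derived constraints, lncRNA injection),
    arrest-phase classification of trajectories, and reproducible in-silico
    experiment suites: a literature mutant benchmark, random-perturbation
    robustness ensembles, checkpoint fixation scans, and ethanol-stress /
    DNA-damage / lncRNA constraint experiments. Models can be read and
    written in a native plain-text format and in SBML-qual.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    purrr,
    rlang,
    tibble,
    tidyr,
    stats,
    utils,
    igraph,
    xml2,
    generics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
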