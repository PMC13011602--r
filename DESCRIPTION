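Package: repgate
Title: Multiplicative Threshold-Gate Simulation of DNA Replication Initiation
Version: 0.1.0
Authors@R:
    person("Repgate", "Maintainers", email = "maintainers@repgate.dev",
           role = c("aut", "cre"))
Description: Models DNA replication initiation as a conjunctive multiplicative
    gate: a cell (or a single origin) commits to S phase only when the product
    of four normalized readiness components - origin-licensing architecture,
    metabolic/kinase drive, chromatin context, and cell-cycle phase
    permissiveness - meets a threshold. Provides the gate and its graded
    (Hill) response, min-max normalization of raw assay correlates, the
    threshold surface in component space, stochastic single-cell population
    sampling with a deterministic quadrature oracle and bimodality
    diagnostics, cell-cycle trajectory simulation with phase-scheduled
    permissiveness, once-per-cycle origin consumption and reversible
    checkpoint arrest, and an in-silico factorial perturbation experiment
    that discriminates multiplicative from additive readiness models by
    binomial maximum likelihood and AIC. Includes YAML/JSON configuration,
    tabular IO, a synthetic correlate-table generator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
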