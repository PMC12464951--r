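Package: floralscape
Title: Floral Adaptive Landscapes from Visitor-Specific Fitness Contributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing floral adaptive landscapes from
    visitor-specific fitness contributions. Provides an algebra of per-visitor
    fitness curves (Gaussian, flat and tabulated forms) with additive and
    multiplicative combination and landscape diagnostics (optima, modality,
    valley depth, steepness); a seeded stochastic simulator of pollinator
    visitation to a flower population with finite pollen budgets,
    visit-by-visit pollen depletion and transfer-efficiency-based pollen
    export, together with its non-interactive additive baseline and binned,
    smoothed per-phenotype summaries; geometric-mean fitness aggregation
    across temporally varying pollinator climates; and a JSON configuration
    and CSV output layer so every analysis is reproducible from a plain-text
    description of the population, pollinator guild and environment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
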