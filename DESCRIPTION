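Package: pbtcea
Title: Cost-Utility Analysis of Proton Beam Therapy for Locally Advanced
    Esophageal Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decision-tree plus Markov cohort model comparing proton beam
    therapy (PBT) with three-dimensional conformal radiotherapy (3D-CRT)
    for locally advanced esophageal cancer from the Japanese payer
    perspective. Provides the packaged model (late radiation toxicity
    states, per-cycle transition probabilities, utility weights and social
    insurance fee based costs), a deterministic cohort engine with
    configurable accrual and discounting conventions, incremental
    cost-effectiveness analysis at two PBT fee levels, one-way (tornado)
    and probabilistic sensitivity analyses with triangular distributions
    and cost-effectiveness acceptability curves, an independent
    microsimulation oracle, and a generator of random synthetic models for
    property-based testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
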