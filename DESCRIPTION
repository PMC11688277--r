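Package: eldersim
Title: Simulation and Optimisation Toolkit for Smart Elder-Care Service Models
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Deterministic simulation and optimisation of a smart elder-care
    service model: scalar health-state dynamics driven by social, psychological
    and environmental signals; health-sensitive logistic resource allocation;
    social-capital modulation of health-behaviour cost; budget-constrained
    utility maximisation by the Lagrange multiplier method; cost-benefit ratio
    accounting and scenario comparison. The operational layer provides
    Gaussian-process imputation of short sensor gaps and a rule-based
    emergency detector (simultaneous activity drop and heart-rate rise).
    A synthetic-cohort generator reproduces urban/rural, income, lifestyle,
    diet, social-activity and pollution contrasts so every component is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
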