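Package: erythrosim
Title: Semi-Mechanistic Population Modelling of Erythropoiesis and Hemoglobin Synthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transit-compartment lifespan model of erythropoiesis coupling
    bone-marrow precursors, reticulocyte maturation and release, erythrocyte
    turnover and per-cell hemoglobin synthesis, with hemoglobin-driven
    feedback, an empirical tolerance mechanism and Imax-type drug effects on
    four distinct pathways. Provides the analytic baseline steady state,
    stiff ODE integration (compiled right-hand side), log-normal
    inter-individual variability and endpoint-specific residual error models,
    a synthetic Phase-1 trial generator, naive-pooled and two-stage maximum
    likelihood estimation, mechanism simulation panels with prediction
    intervals, and visual predictive checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    MASS,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
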