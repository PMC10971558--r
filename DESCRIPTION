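Package: fusht
Title: Focused-Ultrasound Mild Hyperthermia Simulation and Radiosensitization Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for focused-ultrasound (FUS)
    mild hyperthermia used as a radiosensitizer in preclinical rodent tumor
    models. Computes the steady-state pressure field of a focused bowl
    transducer in layered tissue via a Rayleigh-Sommerfeld surface integral,
    converts it to a volumetric heat source, solves the Pennes bioheat
    equation under hysteresis (relay) temperature control, accumulates CEM43
    thermal dose, plans radiotherapy beam-on times from machine factors, and
    analyses caliper-based tumor growth (group summaries, one-way ANOVA,
    pairwise Welch tests with Bonferroni correction). A synthetic-cohort
    generator reproduces the statistical structure of a four-arm
    hyperthermia-radiotherapy experiment so the full pipeline is testable
    without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
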