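Package: cardiolift
Title: Unit-Aware Cardiovascular Risk Classification with Personalized
    Guideline Models
Version: 0.1.0
Authors@R:
    person("Sam", "Vance", email = "svance@example.org",
           role = c("aut", "cre"))
Description: Tools for automated, transparent classification of clinical
    cardiovascular phenotypes. Provides a compositional unit-of-measure
    registry with analyte-aware conversion between mass and molar
    concentrations, a patient-record data model with readers and writers
    for legacy spreadsheet tables and RDF Turtle, derivation of body mass
    index, Friedewald LDL cholesterol and Framingham general-CVD risk
    scores, declarative band-based guideline models (official and
    clinician-personalized variants), a semantic-lifting classifier,
    concordance evaluation against expert labels, recovery of personal
    decision thresholds from labeled data, and a reproducible synthetic
    cohort generator with a configurable rule-following expert labeler.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
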