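Package: ciedsim
Title: Patient-Level Markov Simulation of Cardiac Device Battery Longevity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time Markov microsimulation of follow-up after primary
    implantation of cardiac implantable electronic devices (ICD and CRT-D),
    comparing legacy against extended battery longevity. Simulated patients
    move quarterly through implant, maintenance, generator-change and
    revision states until death or a 15-year horizon, accruing discounted
    payer costs and life years. Includes a deterministic tunnel-state
    expected-value oracle for validating the Monte Carlo engine, declarative
    scenario bundles for reference and sensitivity analyses, and a synthetic
    Medicare-style claims generator together with the claims-derivation rules
    (cohort identification, Charlson comorbidity index, infection
    attribution, quarterly cost aggregation) so the parameter-derivation
    pipeline is testable end to end without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
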