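Package: cardiolab
Title: Lumped-Parameter Simulation of Human Cardiovascular Mechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time (1 ms) lumped-parameter simulator of human
    cardiovascular mechanics for teaching and scripted experiments. Models
    heart chambers as time-varying elastances in the Suga-Sagawa framework,
    heart valves as ideal diodes with series resistance, and arteries as
    Windkessel compliances. Two configurations are provided: an isolated
    left heart filled from a constant-pressure venous source (5
    compartments) and a closed double circulation with all four chambers,
    systemic and pulmonary beds (10 compartments). A heart-rate-dependent
    ECG timing generator (quadratic interval functions of cycle length)
    triggers mechanical activation and yields the diastolic time fraction.
    Includes steady-state detection, parameter sweeps, per-cycle summary
    metrics (EDV, ESV, SV, CO, EF, systolic/diastolic pressure), an
    atrioventricular-plane-displacement animation geometry, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
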