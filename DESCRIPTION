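Package: metroimmune
Title: Tumor-Immune-Drug Dynamics Under Metronomic Chemotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a five-state ordinary differential equation model of
    tumor growth, drug pharmacokinetics and immune recruitment under impulsive
    (bolus) metronomic dosing of an immunogenic-cell-death drug such as
    cyclophosphamide. Generates synthetic longitudinal tumor-volume cohorts
    with the design of a multi-arm mouse glioma experiment, calibrates a
    single population parameter set to pooled multi-arm data by multistart
    bounded nonlinear least squares, and provides downstream analyses:
    immune-peak timing, normalized mean growth curves, tumor-escape
    classification, drug-versus-immune kill attribution, and predictions for
    untested dosing schedules.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
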