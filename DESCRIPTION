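Package: pyrekin
Title: Toxicokinetic Modelling of Permethrin and Cypermethrin Urinary Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-isomer multi-compartment toxicokinetic model of permethrin and
    cypermethrin and their urinary metabolites (cis-DCCA, trans-DCCA, 3-PBA).
    Simulates arbitrary oral/dermal/inhalation exposure scenarios with an
    adaptive Runge-Kutta solver, evaluates closed-form single-bolus solutions,
    fits model parameters to per-void urinary excretion time courses by
    windowed least squares with grid search and rank aggregation, generates
    synthetic urine-void data sets, and reconstructs absorbed parent-compound
    doses from biomarker measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
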