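Package: sirodose
Title: Population Pharmacokinetics and Initial-Dose Simulation of Sirolimus
    in Pediatric Lymphangioma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Nonlinear mixed-effects population pharmacokinetic modelling of
    oral sirolimus in children with lymphatic malformations. Implements a
    one-compartment first-order absorption model with allometric scaling of
    clearance (exponent 0.75) and volume (exponent 1), lognormal
    inter-individual variability on clearance and an additive residual error,
    fitted by first-order conditional estimation with interaction (FOCE-I)
    and an objective-function-value based stepwise covariate search.
    Provides model diagnostics (conditional weighted residuals, nonparametric
    bootstrap, prediction-corrected visual predictive checks), a Monte Carlo
    probability-of-target-attainment engine over a weight-by-dose grid
    against a 5-15 ng/ml trough window, weight-banded initial-dose
    recommendation, a synthetic therapeutic-drug-monitoring cohort generator,
    and NONMEM-convention dataset input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
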