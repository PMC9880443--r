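Package: eudgate
Title: Per-Fraction Dose Effectiveness Analysis for Gated Lung Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify the interfraction stability of delivered dose
    distributions in exhale-gated radiotherapy of locally advanced lung cancer.
    Computes dose-volume histograms and two equivalent uniform dose measures
    (the power-law gEUD and a cell-survival EUD with SF2 calibrated from the
    Poisson tumor control probability model) for clinical target volumes
    deformed fraction by fraction, extracts geometric deformation features
    (directed Hausdorff distance by minimal isotropic expansion, propagated
    minimum-dose points, deformation-vector projections), accumulates dose
    through displacement-field inversion under the static dose cloud
    approximation with gamma-index verification, and evaluates how well the
    per-fraction minimum dose and geometric features predict per-fraction gEUD
    with weighted random-forest and neural-network regressors under
    leave-one-patient-out (nested) cross-validation. A seeded synthetic cohort
    generator reproduces the statistical structure of a gated lung radiotherapy
    series so the entire pipeline runs without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    ranger,
    nnet,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
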