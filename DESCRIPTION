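Package: cachexpk
Title: Population Pharmacokinetics of Monoclonal Antibodies in Murine
    Cancer-Cachexia Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for single-dose intravenous
    monoclonal-antibody pharmacokinetic studies in mouse models of cancer
    cachexia. Provides a closed-form two-compartment intravenous-bolus
    kinetic kernel, a synthetic cohort generator emulating a two-strain
    tumour-bearing/tumour-free study design with cachexia-shifted
    covariates, per-subject non-compartmental analysis (automatic terminal
    phase selection, linear trapezoidal AUC), nonlinear mixed-effects
    estimation by first-order conditional estimation with interaction
    (FOCE-I), stepwise covariate modelling with likelihood-ratio tests
    (univariate screen, forward addition, backward elimination), and
    study-level quality control with nonparametric group statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    deSolve,
    jsonlite,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
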