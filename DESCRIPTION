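Package: cefapk
Title: Population Pharmacokinetics of Prophylactic Cefazolin in Hip Arthroplasty
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonlinear mixed-effects analysis of cefazolin plasma concentrations
    after intravenous bolus prophylaxis in total hip arthroplasty. Provides
    closed-form mammillary compartment kinetics (1-3 compartments), a stochastic
    approximation EM (SAEM) estimation engine with importance-sampling likelihood
    and BIC-based structural and covariate model selection, renal-function
    covariate formulas (Cockcroft-Gault, CKD-EPI), model diagnostics
    (prediction-corrected visual predictive checks, normalized prediction
    distribution errors, goodness-of-fit tables, eta shrinkage), a synthetic
    virtual-cohort generator emulating the study design, and Monte-Carlo dosing
    simulations yielding probability-of-target-attainment and
    toxicity-exceedance summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, ggplot2, yaml, jsonlite
Suggests: testthat (>= 3.0.0), deSolve, minpack.lm, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
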