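Package: cqtr
Title: Cardiodynamic ECG and Concentration-QTc Analysis for Oncology
    Thorough-QT Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A reusable pipeline for the cardiodynamic ECG and
    concentration-QTc analysis of Holter-based thorough-QT assessments in
    oncology trials without a placebo arm.  Provides replicate averaging
    and QT correction (Fridericia, Bazett, and individualized QTcI with a
    per-subject log-log regression exponent), time-matched baseline change
    analysis with one-sided 95% upper confidence bounds from a
    repeated-measures mixed model, categorical ECG threshold analyses,
    non-compartmental pharmacokinetics (linear-log trapezoidal AUC,
    terminal half-life, accumulation ratio), a four-model
    concentration-QTc nonlinear mixed-effects hierarchy (no-effect,
    linear, Emax, sigmoid Emax) with likelihood-ratio selection, covariate
    screening, and a subject-resampling bootstrap, and simulation of the
    QTc effect size at a reference concentration.  A virtual cohort
    generator emulating the triplicate-Holter plus plasma-sampling design
    makes every stage testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    nlme,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
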