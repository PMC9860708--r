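Package: fmnpk
Title: Parent-Metabolite Pharmacokinetic Modeling of Formononetin and Daidzein
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for parent-metabolite pharmacokinetic analysis of the
    isoflavone formononetin and its metabolite daidzein after single oral
    dosing in rats. Provides the two-compartment parent plus metabolite
    compartmental model (closed-form linear solution with a numeric ODE
    fallback), non-compartmental analysis (Cmax, Tmax, terminal slope,
    half-life, AUC, apparent clearance and volume), pooled maximum-likelihood
    and Laplace-approximate nonlinear mixed-effects estimation with
    exponential inter-individual variability and selectable residual-error
    models, information-criterion model comparison, subject-resampling
    bootstrap confidence intervals, bioanalytical calibration and
    protein-binding arithmetic, and a synthetic study generator with known
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
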