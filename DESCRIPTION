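Package: vpaeval
Title: External Evaluation of Pediatric Valproic Acid Population
    Pharmacokinetic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for externally evaluating published population
    pharmacokinetic models of valproic acid in children with epilepsy.
    Provides a library of ten published models with their covariate
    equations, between-subject variability and residual-error structures;
    closed-form one- and two-compartment steady-state predictions; five
    saturable protein-binding strategies (one-binding-site, Langmuir,
    dose-dependent maximum effect, linear non-saturable, simple exponent)
    with population fitting by Laplace-approximate marginal likelihood;
    prediction-based diagnostics (MDPE, MAPE, F20, F30 and the
    four-threshold acceptability verdict); simulation-based diagnostics
    (normalized prediction distribution errors with the three-test
    battery, prediction-corrected visual predictive checks); maximum a
    posteriori Bayesian forecasting from prior observations; and a
    synthetic therapeutic-drug-monitoring cohort generator emulating a
    pediatric trough-concentration dataset.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
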