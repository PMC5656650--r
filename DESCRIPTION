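Package: dialmsm
Title: Marginal Structural Models for Time-Varying Treatment in Dialysis Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Longitudinal causal-inference workflow for the effect of a
    time-varying binary treatment (xanthine oxidoreductase inhibitors) on
    mortality and cardiovascular events in haemodialysis cohorts observed at
    monthly visits. Provides a long-format person-visit data model with
    last-observation-carried-forward imputation and baseline uric-acid
    quintile stratification; a synthetic cohort generator with
    treatment-confounder feedback and a counterfactual ground-truth oracle;
    from-first-principles estimation primitives (weighted logistic regression
    by iteratively reweighted least squares with cluster-robust sandwich
    variance, Cox proportional hazards with Breslow ties and robust standard
    errors, Kaplan-Meier curves, k-group log-rank tests); cumulative
    stabilized inverse-probability-of-treatment weights with percentile
    truncation and diagnostics; and discrete-time pooled-logistic marginal
    structural models with quintile subgroup and truncation sensitivity
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    withr
Config/testthat/edition: 3
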