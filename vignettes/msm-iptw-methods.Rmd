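---
title: "Stabilized IPTW and marginal structural models for dialysis cohorts: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stabilized IPTW and marginal structural models for dialysis cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The estimation problem

In maintenance haemodialysis, urate-lowering drugs (xanthine
oxidoreductase inhibitors) are prescribed month by month in response to a
patient's recent labs — above all serum uric acid (UA) — while the drug
itself lowers UA and low UA is associated with death. Treatment at month
*t* therefore depends on a covariate that earlier treatment changed, and
that covariate predicts the outcome: *treatment–confounder feedback*.
Conditioning on the time-varying confounder in an outcome regression
blocks part of the treatment effect (UA is a mediator of past treatment);
not conditioning leaves confounding. Inverse-probability-of-treatment
weighting breaks the feedback instead: each person-visit is weighted by
the inverse probability of the treatment actually received, producing a
pseudo-population in which treatment is independent of the measured
history, and a simple "marginal structural" outcome model on that
pseudo-population has a causal interpretation.

## The data model

The single currency of the package is the `cohort_panel`: a baseline
table (demographics, entry treatment status, entry labs, optional
comorbidity flags) plus a long person-visit table on a fixed monthly grid
1..T (default T = 36). Follow-up rows stop at the first death or
administrative censoring; a first cardiovascular (CVD) event is recorded
without terminating follow-up, and CVD fits restrict each patient's rows
to the first event. Missing lab values are imputed by last observation
carried forward (`locf_impute()`); leading gaps are back-filled from the
first observed value so that every retained row is complete — back-fill
is only reachable on synthetic data, because baseline completeness is an
entry criterion in the registries this emulates. Patients for whom a
requested lab is never observed are dropped and reported, mirroring the
usual exclusion flow. LOCF is idempotent and both properties are tested.

Baseline UA quintiles (`assign_ua_quintiles()`) are rank-based with a
deterministic tie rule — tied boundary values all take the lower quintile
— which makes the assignment invariant to monotone transforms of the UA
scale and reproducible without randomness.

## Estimation primitives

The statistical primitives are implemented from first principles and
cross-checked against independent references in the test suite:

* `fit_logistic()`: weighted logistic regression by IRLS (tolerance 1e-8
  on the maximum coefficient change, 100 iterations maximum). Separation
  is flagged when a non-constant column's coefficient passes 50 — the
  intercept is exempt because it absorbs covariate means on raw scales.
  The robust covariance is the cluster sandwich: bread = inverse weighted
  information, meat = outer product of cluster-summed weighted scores.
  With one cluster per row it reduces to the HC0 sandwich (tested).
* `fit_cox()`: Breslow-ties partial likelihood by Newton–Raphson with
  step halving; robust covariance from score residuals summed within
  cluster (the grouped dfbeta form). Breslow is used because it is the
  default of the software environment classically used for such
  registry analyses. Efron/exact ties and time-varying-covariate Cox are
  out of scope: the Cox arm here is baseline-only.
* `km_estimate()` / `logrank_test()`: product-limit curves (censored
  subjects at t stay in the risk set at t) and the k-group log-rank
  statistic from hypergeometric moments, on k−1 degrees of freedom.

All p-values are two-sided; chi-square reference distributions are used
throughout. Cluster-robust inference for the pooled logistic models is
clustered by patient, the statistically correct reading of "robust SE"
when a patient contributes up to 36 rows.

## Weights

The denominator model is one pooled logistic fit across all person-visits
(not 36 separate per-visit fits): current treatment on previous
treatment, previous-visit labs (lag 1; baseline values stand in at visit
1) and baseline covariates. Pooling is the standard practice and is
stable at moderate n. The numerator model drops the time-varying labs.
Visit-level factors (1/p or 1/(1−p); p or 1−p) are cumulated
multiplicatively over each patient's visits — in log space, for numerical
safety — and their product is the stabilized weight. Predictions are
clamped to [1e-10, 1−1e-10] with a warning before inversion; an exactly
0/1 probability is an error (infinite weight). Weights exist only while
the patient is at risk; there are no rows after death or censoring, and
no inverse-probability-of-censoring weights are used (dropout is
simulated as independent, and the absence of IPCW is a deliberate
fidelity choice, flagged here).

Truncation (`truncate_weights()`) computes mirrored percentile bounds —
the (100−p)th and p-th percentiles of the *pooled* person-visit weights,
matching the convention of reporting single global bounds such as
(0.69–1.94) at p = 95 — and resets weights outside them. It is monotone,
idempotent, and `"none"` is the identity. With T = 1 the stabilized
weight reduces exactly to the classic point-treatment weight, which the
tests verify against an independently coded stabilized-PS analysis.

## The outcome model and its covariates

The MSM is a weighted pooled logistic regression of the per-month event
on an intercept, *current* treatment and time terms (month, or
month + month² + month³ when events are few, as in the per-quintile
fits), with patient-clustered robust SEs; `exp(coef)` is the
discrete-time hazard ratio and Wald 95% intervals use ±1.96 robust SE.
Current-visit treatment (rather than cumulative exposure) is the exposure
definition; with highly persistent prescriptions the two nearly coincide.

One design question was genuinely open: whether the outcome model should
adjust for covariates beyond treatment and time. Because the stabilized
numerator conditions on the baseline covariates, their confounding is
*not* removed by the weights and must be adjusted in the outcome model;
this includes the baseline labs (entry UA and albumin), through which
pre-cohort prescription selection operates — a pathway no visit-level
weight can reweight because there is no visit-0 weight. We therefore
default `adjust_baseline = TRUE` for weighted fits, with the adjustment
set equal to the numerator's baseline covariates. We deliberately do
*not* adjust for baseline treatment status itself: it is nearly collinear
with current treatment under persistent prescribing, and in calibration
runs conditioning on it doubled the estimator's standard deviation while
the baseline labs already block the selection path. The naive comparator
(`weight_source = "none"`) is fitted crude — unweighted and unadjusted —
because it stands for the analysis a practitioner would run without
g-methods. Subgroup (quintile) fits reuse the all-cohort weights.

## The synthetic cohort and what it emulates

No registry data ship with the package; `generate_cohort()` emulates the
study design instead. Baseline marginals echo a large Japanese dialysis
cohort: age 67.3 ± 12.4, 66.4% male, BMI 21.8 ± 3.8, 40.7% diabetic,
UA 7.3 ± 1.3 mg/dL, ~19–23% treated at baseline with prevalence falling
across UA quintiles (~32% in Q1 to ~13% in Q5), ~17–20% mortality and
~9–10% administrative dropout over follow-up, and ~8% per-lab visit
missingness.

Each lab is modelled as a persistent patient-level set-point plus a fast
stationary AR(1) deviation (`between_frac`, default half the variance,
preserving the printed cross-sectional SDs). The set-point matters: with
a plain AR(1) the confounder decorrelates from any selection event within
a few months and the naive estimate is barely biased — the workflow would
have nothing to fix. Persistent between-patient differences are also the
clinically realistic picture. Treatment follows a monthly logistic rule
(intercept ≈ −5, previous-treatment coefficient 10 — i.e. ~1% initiation
and ~0.5% discontinuation per month — and negative coefficients on
previous UA and albumin); treatment shifts UA by `ua_treatment_effect`
per treated month, accumulating to δ/(1−ρ) ≈ −1.2 mg/dL at steady state;
death and first-CVD events are monthly Bernoulli hazards on current
treatment, UA and albumin. Discrete-time hazards are used deliberately so
the estimand and the estimator live on the same monthly time scale.

Counterfactual arms (`generate_counterfactual_arms()`) share every random
draw with each other (common random numbers) and differ only in the
forced treatment path; dropout and missingness are disabled there. The
oracle (`oracle_marginal_hr()`) stacks always-treated and never-treated
arms at large n — simulated in memory-bounded chunks and aggregated to
(arm, month) event counts, which gives the exact same maximum-likelihood
fit as row-level stacking — and reads off the arm coefficient of an
unweighted pooled logistic model: the true marginal hazard ratio.

Three named fixtures define the study conditions:

* **null** — treatment causally inert (no effect on UA or either hazard)
  under confounded assignment; true HR exactly 1. Its per-month death
  intercept (−4.03) makes cumulative mortality over its 12-visit design
  match the ~19–20% follow-up mortality being emulated, and missingness
  is disabled because this fixture tests estimator calibration, not
  imputation.
* **recovery-A** — moderate feedback; the direct effect (−1.1 on the
  logit) was calibrated once against the oracle at n = 2×10⁵ so the true
  marginal HR is ≈ 0.495 (recorded in the fixture file).
* **feedback-strong** — aggressive selection and lab dependence (direct
  effect −1.37, oracle ≈ 0.505); the condition under which the naive
  regression is most biased (~+0.33 on the log scale).

What passing tests show — and what they do not: the generator reproduces
the feedback structure, visit grid, missingness and dropout of a dialysis
registry, but real registries have non-Gaussian labs, informative
censoring, comorbidity-driven prescribing and drug dosages, none of which
are modelled. Recovery of the oracle here demonstrates the estimator is
correctly implemented and unbiased *when its models are correctly
specified*; it cannot certify unconfoundedness in real data.

## Numerical choices and problem sizes

Tolerances: IRLS 1e-8 (coefficient change), Cox 1e-8 with step halving;
weight-clamp 1e-10; quantiles are type-7. Polynomial month columns that
add no rank (short visit grids) are pruned rather than allowed to break
the fit. Degenerate descriptive cells are guarded: zero residual variance
with equal means reports F = 0, p = 1; with unequal means F = ∞, p = 0;
binary covariates use Pearson chi-square without continuity correction.
The test suite exercises the workflow at the fixtures' native sizes —
200 replications of the null design (n = 1000, 12 visits), 100 seeds of
recovery-A and 40 of feedback-strong (n = 2000, 36 visits each), with the
oracle cross-checked at n = 2×10⁴ against its stored n = 2×10⁵ reference
— sizes chosen to give Monte-Carlo error well inside the margins being
asserted. All randomness flows from a single seed per run; identical
config and seed reproduce panels, weights and report files bit for bit.

## Known limitations

Binary treatment only (no dose); first-event CVD analysis rather than
recurrent events; no inverse-probability-of-censoring weights; Breslow
ties only; quintile fits reuse all-cohort weights (a within-quintile
refit switch would be a natural extension); the naive/weighted contrast
quantifies measured-confounder feedback only.
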