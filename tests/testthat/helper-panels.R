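# Shared fixtures built in code.

# hand-built three-patient panel with a lab gap pattern for imputation tests
toy_panel <- function() {
  baseline <- data.frame(
    patient_id = c("A", "B", "C"),
    age = c(60, 70, 65), sex_male = c(1, 0, 1), bmi = c(22, 21, 23),
    diabetes = c(0, 1, 0), hd_vintage = c(10, 50, 30),
    baseline_treatment = c(1, 0, 0),
    baseline_ua = c(6.0, 7.5, 8.2), baseline_alb = c(3.5, 3.6, 3.7),
    stringsAsFactors = FALSE
  )
  visits <- data.frame(
    patient_id = rep(c("A", "B", "C"), each = 4),
    visit = rep(1:4, 3),
    treatment = c(1, 1, 1, 1, 0, 0, 1, 1, 0, 0, 0, 0),
    event_death = c(0, 0, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0),
    event_cvd = 0,
    censored = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1),
    ua = c(5.0, NA, NA, 6.0, NA, 7.0, 7.2, 7.1, 8.0, 8.1, 7.9, 8.3),
    alb = c(3.5, 3.4, 3.6, 3.5, 3.6, 3.7, 3.6, 3.5, 3.7, 3.8, 3.6, 3.7),
    stringsAsFactors = FALSE
  )
  cohort_panel(baseline, visits)
}

# small generated cohort for structural tests
small_cohort <- function(seed = 42, n = 150, T = 6, ...) {
  generate_cohort(dgp_config(n_patients = n, n_visits = T, seed = seed, ...))
}

# weight set built directly from prediction tables (bypasses model fitting)
manual_weight_set <- function(pred, spec = propensity_spec()) {
  mk <- function(col) list(
    predictions = data.frame(patient_id = pred$patient_id,
                             visit = pred$visit,
                             treatment = pred$treatment,
                             ps_pred = pred[[col]],
                             stringsAsFactors = FALSE),
    spec = spec
  )
  compute_stabilized_weights(NULL, mk("p_den"), mk("p_num"))
}
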