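# Causally inert treatment under confounded assignment: prescription still
# follows previous treatment / uric acid / albumin, but treatment affects
# neither uric acid nor either outcome hazard, so the true marginal hazard
# ratio is exactly 1. The monthly death intercept is set so that cumulative
# mortality over the 12-visit design matches the ~19-20% follow-up mortality
# the generator emulates. Lab missingness is disabled: this fixture exists
# to check estimator calibration (bias and CI coverage), not imputation.
n_patients: 1000
n_visits: 12
seed: 1
treat_coefs:
  intercept: -4.8
  prev_treatment: 10.0
  prev_ua_z: -0.8
  prev_alb_z: -0.3
ua_treatment_effect: 0.0
outcome_death:
  intercept: -4.03
  treatment: 0.0
  ua_z: -0.35
  alb_z: -0.3
outcome_cvd:
  intercept: -3.5
  treatment: 0.0
  ua_z: -0.2
  alb_z: -0.2
dropout_hazard: 0.003
missing_rate: 0.0
oracle_hr: 1.0
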