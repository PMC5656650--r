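# Strong treatment-confounder feedback: aggressive selection on previous
# uric acid and albumin, a larger treatment effect on uric acid and steeper
# outcome dependence on both labs — the condition under which the naive
# regression is most biased. Direct effect (treatment: -1.37) calibrated for
# an oracle hazard ratio of ~0.5; oracle_hr is the reference value computed
# once at n = 200000 per arm (seed 101).
n_patients: 2000
n_visits: 36
seed: 1
baseline:
  treat_ua: -0.6
treat_coefs:
  intercept: -4.8
  prev_treatment: 10.0
  prev_ua_z: -1.2
  prev_alb_z: -0.5
ua_treatment_effect: -0.5
outcome_death:
  intercept: -5.15
  treatment: -1.37
  ua_z: -0.55
  alb_z: -0.4
outcome_cvd:
  intercept: -4.6
  treatment: -0.1
  ua_z: -0.3
  alb_z: -0.3
dropout_hazard: 0.003
missing_rate: 0.08
oracle_hr: 0.505278
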