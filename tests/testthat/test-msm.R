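# weights aligned to a generated panel, for reuse across blocks
.msm_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- dgp_fixture("recovery-A", n_patients = 600, n_visits = 12,
                         seed = 303)
      panel <- locf_impute(generate_cohort(cfg), quiet = TRUE)
      w <- compute_stabilized_weights(panel, fit_denominator_model(panel),
                                      fit_numerator_model(panel))
      cache <<- list(panel = panel, w = w)
    }
    cache
  }
})

test_that("scaling all weights by a constant leaves the point estimate unchanged", {
  fx <- .msm_fixture()
  est1 <- fit_msm(fx$panel, fx$w, outcome_spec())
  w_scaled <- fx$w
  w_scaled$stabilized_weight <- 7 * w_scaled$stabilized_weight
  est2 <- fit_msm(fx$panel, w_scaled, outcome_spec())
  expect_equal(est2$log_hr, est1$log_hr, tolerance = 1e-8)
  expect_equal(est1$ci_lower, exp(est1$log_hr - 1.96 * est1$robust_se))
  expect_equal(est1$ci_upper, exp(est1$log_hr + 1.96 * est1$robust_se))
  expect_true(est1$ci_lower < est1$hr && est1$hr < est1$ci_upper)
})

test_that("with a single visit the MSM equals an independently coded stabilized-PS fit", {
  cfg <- dgp_fixture("recovery-A", n_patients = 800, n_visits = 1,
                     seed = 71)
  cfg$outcome_death["intercept"] <- -2.5   # enough events in one interval
  # moderate persistence so previous treatment cannot separate in one visit
  cfg$treat_coefs[c("intercept", "prev_treatment")] <- c(-1.5, 2)
  panel <- locf_impute(generate_cohort(cfg), quiet = TRUE)
  # lagged labs coincide with baseline labs at T = 1: keep them out of the
  # baseline covariate list
  spec <- propensity_spec(baseline = c("age", "sex_male", "bmi", "diabetes",
                                       "hd_vintage"))
  den <- fit_denominator_model(panel, spec)
  num <- fit_numerator_model(panel, spec)
  w <- compute_stabilized_weights(panel, den, num)
  est <- fit_msm(panel, w, outcome_spec(adjust_baseline = FALSE),
                 quintiles = NULL)

  # independent route: glm propensity fits, textbook point-treatment weight,
  # weighted glm outcome model
  b <- panel$baseline
  v <- panel$visits
  bl <- b[match(v$patient_id, b$patient_id), ]
  dd <- data.frame(a = v$treatment, prev = bl$baseline_treatment,
                   bl[, spec$baseline],
                   setNames(bl[, paste0("baseline_", spec$time_dependent)],
                            paste0("prev_", spec$time_dependent)))
  pd <- fitted(glm(a ~ ., data = dd, family = binomial,
                   control = glm.control(epsilon = 1e-14, maxit = 100)))
  pn <- fitted(glm(a ~ . , data = dd[, c("a", "prev", spec$baseline)],
                   family = binomial,
                   control = glm.control(epsilon = 1e-14, maxit = 100)))
  sw <- ifelse(dd$a == 1, pn / pd, (1 - pn) / (1 - pd))
  ref <- suppressWarnings(
    glm(v$event_death ~ v$treatment, family = quasibinomial, weights = sw,
        control = glm.control(epsilon = 1e-14, maxit = 100)))
  expect_equal(est$log_hr, unname(coef(ref)[2]), tolerance = 1e-8)
})

test_that("without confounding the naive and weighted estimates coincide up to noise", {
  cfg <- dgp_config(
    n_patients = 1500, n_visits = 10, seed = 23,
    treat_coefs = c(intercept = -1.5, prev_treatment = 2, prev_ua_z = 0,
                    prev_alb_z = 0),
    baseline = list(treat_intercept = -1.5, treat_ua = 0),
    ua_treatment_effect = 0,
    outcome_death = c(intercept = -4, treatment = -0.5, ua_z = 0, alb_z = 0),
    missing_rate = 0
  )
  panel <- generate_cohort(cfg)
  w <- compute_stabilized_weights(panel, fit_denominator_model(panel),
                                  fit_numerator_model(panel))
  est_w <- fit_msm(panel, w, outcome_spec(adjust_baseline = FALSE))
  est_n <- fit_msm(panel, NULL, outcome_spec(weight_source = "none"))
  expect_lt(abs(est_w$log_hr - est_n$log_hr), 0.05)
  # weights themselves are concentrated near one
  expect_lt(abs(mean(w$stabilized_weight) - 1), 0.05)
})

test_that("zero-event fits and subgroup bookkeeping fail informatively", {
  fx <- .msm_fixture()
  p0 <- fx$panel
  p0$visits$event_death <- 0
  expect_error(fit_msm(p0, fx$w, outcome_spec()), "zero events")
  expect_error(fit_msm(fx$panel, fx$w, outcome_spec(subgroup = 2)),
               "quintile assignment")
  expect_error(fit_msm(fx$panel, NULL, outcome_spec()), "weights required")
  expect_error(outcome_spec(subgroup = 9), "quintile")
})

test_that("quintile batches collect per-quintile failures instead of aborting", {
  fx <- .msm_fixture()
  q <- assign_ua_quintiles(fx$panel)
  # erase all deaths in quintile 3 so exactly that slot errors
  p <- fx$panel
  kill <- names(q)[q == 3]
  p$visits$event_death[as.character(p$visits$patient_id) %in% kill] <- 0
  res <- run_quintile_analysis(p, fx$w, outcome_spec(), quintiles = q)
  expect_s3_class(res[["quintile_3"]], "msm_error")
  ok <- vapply(res, inherits, logical(1), "effect_estimate")
  expect_true(any(ok))
  for (f in res[ok]) expect_equal(f$spec$time_terms, "cubic")
})

test_that("truncation sensitivity: degenerate weights give identical rows, extreme weights shrink the SE", {
  # all stabilized weights exactly one: the three rows must agree
  fx <- .msm_fixture()
  w1 <- fx$w
  w1$stabilized_weight <- rep(1, nrow(w1))
  tab1 <- sensitivity_truncation(fx$panel, w1, outcome_spec())
  expect_equal(tab1$hr[2], tab1$hr[1], tolerance = 1e-10)
  expect_equal(tab1$hr[3], tab1$hr[1], tolerance = 1e-10)

  # inject extreme weights on event rows: truncated fits are no noisier
  w2 <- fx$w
  v <- fx$panel$visits
  ev_keys <- paste(v$patient_id, v$visit)[v$event_death == 1]
  big <- which(paste(w2$patient_id, w2$visit) %in% ev_keys)[1:6]
  w2$stabilized_weight[big] <- w2$stabilized_weight[big] * 40
  tab2 <- sensitivity_truncation(fx$panel, w2, outcome_spec())
  expect_lte(tab2$robust_se[tab2$weight_source == "truncated-95"],
             tab2$robust_se[tab2$weight_source == "stabilized"])
  expect_lte(tab2$robust_se[tab2$weight_source == "truncated-99"],
             tab2$robust_se[tab2$weight_source == "stabilized"])
})
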