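test_that("visit-1 designs use baseline stand-ins and risk sets shrink after events", {
  panel <- locf_impute(toy_panel(), quiet = TRUE)
  spec <- propensity_spec(time_dependent = c("ua", "alb"),
                          baseline = c("age", "baseline_ua"))
  d1 <- build_design(panel, spec, visit = 1)
  b <- panel$baseline[match(d1$patient_id, panel$baseline$patient_id), ]
  expect_equal(d1$prev_treatment, b$baseline_treatment)
  expect_equal(d1$prev_ua, b$baseline_ua)

  # patient B dies at visit 4, patient C is censored after visit 4:
  # both still appear at visit 4, none at visit 5
  d4 <- build_design(panel, spec, visit = 4)
  expect_setequal(d4$patient_id, c("A", "B", "C"))
  # lagged values at visit 2 are the visit-1 observations
  d2 <- build_design(panel, spec, visit = 2)
  v1 <- panel$visits[panel$visits$visit == 1, ]
  expect_equal(d2$prev_ua, v1$ua[match(d2$patient_id, v1$patient_id)])
  expect_error(build_design(panel, propensity_spec(time_dependent = "nope"),
                            1), "absent")
})

test_that("a constant lab yields an identical lagged column at every visit", {
  panel <- small_cohort(seed = 14, n = 60, T = 4, missing_rate = 0)
  panel$visits$ktv <- 1.4
  panel$baseline$baseline_ktv <- 1.4
  spec <- propensity_spec(time_dependent = "ua", baseline = "age")
  spec2 <- propensity_spec(time_dependent = c("ua", "ktv"),
                           baseline = "age")
  for (v in 1:4) {
    d <- build_design(panel, spec2, v)
    expect_true(all(d$prev_ktv == 1.4))
  }
})

test_that("the two-visit arithmetic example gives a stabilized weight of 0.64", {
  pred <- data.frame(patient_id = "P1", visit = 1:2, treatment = 1,
                     p_den = c(0.5, 0.25), p_num = c(0.4, 0.2))
  w <- manual_weight_set(pred)
  expect_equal(w$cumulative_denominator_inverse, c(2, 8))
  expect_equal(w$cumulative_numerator, c(0.4, 0.08))
  expect_equal(w$stabilized_weight[2], 0.64, tolerance = 1e-12)
})

test_that("identical numerator and denominator predictions cancel to weight one", {
  set.seed(15)
  pred <- data.frame(
    patient_id = rep(sprintf("P%02d", 1:10), each = 5),
    visit = rep(1:5, 10),
    treatment = rbinom(50, 1, 0.4),
    p_den = runif(50, 0.1, 0.9)
  )
  pred$p_num <- pred$p_den
  w <- manual_weight_set(pred)
  expect_equal(w$stabilized_weight, rep(1, 50), tolerance = 1e-12)
})

test_that("exact 0/1 predictions are refused (infinite weights)", {
  pred <- data.frame(patient_id = "P1", visit = 1:2, treatment = 1,
                     p_den = c(0.5, 1), p_num = c(0.5, 0.5))
  expect_error(manual_weight_set(pred), "strictly inside")
})

test_that("truncation resets weights to the published-style bounds and is idempotent, monotone and optional", {
  set.seed(16)
  pred <- data.frame(
    patient_id = rep(sprintf("P%02d", 1:40), each = 3),
    visit = rep(1:3, 40), treatment = rbinom(120, 1, 0.3),
    p_den = runif(120, 0.05, 0.95), p_num = runif(120, 0.2, 0.8)
  )
  w <- manual_weight_set(pred)

  # explicit bounds as printed in a weight-truncation report
  wt <- truncate_weights(w, bounds = c(0.26, 3.62))
  expect_equal(wt$truncated_weight[which.max(w$stabilized_weight)],
               min(max(w$stabilized_weight), 3.62))
  w2 <- w
  w2$stabilized_weight[1] <- 21.95
  w2$stabilized_weight[2] <- 0.0089
  wt2 <- truncate_weights(w2, bounds = c(0.26, 3.62))
  expect_equal(wt2$truncated_weight[1], 3.62)
  expect_equal(wt2$truncated_weight[2], 0.26)

  # percentile bounds: mirrored (100-p)/p percentiles of the pooled weights
  wt95 <- truncate_weights(w, percentile = 95)
  tr <- attr(wt95, "truncation")
  expect_equal(tr$lower, unname(quantile(w$stabilized_weight, 0.05)))
  expect_equal(tr$upper, unname(quantile(w$stabilized_weight, 0.95)))
  # idempotent
  wt95b <- truncate_weights(wt95, percentile = 95)
  expect_equal(wt95b$truncated_weight, wt95$truncated_weight)
  # monotone: ordering preserved
  expect_true(all(diff(wt95$truncated_weight[order(w$stabilized_weight)])
                  >= 0))
  # "none" is the identity
  wnone <- truncate_weights(w, percentile = "none")
  expect_equal(wnone$truncated_weight, w$stabilized_weight)
  # all weights already inside the bounds: output equals input
  win <- truncate_weights(w, bounds = range(w$stabilized_weight) + c(-1, 1))
  expect_equal(win$truncated_weight, w$stabilized_weight)
  expect_error(truncate_weights(w, percentile = 80), "95")
})

test_that("weight diagnostics summarise the pooled person-visit weights", {
  pred1 <- data.frame(patient_id = "P1", visit = 1, treatment = 1,
                      p_den = 0.5, p_num = 0.5)
  d1 <- weight_diagnostics(manual_weight_set(pred1))
  expect_equal(d1$mean, 1)
  expect_equal(d1$sd, 0)
  expect_equal(d1$percentile_95, 1)
  expect_equal(d1$percentile_99, 1)

  w <- manual_weight_set(data.frame(
    patient_id = sprintf("P%d", 1:4), visit = 1, treatment = 1,
    p_den = 0.8 / (1:4), p_num = rep(0.8, 4)))
  # stabilized weights (1, 2, 3, 4)
  d <- weight_diagnostics(w)
  expect_equal(d$mean, 2.5, tolerance = 1e-6)
  expect_equal(d$min, 1, tolerance = 1e-6)
  expect_equal(d$max, 4, tolerance = 1e-6)
})

test_that("numerator designs are strict column subsets of denominator designs", {
  panel <- locf_impute(small_cohort(seed = 17, n = 200, T = 5,
                                    missing_rate = 0.05), quiet = TRUE)
  spec <- propensity_spec()
  den <- fit_denominator_model(panel, spec)
  num <- fit_numerator_model(panel, spec)
  expect_gt(length(den$fit$coefficients), length(num$fit$coefficients))
  expect_setequal(
    setdiff(names(den$fit$coefficients), names(num$fit$coefficients)),
    paste0("prev_", spec$time_dependent)
  )
  # with no time-dependent covariates the two fits coincide
  spec0 <- propensity_spec(time_dependent = character(0))
  d0 <- fit_denominator_model(panel, spec0)
  n0 <- fit_numerator_model(panel, spec0)
  expect_equal(d0$fit$coefficients, n0$fit$coefficients, tolerance = 1e-10)
  expect_equal(d0$predictions$ps_pred, n0$predictions$ps_pred,
               tolerance = 1e-10)
})

test_that("under random assignment the propensity model finds nothing", {
  cfg <- dgp_config(
    n_patients = 1500, n_visits = 6, seed = 18,
    treat_coefs = c(intercept = 0, prev_treatment = 0, prev_ua_z = 0,
                    prev_alb_z = 0),
    missing_rate = 0,
    baseline = list(treat_intercept = 0, treat_ua = 0)
  )
  panel <- generate_cohort(cfg)
  den <- fit_denominator_model(panel)
  expect_true(all(abs(den$predictions$ps_pred - 0.5) < 0.1))
  # previous-treatment coefficient is near zero under random assignment
  expect_lt(abs(den$fit$coefficients["prev_treatment"]), 0.3)
})

test_that("deterministic treatment continuation raises a separation error", {
  panel <- small_cohort(seed = 19, n = 40, T = 4, missing_rate = 0)
  # overwrite: treatment always equals baseline status
  b <- panel$baseline
  panel$visits$treatment <-
    b$baseline_treatment[match(panel$visits$patient_id, b$patient_id)]
  if (sum(b$baseline_treatment) %in% c(0, nrow(b))) {
    b$baseline_treatment[1] <- 1 - b$baseline_treatment[1]
  }
  expect_error(fit_denominator_model(panel), "separation")
})

test_that("with one visit the stabilized weight is the classic point-treatment weight", {
  # moderate persistence: at a single visit an extreme continuation rate
  # would make previous treatment a perfect (separating) predictor
  panel <- locf_impute(small_cohort(
    seed = 20, n = 400, T = 1, missing_rate = 0,
    treat_coefs = c(intercept = -1.5, prev_treatment = 2, prev_ua_z = -0.5,
                    prev_alb_z = -0.2)), quiet = TRUE)
  # at a single visit the lagged labs ARE the baseline labs, so the baseline
  # covariate list must not duplicate them
  spec <- propensity_spec(baseline = c("age", "sex_male", "bmi", "diabetes",
                                       "hd_vintage"))
  den <- fit_denominator_model(panel, spec)
  num <- fit_numerator_model(panel, spec)
  w <- compute_stabilized_weights(panel, den, num)
  a <- w$treatment
  pd <- w$ps_pred_denominator
  pn <- w$ps_pred_numerator
  manual <- ifelse(a == 1, pn / pd, (1 - pn) / (1 - pd))
  expect_equal(w$stabilized_weight, manual, tolerance = 1e-12)
})

test_that("weight diagnostics on the recovery fixture are reproducible at a fixed seed", {
  cfg <- dgp_fixture("recovery-A", n_patients = 400, n_visits = 12,
                     seed = 2024)
  panel <- locf_impute(generate_cohort(cfg), quiet = TRUE)
  w <- compute_stabilized_weights(panel, fit_denominator_model(panel),
                                  fit_numerator_model(panel))
  d <- weight_diagnostics(w)
  # regression lock: values recorded from the first verified run
  expect_equal(d$n_person_visits, 4539)
  expect_equal(d$mean, 0.99130753, tolerance = 1e-6)
  expect_equal(d$sd, 0.12253499, tolerance = 1e-6)
  expect_equal(d$percentile_95, 1.06327282, tolerance = 1e-6)
  expect_equal(d$percentile_99, 1.25630115, tolerance = 1e-6)
})
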