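test_that("CSV round trip reproduces a generated panel and a tiny literal one", {
  panel <- small_cohort(seed = 11, missing_rate = 0.1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel(panel, path)
  back <- read_panel(path, quiet = TRUE)
  expect_equal(back$baseline, panel$baseline, tolerance = 1e-12)
  expect_equal(back$visits, panel$visits, tolerance = 1e-12)
  expect_identical(back$n_visits, panel$n_visits)

  # one patient, visits 1..3, written by hand
  tiny <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "patient_id,age,sex_male,bmi,diabetes,hd_vintage,baseline_treatment,baseline_ua,visit,treatment,event_death,event_cvd,censored,ua",
    "P1,61,1,22.5,0,24,0,7.1,1,0,0,0,0,7.0",
    "P1,61,1,22.5,0,24,0,7.1,2,1,0,0,0,6.5",
    "P1,61,1,22.5,0,24,0,7.1,3,1,1,0,0,6.1"
  ), tiny)
  p <- read_panel(tiny, quiet = TRUE)
  expect_equal(nrow(p$baseline), 1L)
  expect_equal(nrow(p$visits), 3L)
  expect_identical(panel_labs(p), "ua")
})

test_that("validation rejects visit gaps, orphans and double event flags", {
  tiny <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "patient_id,age,baseline_ua,visit,treatment,event_death,event_cvd,censored,ua",
    "P1,61,7.1,1,0,0,0,0,7.0",
    "P1,61,7.1,3,1,0,0,0,6.5"
  ), tiny)
  expect_error(read_panel(tiny, quiet = TRUE), "non-consecutive.*P1")

  p <- toy_panel()
  bad <- p$visits
  bad$event_death[4] <- 1
  bad$censored[4] <- 1
  expect_error(cohort_panel(p$baseline, bad), "event_death and censored")
  expect_error(cohort_panel(p$baseline[-1, ], p$visits),
               "absent from baseline")
})

test_that("read_panel names missing required columns and applies a schema", {
  tiny <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,visit,treatment,event_death,censored",
               "P1,1,0,0,0"), tiny)
  expect_error(read_panel(tiny, quiet = TRUE), "event_cvd")

  renamed <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "id,month,xori,died,cvd,cens,ua",
    "P1,1,0,0,0,0,7.0"
  ), renamed)
  p <- read_panel(renamed, quiet = TRUE,
                  schema = c(patient_id = "id", visit = "month",
                             treatment = "xori", event_death = "died",
                             event_cvd = "cvd", censored = "cens"))
  expect_equal(p$visits$visit, 1)
  expect_error(
    read_panel(renamed, quiet = TRUE, schema = c(patient_id = "nope")),
    "missing file column 'nope'")
})

test_that("writing an empty cohort yields a header-only re-readable CSV", {
  p <- toy_panel()
  empty <- cohort_panel(p$baseline[0, ], p$visits[0, ], n_visits = 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel(empty, path)
  expect_length(readLines(path), 1L)
  back <- read_panel(path, quiet = TRUE)
  expect_equal(nrow(back$visits), 0L)
})

test_that("LOCF forward-fills, back-fills leading gaps and is idempotent", {
  p <- locf_impute(toy_panel(), quiet = TRUE)
  # (5.0, NA, NA, 6.0) -> (5.0, 5.0, 5.0, 6.0)
  expect_equal(p$visits$ua[p$visits$patient_id == "A"], c(5, 5, 5, 6))
  # leading missing back-filled from the first observed value
  expect_equal(p$visits$ua[p$visits$patient_id == "B"][1:2], c(7, 7))
  p2 <- locf_impute(p, quiet = TRUE)
  expect_identical(p2$visits, p$visits)

  gen <- small_cohort(seed = 5, missing_rate = 0.3)
  g1 <- locf_impute(gen, quiet = TRUE)
  g2 <- locf_impute(g1, quiet = TRUE)
  expect_identical(g1$visits, g2$visits)
  expect_false(anyNA(g1$visits[, panel_labs(g1)]))
})

test_that("patients with a lab never observed are dropped, named labs checked", {
  p <- toy_panel()
  p$visits$ua[p$visits$patient_id == "C"] <- NA
  expect_message(out <- locf_impute(p, lab_names = "ua"), "dropping 1")
  expect_equal(sort(as.character(out$baseline$patient_id)), c("A", "B"))
  expect_equal(sum(out$visits$patient_id == "C"), 0L)
  expect_error(locf_impute(p, lab_names = "nope"), "nope")
})

test_that("quintile assignment splits ranks, sends boundary ties down, and is monotone-invariant", {
  mk <- function(ua) {
    n <- length(ua)
    cohort_panel(
      data.frame(patient_id = sprintf("P%02d", seq_len(n)),
                 baseline_ua = ua),
      data.frame(patient_id = sprintf("P%02d", seq_len(n)), visit = 1,
                 treatment = 0, event_death = 0, event_cvd = 0,
                 censored = 0)
    )
  }
  q <- assign_ua_quintiles(mk(10:1))  # values 10..1 for P01..P10
  expect_equal(unname(q[c("P10", "P09")]), c(1L, 1L))
  expect_equal(unname(q[c("P01", "P02")]), c(5L, 5L))

  expect_equal(unique(unname(assign_ua_quintiles(mk(rep(7, 10))))), 1L)

  set.seed(9)
  ua <- rnorm(103, 7.3, 1.3)
  q1 <- assign_ua_quintiles(mk(ua))
  q2 <- assign_ua_quintiles(mk(exp(ua / 2)))  # strictly monotone transform
  expect_identical(q1, q2)

  expect_error(assign_ua_quintiles(mk(c(1, 2, 3, 4))), "at least 5")
})

test_that("per-quintile mean uric acid increases strictly from Q1 to Q5", {
  set.seed(31)
  n <- 400
  panel <- cohort_panel(
    data.frame(patient_id = sprintf("P%03d", 1:n),
               baseline_ua = rnorm(n, 7.3, 1.3)),
    data.frame(patient_id = sprintf("P%03d", 1:n), visit = 1, treatment = 0,
               event_death = 0, event_cvd = 0, censored = 0)
  )
  q <- assign_ua_quintiles(panel)
  means <- tapply(panel$baseline$baseline_ua,
                  q[as.character(panel$baseline$patient_id)], mean)
  expect_true(all(diff(means) > 0))
})
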