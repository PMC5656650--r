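# Synthetic longitudinal cohort generator with treatment-confounder
# feedback, plus a counterfactual ground-truth oracle for the marginal
# hazard ratio of sustained treatment.
#
# Causal structure per month t:
#   A_t  ~ Bernoulli(logit^-1(th0 + th1 A_{t-1} + th2 z(UA_{t-1}) + th3 z(Alb_{t-1})))
#   labs follow stationary AR(1); treatment shifts uric acid by `ua_treatment_effect`
#   death_t ~ Bernoulli(logit^-1(b0 + gamma A_t + b_ua z(UA_t) + b_alb z(Alb_t)))
#   first CVD event uses a parallel channel with its own coefficients
#   dropout is an independent Bernoulli censoring hazard
# so past treatment affects a lab (uric acid) that affects both future
# treatment and the outcome: the feedback a marginal structural model exists
# to handle.

# Each lab is a patient-level set-point plus a stationary AR(1) deviation:
#   value_it = mean + b_i + d_it,  b_i ~ N(0, sd^2 * between_frac),
#   d_it = rho d_i,t-1 + innovation,  Var(d) = sd^2 * (1 - between_frac),
# so the printed cross-sectional SD is preserved while between-patient
# differences persist over the whole follow-up (the component treatment
# selection can keep acting on) and month-to-month fluctuation stays fast.
.DEFAULT_LABS <- data.frame(
  name = c("ua", "alb", "npcr", "cgr", "ferritin", "sodium", "ktv"),
  mean = c(7.3, 3.6, 0.87, 91.5, 96.9, 137.9, 1.4),
  sd = c(1.3, 0.4, 0.17, 26.8, 113.5, 2.1, 0.3),
  rho = c(0.7, 0.7, 0.7, 0.7, 0.7, 0.7, 0.7),
  between_frac = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
  stringsAsFactors = FALSE
)

#' Configure the synthetic data-generating process
#'
#' Defaults echo a large Japanese haemodialysis cohort: ~2400 patients
#' followed over 36 monthly visits, mean age 67.3 (SD 12.4), 66.4% male,
#' BMI 21.8 (3.8), 40.7% diabetic, baseline uric acid 7.3 (1.3) mg/dL,
#' ~19% treated with a urate-lowering (xanthine oxidoreductase inhibiting)
#' drug at baseline with prevalence decreasing across uric-acid quintiles,
#' ~19% three-year mortality and ~10% administrative dropout.
#'
#' @param n_patients cohort size.
#' @param n_visits number of monthly visits (study design length).
#' @param seed RNG seed; same config + seed gives a bit-identical panel.
#' @param baseline list of baseline marginals and the baseline prescription
#'   model: `age_mean`, `age_sd`, `male_p`, `bmi_mean`, `bmi_sd`,
#'   `diabetes_p`, `vintage_mean`, `vintage_sd` (gamma-distributed dialysis
#'   vintage, months), `treat_intercept`, `treat_ua` (logit-scale intercept
#'   and per-SD uric-acid slope of baseline treatment).
#' @param labs data.frame with columns `name`, `mean`, `sd`, `rho`,
#'   `between_frac`: stationary mean and cross-sectional SD of each
#'   time-varying lab, the AR(1) coefficient of its within-patient
#'   deviation, and the fraction of total variance held by the persistent
#'   patient-level set-point.
#' @param treat_coefs named vector, logit scale: `intercept`,
#'   `prev_treatment`, `prev_ua_z`, `prev_alb_z`.
#' @param ua_treatment_effect uric-acid shift (mg/dL) added in each treated
#'   month; the steady-state shift is `ua_treatment_effect / (1 - rho_ua)`.
#' @param outcome_death named vector, logit scale per month: `intercept`,
#'   `treatment` (the direct causal effect gamma), `ua_z`, `alb_z`.
#' @param outcome_cvd same structure for the first-CVD-event channel.
#' @param dropout_hazard per-month administrative censoring probability.
#' @param missing_rate per-lab per-visit probability that a measurement is
#'   unrecorded (applied to the observed panel only, never to the dynamics).
#' @return validated object of class `dgp_config`.
#' @export
dgp_config <- function(n_patients = 2429,
                       n_visits = 36,
                       seed = 1,
                       baseline = list(),
                       labs = .DEFAULT_LABS,
                       treat_coefs = c(intercept = -4.8, prev_treatment = 10,
                                       prev_ua_z = -0.8, prev_alb_z = -0.3),
                       ua_treatment_effect = -0.35,
                       outcome_death = c(intercept = -5.15, treatment = -0.75,
                                         ua_z = -0.35, alb_z = -0.3),
                       outcome_cvd = c(intercept = -4.6, treatment = -0.1,
                                       ua_z = -0.2, alb_z = -0.2),
                       dropout_hazard = 0.003,
                       missing_rate = 0.08) {
  bl_default <- list(age_mean = 67.3, age_sd = 12.4, male_p = 0.664,
                     bmi_mean = 21.8, bmi_sd = 3.8, diabetes_p = 0.407,
                     vintage_mean = 74.6, vintage_sd = 84.2,
                     treat_intercept = -1.27, treat_ua = -0.43)
  baseline <- utils::modifyList(bl_default, baseline)
  cfg <- structure(list(
    n_patients = as.integer(n_patients),
    n_visits = as.integer(n_visits),
    seed = as.integer(seed),
    baseline = baseline,
    labs = {
      lb <- as.data.frame(labs, stringsAsFactors = FALSE)
      if (!"between_frac" %in% names(lb)) lb$between_frac <- 0
      lb
    },
    treat_coefs = treat_coefs,
    ua_treatment_effect = ua_treatment_effect,
    outcome_death = outcome_death,
    outcome_cvd = outcome_cvd,
    dropout_hazard = dropout_hazard,
    missing_rate = missing_rate
  ), class = "dgp_config")
  validate_dgp_config(cfg)
  cfg
}

validate_dgp_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 1, cfg$n_visits >= 1)
  probs <- c(cfg$baseline$male_p, cfg$baseline$diabetes_p,
             cfg$dropout_hazard, cfg$missing_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(abs(cfg$labs$rho) >= 1)) {
    stop("lab autoregression coefficients must lie in (-1, 1)", call. = FALSE)
  }
  if (!"between_frac" %in% names(cfg$labs)) {
    stop("labs table must carry a between_frac column", call. = FALSE)
  }
  if (any(cfg$labs$between_frac < 0 | cfg$labs$between_frac >= 1)) {
    stop("between_frac must lie in [0, 1)", call. = FALSE)
  }
  needed <- c("intercept", "prev_treatment", "prev_ua_z", "prev_alb_z")
  if (!all(needed %in% names(cfg$treat_coefs))) {
    stop("treat_coefs must name: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  needed_out <- c("intercept", "treatment", "ua_z", "alb_z")
  for (nm in c("outcome_death", "outcome_cvd")) {
    if (!all(needed_out %in% names(cfg[[nm]]))) {
      stop(nm, " must name: ", paste(needed_out, collapse = ", "),
           call. = FALSE)
    }
  }
  if (!all(c("ua", "alb") %in% cfg$labs$name)) {
    stop("labs must include 'ua' and 'alb'", call. = FALSE)
  }
  invisible(TRUE)
}

#' Load a packaged DGP fixture
#'
#' Fixtures are YAML files shipped with the package defining named study
#' conditions: `"null"` (treatment causally inert, confounded assignment),
#' `"recovery-A"` (moderate treatment-confounder feedback, counterfactual
#' marginal hazard ratio ~0.5) and `"feedback-strong"` (strong feedback and
#' selection; the condition under which a naive regression is most biased).
#'
#' @param name fixture name.
#' @param n_patients,n_visits,seed optional overrides of the fixture values.
#' @return a `dgp_config`. The fixture's reference counterfactual hazard
#'   ratio (computed once by [oracle_marginal_hr()] at large n) is attached
#'   as attribute `"oracle_hr"` when recorded in the file.
#' @export
dgp_fixture <- function(name, n_patients = NULL, n_visits = NULL, seed = NULL) {
  path <- system.file("extdata", "fixtures", paste0(name, ".yaml"),
                      package = "dialmsm")
  if (!nzchar(path)) {
    stop("unknown fixture '", name, "'; packaged fixtures: ",
         paste(sub("\\.yaml$", "",
                   list.files(system.file("extdata", "fixtures",
                                          package = "dialmsm"))),
               collapse = ", "), call. = FALSE)
  }
  spec <- yaml::read_yaml(path)
  cfg <- dgp_config(
    n_patients = if (!is.null(n_patients)) n_patients else spec$n_patients,
    n_visits = if (!is.null(n_visits)) n_visits else spec$n_visits,
    seed = if (!is.null(seed)) seed else spec$seed,
    baseline = spec$baseline %||% list(),
    treat_coefs = unlist(spec$treat_coefs),
    ua_treatment_effect = spec$ua_treatment_effect,
    outcome_death = unlist(spec$outcome_death),
    outcome_cvd = unlist(spec$outcome_cvd),
    dropout_hazard = spec$dropout_hazard,
    missing_rate = spec$missing_rate
  )
  if (!is.null(spec$oracle_hr)) attr(cfg, "oracle_hr") <- spec$oracle_hr
  attr(cfg, "fixture") <- name
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Drop trailing columns that add no rank (e.g. polynomial time terms on a
# short visit grid). The first `protect` columns are never dropped.
.drop_collinear <- function(X, protect = 0L) {
  keep <- seq_len(min(protect, ncol(X)))
  for (j in setdiff(seq_len(ncol(X)), keep)) {
    cand <- c(keep, j)
    if (qr(X[, cand, drop = FALSE])$rank == length(cand)) keep <- cand
  }
  X[, keep, drop = FALSE]
}

# All random draws of a simulation, generated up front so that
# counterfactual arms can share them (common random numbers).
.sim_draws <- function(cfg) {
  n <- cfg$n_patients
  T <- cfg$n_visits
  labs <- cfg$labs
  set.seed(cfg$seed)
  bl <- cfg$baseline
  baseline <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    age = pmax(stats::rnorm(n, bl$age_mean, bl$age_sd), 18),
    sex_male = stats::rbinom(n, 1, bl$male_p),
    bmi = pmax(stats::rnorm(n, bl$bmi_mean, bl$bmi_sd), 12),
    diabetes = stats::rbinom(n, 1, bl$diabetes_p),
    hd_vintage = stats::rgamma(n,
                               shape = (bl$vintage_mean / bl$vintage_sd)^2,
                               scale = bl$vintage_sd^2 / bl$vintage_mean),
    stringsAsFactors = FALSE
  )
  anchor <- matrix(NA_real_, n, nrow(labs),
                   dimnames = list(NULL, labs$name))
  lab0 <- anchor
  for (j in seq_len(nrow(labs))) {
    bf <- labs$between_frac[j]
    anchor[, j] <- labs$mean[j] +
      stats::rnorm(n, 0, labs$sd[j] * sqrt(bf))
    lab0[, j] <- anchor[, j] +
      stats::rnorm(n, 0, labs$sd[j] * sqrt(1 - bf))
  }
  lab0[, "ua"] <- pmax(lab0[, "ua"], 0.5)     # uric acid is positive
  u_bl_treat <- stats::runif(n)
  eps <- array(stats::rnorm(n * T * nrow(labs)), dim = c(n, T, nrow(labs)),
               dimnames = list(NULL, NULL, labs$name))
  list(
    baseline = baseline, anchor = anchor, lab0 = lab0,
    u_bl_treat = u_bl_treat, eps = eps,
    u_treat = matrix(stats::runif(n * T), n, T),
    u_death = matrix(stats::runif(n * T), n, T),
    u_cvd = matrix(stats::runif(n * T), n, T),
    u_drop = matrix(stats::runif(n * T), n, T),
    u_miss = array(stats::runif(n * T * nrow(labs)),
                   dim = c(n, T, nrow(labs)),
                   dimnames = list(NULL, NULL, labs$name))
  )
}

# Core simulator. `treat_override` forces the treatment path (0 or 1) for a
# counterfactual arm; dropout and missingness are then disabled by callers.
.sim_run <- function(cfg, draws, treat_override = NULL,
                     enable_dropout = TRUE, enable_missing = TRUE) {
  n <- cfg$n_patients
  T <- cfg$n_visits
  labs <- cfg$labs
  nlab <- nrow(labs)
  th <- cfg$treat_coefs
  bd <- cfg$outcome_death
  bc <- cfg$outcome_cvd
  zua <- function(x) (x - labs$mean[labs$name == "ua"]) /
    labs$sd[labs$name == "ua"]
  zalb <- function(x) (x - labs$mean[labs$name == "alb"]) /
    labs$sd[labs$name == "alb"]

  baseline <- draws$baseline
  if (is.null(treat_override)) {
    eta_bl <- cfg$baseline$treat_intercept +
      cfg$baseline$treat_ua * zua(draws$lab0[, "ua"])
    baseline$baseline_treatment <-
      as.integer(draws$u_bl_treat < stats::plogis(eta_bl))
  } else {
    baseline$baseline_treatment <- as.integer(treat_override)
  }
  for (j in seq_len(nlab)) {
    baseline[[paste0("baseline_", labs$name[j])]] <- draws$lab0[, j]
  }

  L <- draws$lab0
  anchor <- draws$anchor
  A_prev <- baseline$baseline_treatment
  at_risk <- rep(TRUE, n)
  had_cvd <- rep(FALSE, n)
  sd_innov <- labs$sd * sqrt((1 - labs$between_frac) * (1 - labs$rho^2))

  # preallocate the person-visit record as one numeric matrix
  rec <- matrix(NA_real_, n * T, 5L + nlab)
  colnames(rec) <- c("visit", "treatment", "event_death", "event_cvd",
                     "censored", labs$name)
  rec_pid <- integer(n * T)
  n_rec <- 0L

  for (t in seq_len(T)) {
    if (!any(at_risk)) break
    if (is.null(treat_override)) {
      eta_a <- th["intercept"] + th["prev_treatment"] * A_prev +
        th["prev_ua_z"] * zua(L[, "ua"]) + th["prev_alb_z"] * zalb(L[, "alb"])
      if (any(!is.finite(eta_a[at_risk]))) {
        stop("non-finite treatment linear predictor; check treat_coefs: ",
             paste(sprintf("%s=%.3g", names(th), th), collapse = ", "),
             call. = FALSE)
      }
      A <- as.integer(draws$u_treat[, t] < stats::plogis(eta_a))
    } else {
      A <- rep(as.integer(treat_override), n)
    }
    L_new <- L
    for (j in seq_len(nlab)) {
      L_new[, j] <- anchor[, j] * (1 - labs$rho[j]) + labs$rho[j] * L[, j] +
        sd_innov[j] * draws$eps[, t, j]
    }
    L_new[, "ua"] <- pmax(L_new[, "ua"] + cfg$ua_treatment_effect * A, 0.1)

    eta_d <- bd["intercept"] + bd["treatment"] * A +
      bd["ua_z"] * zua(L_new[, "ua"]) + bd["alb_z"] * zalb(L_new[, "alb"])
    eta_c <- bc["intercept"] + bc["treatment"] * A +
      bc["ua_z"] * zua(L_new[, "ua"]) + bc["alb_z"] * zalb(L_new[, "alb"])
    if (any(!is.finite(eta_d[at_risk])) || any(!is.finite(eta_c[at_risk]))) {
      stop("non-finite outcome linear predictor; check outcome coefficients",
           call. = FALSE)
    }
    death <- draws$u_death[, t] < stats::plogis(eta_d)
    cvd_new <- draws$u_cvd[, t] < stats::plogis(eta_c) & !had_cvd
    drop_now <- enable_dropout & draws$u_drop[, t] < cfg$dropout_hazard &
      !death

    idx <- which(at_risk)
    lab_obs <- L_new[idx, , drop = FALSE]
    if (enable_missing && cfg$missing_rate > 0) {
      for (j in seq_len(nlab)) {
        lab_obs[draws$u_miss[idx, t, j] < cfg$missing_rate, j] <- NA_real_
      }
    }
    slot <- n_rec + seq_along(idx)
    rec_pid[slot] <- idx
    rec[slot, 1:5] <- cbind(t, A[idx], as.integer(death[idx]),
                            as.integer(cvd_new[idx]),
                            as.integer(drop_now[idx]))
    rec[slot, 5L + seq_len(nlab)] <- lab_obs
    n_rec <- n_rec + length(idx)

    had_cvd <- had_cvd | cvd_new
    at_risk <- at_risk & !death & !drop_now
    A_prev <- A
    L <- L_new
  }
  rec <- rec[seq_len(n_rec), , drop = FALSE]
  rec_pid <- rec_pid[seq_len(n_rec)]
  ord <- order(rec_pid, rec[, "visit"])
  visits <- data.frame(patient_id = baseline$patient_id[rec_pid[ord]],
                       rec[ord, , drop = FALSE],
                       stringsAsFactors = FALSE)
  cohort_panel(baseline, visits, n_visits = T)
}

#' Generate a synthetic observational cohort
#'
#' Sequential monthly simulation with treatment-confounder feedback: the
#' treatment decision looks at the previous month's treatment, uric acid and
#' albumin; treatment lowers subsequent uric acid; death and first-CVD
#' hazards depend on current treatment, uric acid and albumin. Follow-up
#' rows stop at death or administrative dropout; lab measurements are then
#' masked at the configured missingness rate.
#'
#' @param config a `dgp_config`.
#' @return a validated `cohort_panel`. Identical config + seed reproduce the
#'   panel bit for bit.
#' @export
generate_cohort <- function(config) {
  validate_dgp_config(config)
  draws <- .sim_draws(config)
  .sim_run(config, draws)
}

#' Generate counterfactual always-treated / never-treated arms
#'
#' Both arms share every random draw (baselines, lab innovations, event
#' uniforms); only the treatment path differs. Dropout and lab missingness
#' are disabled so the arms represent the estimand directly.
#'
#' @param config a `dgp_config`.
#' @return object of class `counterfactual_arms` with elements
#'   `panel_always`, `panel_never`.
#' @export
generate_counterfactual_arms <- function(config) {
  validate_dgp_config(config)
  draws <- .sim_draws(config)
  structure(list(
    panel_always = .sim_run(config, draws, treat_override = 1L,
                            enable_dropout = FALSE, enable_missing = FALSE),
    panel_never = .sim_run(config, draws, treat_override = 0L,
                           enable_dropout = FALSE, enable_missing = FALSE)
  ), class = "counterfactual_arms")
}

#' Ground-truth marginal hazard ratio by counterfactual simulation
#'
#' Simulates always-treated and never-treated counterfactual arms at large n
#' (in memory-bounded chunks with seeds derived from the config seed),
#' aggregates event counts by arm and month, and fits an unweighted pooled
#' logistic model of the event on the arm indicator plus polynomial month
#' terms via frequency weights — the exact maximum-likelihood fit that
#' row-level stacking would give. The exponentiated arm coefficient is the
#' true marginal hazard ratio the weighted analyses are judged against.
#'
#' @param config a `dgp_config`.
#' @param n_large total patients per arm (>= 1e5 recommended for a
#'   reference-quality oracle; smaller n gives a noisier check).
#' @param outcome `"death"` or `"cvd"`.
#' @param chunk_size patients simulated per chunk.
#' @return the oracle hazard ratio (positive scalar), with attributes
#'   `n_events` (per arm) and `log_hr`.
#' @export
oracle_marginal_hr <- function(config, n_large = 1e5, outcome = "death",
                               chunk_size = 20000) {
  validate_dgp_config(config)
  outcome <- match.arg(outcome, c("death", "cvd"))
  ycol <- if (outcome == "death") "event_death" else "event_cvd"
  n_chunks <- ceiling(n_large / chunk_size)
  sizes <- rep(chunk_size, n_chunks)
  sizes[n_chunks] <- n_large - chunk_size * (n_chunks - 1)
  set.seed(config$seed)
  chunk_seeds <- sample.int(.Machine$integer.max - 1L, n_chunks)

  T <- config$n_visits
  events <- matrix(0, nrow = 2, ncol = T, dimnames = list(c("never", "always")))
  atrisk <- matrix(0, nrow = 2, ncol = T, dimnames = list(c("never", "always")))
  for (ch in seq_len(n_chunks)) {
    cfg_ch <- config
    cfg_ch$n_patients <- as.integer(sizes[ch])
    cfg_ch$seed <- chunk_seeds[ch]
    arms <- generate_counterfactual_arms(cfg_ch)
    for (arm in c("never", "always")) {
      v <- if (arm == "always") arms$panel_always$visits else
        arms$panel_never$visits
      if (outcome == "cvd") {
        # risk set for a first event: rows up to and including the first event
        keep <- stats::ave(v$event_cvd, v$patient_id,
                           FUN = function(e) cumsum(cumsum(e)) <= 1)
        v <- v[keep == 1, , drop = FALSE]
      }
      ev_t <- rowsum(v[[ycol]], v$visit)
      n_t <- rowsum(rep(1, nrow(v)), v$visit)
      tt <- as.integer(rownames(ev_t))
      events[arm, tt] <- events[arm, tt] + ev_t[, 1]
      atrisk[arm, tt] <- atrisk[arm, tt] + n_t[, 1]
    }
  }
  if (any(rowSums(events) == 0)) {
    stop("an arm produced zero events; increase n_large or the baseline ",
         "event rate", call. = FALSE)
  }
  # frequency-weighted pooled logistic on the (arm, month) aggregate
  grid <- expand.grid(arm = c(0, 1), month = seq_len(T))
  d <- mapply(function(a, m) events[a + 1, m], grid$arm, grid$month)
  r <- mapply(function(a, m) atrisk[a + 1, m], grid$arm, grid$month)
  agg <- rbind(
    data.frame(y = 1, arm = grid$arm, month = grid$month, w = d),
    data.frame(y = 0, arm = grid$arm, month = grid$month, w = r - d)
  )
  agg <- agg[agg$w > 0, ]
  X <- cbind(intercept = 1, arm = agg$arm, month = agg$month,
             month2 = agg$month^2, month3 = agg$month^3)
  # a short design (small T) cannot support all cubic month terms
  X <- .drop_collinear(X, protect = 2L)
  fit <- fit_logistic(agg$y, X, weights = agg$w)
  log_hr <- unname(fit$coefficients["arm"])
  structure(exp(log_hr), log_hr = log_hr,
            n_events = rowSums(events), n = n_large)
}

#' @export
print.counterfactual_arms <- function(x, ...) {
  cat("<counterfactual_arms>\n  always:")
  print(x$panel_always)
  cat("  never:")
  print(x$panel_never)
  invisible(x)
}
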