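# Visit-level treatment-probability models and cumulative stabilized
# inverse-probability-of-treatment weights, with truncation and diagnostics.

#' Specify the propensity (treatment) model
#'
#' The denominator model predicts this month's treatment from the previous
#' month's treatment, the previous month's lab values and the baseline
#' covariates; the numerator model uses the same specification without the
#' time-varying labs. At visit 1 the baseline treatment status and baseline
#' lab values serve as the lag-1 stand-ins.
#'
#' @param time_dependent lab names entered as previous-visit values.
#' @param baseline baseline covariate names (columns of the baseline table).
#' @param include_previous_treatment must be `TRUE`: past prescription is
#'   always a predictor of current prescription.
#' @param lag visit lag for the time-dependent covariates (only 1 supported).
#' @return object of class `propensity_spec`.
#' @export
propensity_spec <- function(time_dependent = c("ua", "alb", "npcr", "cgr",
                                               "ferritin", "sodium", "ktv"),
                            baseline = c("age", "sex_male", "bmi",
                                         "diabetes", "hd_vintage",
                                         "baseline_ua", "baseline_alb"),
                            include_previous_treatment = TRUE,
                            lag = 1L) {
  if (!isTRUE(include_previous_treatment)) {
    stop("previous treatment is always included in the propensity model",
         call. = FALSE)
  }
  if (lag != 1L) stop("only lag = 1 is supported", call. = FALSE)
  structure(list(
    time_dependent = time_dependent,
    baseline = baseline,
    include_previous_treatment = TRUE,
    lag = 1L
  ), class = "propensity_spec")
}

# Stacked person-visit design frame with lagged labs and previous treatment.
# Row order matches panel$visits.
.design_stack <- function(panel, spec) {
  v <- panel$visits
  b <- panel$baseline
  absent <- setdiff(spec$time_dependent, panel_labs(panel))
  if (length(absent)) {
    stop("lab(s) requested by the propensity model are absent: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  absent_b <- setdiff(spec$baseline, names(b))
  if (length(absent_b)) {
    stop("baseline covariate(s) absent: ", paste(absent_b, collapse = ", "),
         call. = FALSE)
  }
  bidx <- match(v$patient_id, b$patient_id)
  first <- !duplicated(v$patient_id)
  out <- data.frame(patient_id = v$patient_id, visit = v$visit,
                    treatment = v$treatment, stringsAsFactors = FALSE)
  # previous treatment: shift within patient; baseline status at visit 1
  prev_a <- c(NA_real_, v$treatment[-nrow(v)])
  prev_a[first] <- b$baseline_treatment[bidx[first]]
  out$prev_treatment <- prev_a
  for (lab in spec$time_dependent) {
    lagged <- c(NA_real_, v[[lab]][-nrow(v)])
    bl_col <- paste0("baseline_", lab)
    if (!bl_col %in% names(b)) {
      stop("no baseline column '", bl_col, "' to seed visit-1 lag for lab '",
           lab, "'", call. = FALSE)
    }
    lagged[first] <- b[[bl_col]][bidx[first]]
    out[[paste0("prev_", lab)]] <- lagged
  }
  for (cov in spec$baseline) out[[cov]] <- b[[cov]][bidx]
  out
}

#' Design rows for one visit of the treatment model
#'
#' One row per patient still at risk at that visit; time-dependent
#' covariates are the previous visit's values (baseline values at visit 1),
#' previous treatment is the visit-1 baseline status or the preceding
#' month's indicator.
#'
#' @param panel a `cohort_panel`.
#' @param spec a `propensity_spec`.
#' @param visit visit index (1-based).
#' @return data.frame with `patient_id`, `visit`, the response `treatment`,
#'   `prev_treatment`, lagged labs (`prev_<lab>`) and baseline covariates.
#' @export
build_design <- function(panel, spec, visit) {
  if (visit < 1) stop("visit must be >= 1", call. = FALSE)
  stack <- .design_stack(panel, spec)
  out <- stack[stack$visit == visit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# model matrix from a stacked design frame
.ps_model_matrix <- function(stack, spec, time_dependent = TRUE) {
  cols <- c("prev_treatment",
            if (time_dependent && length(spec$time_dependent))
              paste0("prev_", spec$time_dependent),
            spec$baseline)
  X <- cbind(intercept = 1, as.matrix(stack[, cols, drop = FALSE]))
  storage.mode(X) <- "double"
  X
}

.fit_ps_model <- function(panel, spec, time_dependent) {
  stack <- .design_stack(panel, spec)
  if (anyNA(stack)) {
    stop("missing covariate values in the propensity design; run ",
         "locf_impute() first", call. = FALSE)
  }
  X <- .ps_model_matrix(stack, spec, time_dependent)
  fit <- fit_logistic(stack$treatment, X, cluster = stack$patient_id)
  pred <- fit$fitted
  n_clamped <- sum(pred < 1e-10 | pred > 1 - 1e-10)
  if (n_clamped > 0) {
    warning(n_clamped, " propensity prediction(s) clamped away from 0/1",
            call. = FALSE)
  }
  pred <- pmin(pmax(pred, 1e-10), 1 - 1e-10)
  structure(list(
    fit = fit,
    predictions = data.frame(patient_id = stack$patient_id,
                             visit = stack$visit,
                             treatment = stack$treatment,
                             ps_pred = pred,
                             stringsAsFactors = FALSE),
    spec = spec,
    time_dependent = time_dependent
  ), class = "ps_model")
}

#' Fit the denominator (full) treatment-probability model
#'
#' A single pooled logistic fit across all person-visits: current treatment
#' on previous treatment, previous-visit labs and baseline covariates.
#'
#' @param panel a LOCF-complete `cohort_panel`.
#' @param spec a `propensity_spec`.
#' @return object of class `ps_model`: the `logistic_fit` and per
#'   person-visit predicted treatment probabilities in (0, 1).
#' @export
fit_denominator_model <- function(panel, spec = propensity_spec()) {
  .fit_ps_model(panel, spec, time_dependent = TRUE)
}

#' Fit the numerator (reduced) treatment-probability model
#'
#' Same covariates as the denominator minus the time-varying labs: previous
#' treatment and baseline covariates only. Its predictions stabilize the
#' weights.
#'
#' @inheritParams fit_denominator_model
#' @return a `ps_model`.
#' @export
fit_numerator_model <- function(panel, spec = propensity_spec()) {
  .fit_ps_model(panel, spec, time_dependent = FALSE)
}

#' @export
print.ps_model <- function(x, ...) {
  cat("<ps_model> ", if (x$time_dependent) "denominator (full)" else
    "numerator (reduced)", " treatment model\n", sep = "")
  print(x$fit)
  invisible(x)
}

# cumulative sum within consecutive groups (rows sorted by patient, visit)
.group_cumsum <- function(x, first) {
  cs <- cumsum(x)
  offset <- c(0, cs)[which(first)][cumsum(first)]
  cs - offset
}

#' Cumulative stabilized inverse-probability-of-treatment weights
#'
#' Converts per-visit treatment probabilities into visit-level weight
#' factors — `1/p` if treated, `1/(1-p)` if untreated for the denominator;
#' `p` or `1-p` for the numerator — and multiplies them cumulatively over a
#' patient's visits. The stabilized weight at visit t is the cumulative
#' numerator times the cumulative inverse denominator; its mean is ~1 when
#' both models are correctly specified.
#'
#' @param panel a `cohort_panel` (defines the person-visit rows at risk).
#' @param denominator a `ps_model` from [fit_denominator_model()].
#' @param numerator a `ps_model` from [fit_numerator_model()].
#' @return object of class `weight_set`: a data.frame with one row per
#'   person-visit carrying the predictions, visit-level factors, cumulative
#'   products and `stabilized_weight`; `truncated_weight` is filled by
#'   [truncate_weights()].
#' @export
compute_stabilized_weights <- function(panel, denominator, numerator) {
  dn <- denominator$predictions
  nm <- numerator$predictions
  if (nrow(dn) != nrow(nm) ||
      any(dn$patient_id != nm$patient_id) || any(dn$visit != nm$visit)) {
    stop("denominator and numerator predictions are not aligned",
         call. = FALSE)
  }
  p_d <- dn$ps_pred
  p_n <- nm$ps_pred
  if (any(p_d <= 0 | p_d >= 1) || any(p_n <= 0 | p_n >= 1)) {
    stop("treatment probabilities must lie strictly inside (0, 1); a ",
         "prediction of exactly 0 or 1 yields an infinite weight",
         call. = FALSE)
  }
  a <- dn$treatment
  w <- data.frame(
    patient_id = dn$patient_id,
    visit = dn$visit,
    treatment = a,
    ps_pred_denominator = p_d,
    ps_pred_numerator = p_n,
    visit_weight_denominator = ifelse(a == 1, 1 / p_d, 1 / (1 - p_d)),
    visit_weight_numerator = ifelse(a == 1, p_n, 1 - p_n),
    stringsAsFactors = FALSE
  )
  first <- !duplicated(w$patient_id)
  log_cum_den_inv <- .group_cumsum(log(w$visit_weight_denominator), first)
  log_cum_num <- .group_cumsum(log(w$visit_weight_numerator), first)
  w$cumulative_denominator_inverse <- exp(log_cum_den_inv)
  w$cumulative_numerator <- exp(log_cum_num)
  w$stabilized_weight <- exp(log_cum_num + log_cum_den_inv)
  w$truncated_weight <- NA_real_
  if (any(!is.finite(w$stabilized_weight))) {
    stop("non-finite stabilized weight produced", call. = FALSE)
  }
  structure(w, class = c("weight_set", "data.frame"),
            ps_spec = denominator$spec, truncation = NULL)
}

#' Truncate stabilized weights at mirrored percentile bounds
#'
#' The lower bound is the (100 - p)th percentile and the upper bound the
#' p-th percentile of the pooled person-visit stabilized weights; weights
#' outside the bounds are reset to them. Truncation is monotone and
#' idempotent; `percentile = "none"` leaves the weights untouched. Explicit
#' `bounds` override the percentile computation.
#'
#' @param weights a `weight_set`.
#' @param percentile 95, 99 or `"none"`.
#' @param bounds optional numeric `c(lower, upper)` overriding the
#'   percentile-derived bounds.
#' @return the `weight_set` with `truncated_weight` filled and a
#'   `truncation` attribute recording percentile and bounds.
#' @export
truncate_weights <- function(weights, percentile = 99, bounds = NULL) {
  sw <- weights$stabilized_weight
  if (identical(percentile, "none") && is.null(bounds)) {
    weights$truncated_weight <- sw
    attr(weights, "truncation") <- list(percentile = "none",
                                        lower = -Inf, upper = Inf)
    return(weights)
  }
  if (is.null(bounds)) {
    if (!percentile %in% c(95, 99)) {
      stop("percentile must be 95, 99 or \"none\"", call. = FALSE)
    }
    bounds <- unname(stats::quantile(sw, c((100 - percentile) / 100,
                                           percentile / 100)))
  } else {
    percentile <- NA
  }
  if (bounds[1] > bounds[2]) stop("lower bound exceeds upper bound",
                                  call. = FALSE)
  weights$truncated_weight <- pmin(pmax(sw, bounds[1]), bounds[2])
  attr(weights, "truncation") <- list(percentile = percentile,
                                      lower = bounds[1], upper = bounds[2])
  weights
}

#' Summary statistics of the pooled stabilized weights
#'
#' @param weights a `weight_set`.
#' @param which `"stabilized"` or `"truncated"`.
#' @return object of class `weight_diagnostics`: mean, SD, min, max, 95th
#'   and 99th percentiles and the person-visit count.
#' @export
weight_diagnostics <- function(weights, which = "stabilized") {
  col <- match.arg(which, c("stabilized", "truncated"))
  x <- if (col == "stabilized") weights$stabilized_weight else
    weights$truncated_weight
  if (!length(x)) stop("empty weight set", call. = FALSE)
  if (anyNA(x)) stop("truncated weights not yet computed", call. = FALSE)
  q <- stats::quantile(x, c(0.95, 0.99), names = FALSE)
  structure(list(
    mean = mean(x),
    sd = if (length(x) > 1) stats::sd(x) else 0,
    min = min(x), max = max(x),
    percentile_95 = q[1], percentile_99 = q[2],
    n_person_visits = length(x)
  ), class = "weight_diagnostics")
}

#' @export
print.weight_diagnostics <- function(x, ...) {
  cat(sprintf(paste0(
    "<weight_diagnostics> n = %d person-visits\n",
    "  mean %.3f, sd %.3f (min %.4g, max %.4g), 95%% point %.3f, ",
    "99%% point %.3f\n"),
    x$n_person_visits, x$mean, x$sd, x$min, x$max,
    x$percentile_95, x$percentile_99))
  invisible(x)
}

#' Export a weight table as CSV
#'
#' @param weights a `weight_set`.
#' @param path output path.
#' @export
write_weights <- function(weights, path) {
  cols <- c("patient_id", "visit", "ps_pred_denominator",
            "ps_pred_numerator", "stabilized_weight", "truncated_weight")
  utils::write.csv(as.data.frame(weights)[, cols], path, row.names = FALSE,
                   na = "")
  invisible(path)
}
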