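# Kaplan-Meier product-limit estimator and the k-group log-rank test.

#' Kaplan-Meier product-limit estimate
#'
#' Standard convention: subjects censored at time t remain in the risk set
#' for events at t.
#'
#' @param time non-negative event/censoring times.
#' @param event binary event indicator.
#' @return object of class `km_curve`: `time` (distinct event times,
#'   increasing), `n_risk`, `n_event`, `survival` (non-increasing, S(0)=1
#'   implicit), plus `n` and `n_events` totals.
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1) stop("need at least one subject", call. = FALSE)
  if (any(time < 0)) stop("negative times are not allowed", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("event must be binary 0/1", call. = FALSE)
  ev_times <- sort(unique(time[event == 1]))
  n_risk <- vapply(ev_times, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ev_times, function(t) sum(time == t & event == 1),
                    numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(list(
    time = ev_times, n_risk = n_risk, n_event = n_event, survival = surv,
    n = length(time), n_events = sum(event)
  ), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("<km_curve> ", x$n, " subjects, ", x$n_events, " events\n", sep = "")
  print(data.frame(time = x$time, n_risk = x$n_risk,
                   n_event = x$n_event, survival = x$survival))
  invisible(x)
}

#' k-group log-rank test
#'
#' Sums hypergeometric means and covariances of the per-group event counts
#' over the distinct event times; the statistic is the quadratic form of the
#' observed-minus-expected vector (dropping one group) in the inverse of its
#' covariance, referred to a chi-square on k-1 degrees of freedom. Pairwise
#' two-group comparisons are the k = 2 special case.
#'
#' @param time event/censoring times.
#' @param event binary event indicator.
#' @param group group labels (at least two distinct values).
#' @return object of class `logrank_result`: `chi_square`, `df`, `p_value`,
#'   `observed` and `expected` per-group event counts.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  k <- nlevels(group)
  if (k < 2) stop("log-rank test needs at least two groups", call. = FALSE)
  if (sum(event) < 1) stop("log-rank test needs at least one event",
                           call. = FALSE)
  ev_times <- sort(unique(time[event == 1]))
  O <- stats::setNames(numeric(k), levels(group))
  E <- stats::setNames(numeric(k), levels(group))
  V <- matrix(0, k, k, dimnames = list(levels(group), levels(group)))
  for (t in ev_times) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    d_t <- sum(time == t & event == 1)
    n_g <- vapply(levels(group), function(g) sum(at_risk & group == g),
                  numeric(1))
    d_g <- vapply(levels(group),
                  function(g) sum(time == t & event == 1 & group == g),
                  numeric(1))
    O <- O + d_g
    E <- E + d_t * n_g / n_t
    if (n_t > 1) {
      hyper <- d_t * (n_t - d_t) / (n_t - 1)
      p_g <- n_g / n_t
      V <- V + hyper * (diag(p_g, nrow = k) - tcrossprod(p_g))
    }
  }
  oe <- (O - E)[-k]
  Vsub <- V[-k, -k, drop = FALSE]
  chi <- tryCatch(drop(t(oe) %*% solve(Vsub, oe)), error = function(e) {
    # degenerate covariance (e.g. a group never at risk with others)
    qr_v <- qr(Vsub)
    drop(t(oe) %*% qr.coef(qr_v, oe))
  })
  if (!is.finite(chi)) chi <- 0
  chi <- max(chi, 0)
  structure(list(
    chi_square = chi, df = k - 1L,
    p_value = stats::pchisq(chi, df = k - 1L, lower.tail = FALSE),
    observed = O, expected = E
  ), class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat("<logrank_result> chi-square = ", format(x$chi_square, digits = 5),
      " on ", x$df, " df, p = ", format(x$p_value, digits = 4), "\n", sep = "")
  print(data.frame(observed = x$observed, expected = x$expected))
  invisible(x)
}
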