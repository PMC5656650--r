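# Cox proportional hazards with Breslow tie handling, Newton-Raphson
# maximisation of the partial likelihood, and a grouped sandwich variance
# built from score residuals summed within cluster.

# suffix (reverse cumulative) sums of a vector or the columns of a matrix
.revcumsum <- function(x) {
  if (is.matrix(x)) {
    apply(x, 2, function(col) rev(cumsum(rev(col))))
  } else {
    rev(cumsum(rev(x)))
  }
}

#' Cox proportional hazards with robust standard errors
#'
#' Maximises the Breslow-ties partial likelihood by Newton-Raphson with step
#' halving. The robust covariance is the grouped sandwich on score residuals:
#' per-subject dfbeta contributions are summed within cluster and their outer
#' product taken, which reduces to the usual robust Cox variance when every
#' subject is its own cluster.
#'
#' @param time positive event/censoring times.
#' @param event binary event indicator (1 = event, 0 = censored).
#' @param X design matrix of covariates (no intercept; it cancels from the
#'   partial likelihood).
#' @param cluster cluster identifiers; `NULL` treats subjects as independent.
#' @param tol convergence tolerance on the maximum coefficient change.
#' @param max_iter maximum Newton iterations.
#' @param coef_bound guard against monotone likelihood (no finite maximiser).
#' @return object of class `cox_fit`: `coefficients`, `covariance_model`,
#'   `covariance_robust`, `n_events`, `ties_method` ("breslow"),
#'   `iterations`, `loglik`.
#' @export
fit_cox <- function(time, event, X, cluster = NULL,
                    tol = 1e-8, max_iter = 50L, coef_bound = 50) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- length(time)
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("times must be positive and finite", call. = FALSE)
  }
  if (!all(event %in% c(0, 1))) stop("event must be binary 0/1", call. = FALSE)
  if (sum(event) < 1) stop("at least one event is required", call. = FALSE)
  if (nrow(X) != n) stop("nrow(X) must equal length(time)", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(cluster)) cluster <- seq_len(n)
  p <- ncol(X)

  # a covariate constant over subjects (or any collinear set) is not
  # identified in the partial likelihood
  qr0 <- qr(scale(X, center = TRUE, scale = FALSE))
  if (qr0$rank < p) {
    bad <- colnames(X)[qr0$pivot[(qr0$rank + 1L):p]]
    stop("design matrix is rank deficient on risk sets; column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  ord <- order(time)
  time <- time[ord]
  event <- event[ord]
  X <- X[ord, , drop = FALSE]
  cluster <- cluster[ord]

  # risk set of a time t is the suffix starting at the first row with that
  # time; map every row to the first index of its tie group
  first_of_time <- match(time, time)

  # distinct event times and per-time event counts
  ev_idx <- which(event == 1)
  ev_times <- unique(time[ev_idx])
  ev_first <- match(ev_times, time)            # suffix index per event time
  d_k <- as.numeric(rowsum(rep(1, length(ev_idx)),
                           group = match(time[ev_idx], ev_times),
                           reorder = TRUE))
  # sum of covariates over deaths at each distinct event time
  xsum_k <- rowsum(X[ev_idx, , drop = FALSE],
                   group = match(time[ev_idx], ev_times), reorder = TRUE)

  pl_terms <- function(beta) {
    eta <- drop(X %*% beta)
    r <- exp(eta)
    S0 <- .revcumsum(r)
    S1 <- .revcumsum(X * r)
    if (!is.matrix(S1)) S1 <- matrix(S1, ncol = p)
    S0k <- S0[ev_first]
    S1k <- S1[ev_first, , drop = FALSE]
    ll <- sum(eta[ev_idx]) - sum(d_k * log(S0k))
    list(eta = eta, r = r, S0k = S0k, S1k = S1k, ll = ll)
  }

  beta <- rep(0, p)
  cur <- pl_terms(beta)
  iterations <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    xbar <- cur$S1k / cur$S0k
    U <- colSums(xsum_k - d_k * xbar)
    # information: sum_k d_k (S2/S0 - xbar xbar')
    H <- matrix(0, p, p)
    r <- cur$r
    for (a in seq_len(p)) {
      Za <- X[, a] * r
      S2a <- .revcumsum(X * Za)
      if (!is.matrix(S2a)) S2a <- matrix(S2a, ncol = p)
      S2a_k <- S2a[ev_first, , drop = FALSE] / cur$S0k
      H[a, ] <- colSums(d_k * (S2a_k - xbar[, a] * xbar))
    }
    H <- (H + t(H)) / 2
    step <- tryCatch(solve(H, U), error = function(e) {
      stop("singular information matrix in Cox Newton-Raphson (possible ",
           "monotone partial likelihood)", call. = FALSE)
    })
    # step halving if the partial likelihood does not improve
    lambda <- 1
    repeat {
      beta_new <- beta + lambda * step
      if (any(abs(beta_new) > coef_bound)) {
        stop("monotone partial likelihood: coefficient for ",
             paste(colnames(X)[abs(beta_new) > coef_bound], collapse = ", "),
             " diverges (no finite maximiser)", call. = FALSE)
      }
      cand <- pl_terms(beta_new)
      if (cand$ll >= cur$ll - 1e-12 || lambda < 1 / 1024) break
      lambda <- lambda / 2
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    cur <- cand
    iterations <- it
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop("Cox Newton-Raphson failed to converge in ", max_iter, " iterations",
         call. = FALSE)
  }

  # final information and model covariance
  xbar <- cur$S1k / cur$S0k
  H <- matrix(0, p, p)
  for (a in seq_len(p)) {
    Za <- X[, a] * cur$r
    S2a <- .revcumsum(X * Za)
    if (!is.matrix(S2a)) S2a <- matrix(S2a, ncol = p)
    S2a_k <- S2a[ev_first, , drop = FALSE] / cur$S0k
    H[a, ] <- colSums(d_k * (S2a_k - xbar[, a] * xbar))
  }
  H <- (H + t(H)) / 2
  vmod <- solve(H)

  # score residuals:
  # U_i = delta_i (x_i - xbar(t_i)) - r_i [x_i cumLam(t_i) - cumB(t_i)]
  dLam <- d_k / cur$S0k
  cumLam_steps <- cumsum(dLam)
  cumB_steps <- apply(dLam * xbar, 2, cumsum)
  if (!is.matrix(cumB_steps)) cumB_steps <- matrix(cumB_steps, ncol = p)
  pos <- findInterval(time, ev_times)          # # event times <= t_i
  cumLam <- c(0, cumLam_steps)[pos + 1L]
  cumB <- rbind(0, cumB_steps)[pos + 1L, , drop = FALSE]
  res <- -cur$r * (X * cumLam - cumB)
  if (length(ev_idx)) {
    k_of_event <- match(time[ev_idx], ev_times)
    res[ev_idx, ] <- res[ev_idx, , drop = FALSE] +
      X[ev_idx, , drop = FALSE] - xbar[k_of_event, , drop = FALSE]
  }
  D <- res %*% vmod                            # per-subject dfbeta
  Dg <- rowsum(D, group = as.character(cluster), reorder = FALSE)
  vrob <- crossprod(Dg)
  vrob <- (vrob + t(vrob)) / 2
  dimnames(vmod) <- dimnames(vrob) <- list(colnames(X), colnames(X))

  structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    covariance_model = vmod,
    covariance_robust = vrob,
    n_events = sum(event),
    ties_method = "breslow",
    iterations = iterations,
    loglik = cur$ll
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("<cox_fit> Breslow ties, ", x$n_events, " events, ",
      x$iterations, " Newton iterations\n", sep = "")
  se_r <- sqrt(diag(x$covariance_robust))
  z <- x$coefficients / se_r
  print(data.frame(
    coef = x$coefficients, hr = exp(x$coefficients),
    se_robust = se_r, p = 2 * stats::pnorm(-abs(z))
  ))
  invisible(x)
}
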