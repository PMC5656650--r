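# Weighted logistic regression by iteratively reweighted least squares,
# with a cluster-robust sandwich covariance. This is the workhorse behind
# the propensity models, the pooled-logistic outcome model and the
# counterfactual oracle, so it is implemented from first principles rather
# than delegated.

#' Weighted logistic regression with cluster-robust variance
#'
#' Maximises the weighted Bernoulli log-likelihood by Newton-Raphson /
#' iteratively reweighted least squares. Two covariance estimates are
#' returned: the model-based inverse Fisher information, and a cluster
#' sandwich (bread = inverse weighted information; meat = outer product of
#' cluster-summed weighted scores) that is valid under within-cluster
#' correlation, e.g. repeated person-visit rows of the same patient.
#'
#' @param y binary response vector (0/1).
#' @param X design matrix (include an intercept column yourself).
#' @param weights non-negative observation weights; `NULL` means 1.
#'   Multiplying all weights by a positive constant rescales the covariance
#'   but leaves the coefficients unchanged.
#' @param cluster cluster identifiers for the sandwich; `NULL` treats each
#'   observation as its own cluster (heteroskedasticity-robust sandwich).
#' @param tol convergence tolerance on the maximum absolute coefficient
#'   change per iteration.
#' @param max_iter maximum IRLS iterations.
#' @param coef_bound separation guard: the fit aborts if any coefficient
#'   exceeds this magnitude, which with standardised-scale covariates signals
#'   (quasi-)complete separation.
#' @return object of class `logistic_fit`: `coefficients`,
#'   `covariance_model`, `covariance_robust`, `fitted` (probabilities),
#'   `n_obs`, `n_clusters`, `converged`, `iterations`.
#' @export
fit_logistic <- function(y, X, weights = NULL, cluster = NULL,
                         tol = 1e-8, max_iter = 100L, coef_bound = 50) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(X) != n) stop("nrow(X) must equal length(y)", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || anyNA(weights)) {
    stop("weights must be non-negative and non-missing", call. = FALSE)
  }
  if (is.null(cluster)) cluster <- seq_len(n)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  p <- ncol(X)

  keep <- weights > 0
  qr0 <- qr(X[keep, , drop = FALSE] * sqrt(weights[keep]))
  if (qr0$rank < p) {
    bad <- colnames(X)[qr0$pivot[(qr0$rank + 1L):p]]
    stop("design matrix is rank deficient; dependent column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  beta <- rep(0, p)
  converged <- FALSE
  iterations <- 0L
  # the intercept absorbs covariate means on their raw scales, so the
  # separation bound applies only to non-constant columns
  slope_cols <- apply(X, 2, function(col) max(col) != min(col))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    v <- pmax(mu * (1 - mu), 1e-12)
    wirls <- weights * v
    z <- eta + (y - mu) / v
    fit <- stats::lm.wfit(X, z, w = wirls)
    beta_new <- fit$coefficients
    if (any(!is.finite(beta_new))) {
      stop("IRLS produced non-finite coefficients (degenerate working weights)",
           call. = FALSE)
    }
    bad <- slope_cols & abs(beta_new) > coef_bound
    if (any(bad)) {
      stop("separation detected: |coefficient| for ",
           paste(colnames(X)[bad], collapse = ", "),
           " exceeds ", coef_bound, call. = FALSE)
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    iterations <- it
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop("IRLS failed to converge in ", max_iter,
         " iterations; last coefficients: ",
         paste(sprintf("%s=%.4g", colnames(X), beta), collapse = ", "),
         call. = FALSE)
  }

  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  wirls <- weights * mu * (1 - mu)
  info <- crossprod(X * sqrt(wirls))
  bread <- solve(info)
  score <- X * (weights * (y - mu))
  score_g <- rowsum(score, group = as.character(cluster), reorder = FALSE)
  meat <- crossprod(score_g)
  vrob <- bread %*% meat %*% bread
  vrob <- (vrob + t(vrob)) / 2
  vmod <- (bread + t(bread)) / 2
  dimnames(vrob) <- dimnames(vmod) <- list(colnames(X), colnames(X))

  structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    covariance_model = vmod,
    covariance_robust = vrob,
    fitted = mu,
    n_obs = n,
    n_clusters = nrow(score_g),
    converged = converged,
    iterations = iterations
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit> ", x$n_obs, " obs, ", x$n_clusters, " clusters, ",
      x$iterations, " IRLS iterations\n", sep = "")
  se_m <- sqrt(diag(x$covariance_model))
  se_r <- sqrt(diag(x$covariance_robust))
  print(data.frame(coef = x$coefficients, se_model = se_m, se_robust = se_r))
  invisible(x)
}
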