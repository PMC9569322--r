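# Internal helpers: structured conditions, goodness of fit, and a thin
# wrapper around Levenberg-Marquardt least squares.

mq_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("mq_", class), "mq_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

mq_check <- function(cond, class, msg) {
  if (!isTRUE(cond)) mq_stop(class, msg)
  invisible(TRUE)
}

check_finite <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    mq_stop("invalid_argument", sprintf("'%s' must be finite numeric", name))
  }
  if (positive && any(x <= 0)) {
    mq_stop("invalid_argument", sprintf("'%s' must be strictly positive", name))
  }
  if (nonneg && any(x < 0)) {
    mq_stop("invalid_argument", sprintf("'%s' must be non-negative", name))
  }
  invisible(x)
}

#' Goodness-of-fit summary for a least-squares fit
#'
#' Collects the per-point signed residuals, the root mean squared
#' deviation and the reduced chi-square.  For unweighted fits the
#' reduced chi-square uses unit variances, i.e. `chi2_red =
#' sum(residuals^2) / (n - p)`; when weights are supplied it is
#' `sum(w * residuals^2) / (n - p)`.
#'
#' @param observed,expected numeric vectors of equal length.
#' @param n_par number of fitted parameters.
#' @param weights optional per-point weights (1/variance).
#' @return an object of class `"mq_gof"`: list with `residuals`,
#'   `rmsd`, `chi2_red`, `n`, `n_par`.
#' @export
goodness_of_fit <- function(observed, expected, n_par, weights = NULL) {
  mq_check(length(observed) == length(expected), "invalid_argument",
           "observed and expected lengths differ")
  r <- observed - expected
  n <- length(r)
  dof <- max(n - n_par, 1L)
  w <- if (is.null(weights)) rep(1, n) else weights
  structure(
    list(residuals = r,
         rmsd = sqrt(mean(r^2)),
         chi2_red = sum(w * r^2) / dof,
         n = n, n_par = n_par),
    class = "mq_gof"
  )
}

#' @export
print.mq_gof <- function(x, ...) {
  cat(sprintf("RMSD = %.4g, chi2_red = %.4g (n = %d, p = %d)\n",
              x$rmsd, x$chi2_red, x$n, x$n_par))
  invisible(x)
}

# Levenberg-Marquardt driver.  `fn` maps a parameter vector to weighted
# residuals.  Returns estimates, standard errors (from the local
# Jacobian), convergence info.  Bounds are honoured by nls.lm.
mq_nlslm <- function(par, fn, lower = NULL, upper = NULL, maxiter = 200) {
  ctrl <- minpack.lm::nls.lm.control(maxiter = maxiter, ftol = 1e-12,
                                     ptol = 1e-12,
                                     maxfev = 100 * (length(par) + 1) *
                                       maxiter)
  fit <- minpack.lm::nls.lm(
    par = par, fn = fn,
    lower = if (is.null(lower)) rep(-Inf, length(par)) else lower,
    upper = if (is.null(upper)) rep(Inf, length(par)) else upper,
    control = ctrl
  )
  est <- coef(fit)
  se <- rep(NA_real_, length(est))
  names(se) <- names(est)
  ssum <- try(summary(fit), silent = TRUE)
  if (!inherits(ssum, "try-error")) {
    se_tab <- ssum$coefficients
    se[rownames(se_tab)] <- se_tab[, "Std. Error"]
  }
  list(par = est, se = se, info = fit$info, message = fit$message,
       deviance = fit$deviance, niter = fit$niter, object = fit)
}

# Common container for all fit results.  Subclasses add model-specific
# coefficient names; shared methods live in methods.R.
new_quench_fit <- function(subclass, coefficients, se, data, fitted_values,
                           gof, flags = character(), extra = list()) {
  structure(
    c(list(coefficients = coefficients,
           se = se,
           data = data,
           fitted_values = fitted_values,
           gof = gof,
           flags = flags),
      extra),
    class = c(subclass, "quench_fit")
  )
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

`%||%` <- function(a, b) if (is.null(a)) b else a
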