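# Boundary-lipid contact model: quenching of membrane-embedded
# tryptophans by spin-labeled PC, interpreted as static quenching by
# the L_n lipids in direct contact with the accessible fluorophores.

#' Boundary-lipid quenching model
#'
#' Predicted emission when a fraction `quencher_fraction` of the
#' membrane lipid carries a contact quencher:
#'
#' `F(Q) = (F0 - F_min) * (1 - Q)^L_n + F_min`
#'
#' `(1 - Q)^L_n` is the probability that none of the `L_n` boundary
#' lipid sites is occupied by a quencher-labeled lipid; `F_min` is the
#' emission that survives in pure quencher lipid (the inaccessible
#' fluorophore population).
#'
#' @param quencher_fraction mole fraction of quencher lipid, in
#'   \[0, 1\]; vectorized.
#' @param F0 emission without quencher (use 1 for normalized data).
#' @param F_min non-quenchable emission, `0 <= F_min < F0`.
#' @param L_n number of boundary lipids in contact with the accessible
#'   fluorophores, > 0.
#' @return predicted emission, same length as `quencher_fraction`.
#' @export
#' @examples
#' exposure_model(0.30, F0 = 1, F_min = 0.72, L_n = 2.49)  # ~0.8352
exposure_model <- function(quencher_fraction, F0, F_min, L_n) {
  check_finite(quencher_fraction, "quencher_fraction")
  mq_check(all(quencher_fraction >= 0 & quencher_fraction <= 1),
           "invalid_argument",
           "quencher_fraction must be a mole fraction in [0, 1]")
  check_finite(F0, "F0", positive = TRUE)
  check_finite(F_min, "F_min", nonneg = TRUE)
  mq_check(F0 > F_min, "invalid_argument", "F0 must exceed F_min")
  check_finite(L_n, "L_n", positive = TRUE)
  (F0 - F_min) * (1 - quencher_fraction)^L_n + F_min
}

#' Fit the boundary-lipid contact model to a quenching series
#'
#' Least-squares fit of [exposure_model()] to normalized steady-state
#' quenching data, with `F0` fixed at 1 (the series is normalized to
#' its zero-quencher point, so a free scale would be redundant).  Fitted
#' parameters: the boundary-lipid count `L_n` and the non-quenchable
#' fraction `F_min`; `F_min` itself is the accessibility readout (an
#' `F_min` of 0.72 means 72% of the emission comes from fluorophores
#' the quencher cannot reach).
#'
#' Initialization: `F_min = min(response)`, `L_n = 2`; bounds
#' `L_n` in (0.01, 50), `F_min` in \[0, 1).  Residuals are unweighted.
#'
#' @param series a [quenching_series()] with
#'   `response_kind = "intensity"` and at least 4 points including
#'   `quencher_fraction = 0`.
#' @return an object of class `c("exposure_fit", "quench_fit")` with
#'   coefficients `L_n` and `F_min`.  A series with no measurable
#'   quenching is flagged `"degenerate"`/`"unidentifiable"`; a response
#'   that rises with quencher beyond noise is flagged
#'   `"non_monotone"`.
#' @export
fit_exposure <- function(series) {
  if (!inherits(series, "quenching_series")) {
    series <- quenching_series(series$quencher_fraction, series$response)
  }
  mq_check(attr(series, "response_kind") == "intensity", "invalid_argument",
           "the contact model applies to steady-state intensity data")
  mq_check(nrow(series) >= 4, "invalid_argument",
           "need at least 4 points to fit (L_n, F_min)")
  q <- series$quencher_fraction
  y <- series$response

  flags <- character()
  if (any(diff(y) > 0.02)) flags <- c(flags, "non_monotone")
  if (min(y) > 1 - 1e-6) {
    gof <- goodness_of_fit(y, rep(1, length(y)), n_par = 1)
    return(new_quench_fit(
      "exposure_fit",
      coefficients = c(L_n = NA_real_, F_min = 1),
      se = c(L_n = NA_real_, F_min = NA_real_),
      data = series, fitted_values = rep(1, length(y)), gof = gof,
      flags = c(flags, "degenerate", "unidentifiable")
    ))
  }

  par0 <- c(L_n = 2, F_min = max(min(y) - 1e-3, 0))
  resid_fn <- function(p) y - exposure_model(q, 1, p[["F_min"]], p[["L_n"]])
  res <- mq_nlslm(par0, resid_fn,
                  lower = c(L_n = 0.01, F_min = 0),
                  upper = c(L_n = 50, F_min = 1 - 1e-9))
  if (res$info == 0 || res$info == 5) {
    mq_stop("fit_failure",
            paste0("exposure fit did not converge: ", res$message),
            last_par = res$par, deviance = res$deviance)
  }
  p <- res$par
  yhat <- exposure_model(q, 1, p[["F_min"]], p[["L_n"]])
  gof <- goodness_of_fit(y, yhat, n_par = 2)
  new_quench_fit(
    "exposure_fit",
    coefficients = c(L_n = unname(p[["L_n"]]), F_min = unname(p[["F_min"]])),
    se = c(L_n = unname(res$se[["L_n"]]), F_min = unname(res$se[["F_min"]])),
    data = series, fitted_values = yhat, gof = gof, flags = flags,
    extra = list(convergence = res$message)
  )
}

#' @export
predict.exposure_fit <- function(object, quencher_fraction = NULL, ...) {
  if (is.null(quencher_fraction)) return(object$fitted_values)
  cf <- object$coefficients
  exposure_model(quencher_fraction, 1, cf[["F_min"]], cf[["L_n"]])
}

plot_info.exposure_fit <- function(x) {
  list(x = x$data$quencher_fraction, y = x$data$response,
       yhat = x$fitted_values,
       xlab = "quencher mole fraction", ylab = "F/F0")
}

#' @export
simulate.exposure_fit <- function(object, nsim = 1, seed = NULL, ...) {
  cf <- object$coefficients
  if (!is.null(seed)) set.seed(seed)
  replicate(nsim, make_quenching_series(list(
    L_n = cf[["L_n"]], F_min = cf[["F_min"]],
    q_grid = object$data$quencher_fraction, noise_sd = 0
  )), simplify = FALSE)
}

#' Stern-Volmer representation of a quenching series
#'
#' Converts normalized responses to Stern-Volmer ratios: F0/F for
#' intensity data, tau0/tau for lifetime data.  The transformation is
#' a pointwise reciprocal, so applying it twice returns the original
#' series.
#'
#' @param series a [quenching_series()].
#' @return a `stern_volmer` data.frame with columns `quencher_fraction`
#'   and `ratio`; the `response_kind` attribute is propagated as
#'   `kind`.
#' @export
stern_volmer <- function(series) {
  if (inherits(series, "stern_volmer")) {
    # involution: back to a quenching series
    return(quenching_series(series$quencher_fraction, 1 / series$ratio,
                            response_kind = attr(series, "kind")))
  }
  if (!inherits(series, "quenching_series")) {
    series <- quenching_series(series$quencher_fraction, series$response)
  }
  mq_check(all(series$response > 0), "invalid_argument",
           "responses must be positive to form F0/F")
  out <- data.frame(quencher_fraction = series$quencher_fraction,
                    ratio = 1 / series$response)
  attr(out, "kind") <- attr(series, "response_kind")
  attr(out, "meta") <- attr(series, "meta")
  class(out) <- c("stern_volmer", "data.frame")
  out
}

#' Partition quenching into static and dynamic components
#'
#' Compares steady-state and lifetime Stern-Volmer series measured on
#' the same quencher grid.  Dynamic (collisional) quenching shortens
#' the lifetime, so tau0/tau tracks that component; whatever part of
#' F0/F it does not explain behaves as static quenching:
#'
#' `static(Q) = (F0/F) / (tau0/tau)`
#'
#' (the product rule `F0/F = static * dynamic`).  Values above 1 mean
#' apparent static quenching -- for sticholysins the steady-state
#' ratios far exceed the lifetime ratios, the signature of contact
#' quenching by boundary lipids.
#'
#' @param intensity a `stern_volmer` object of kind `"intensity"`.
#' @param lifetime a `stern_volmer` object of kind `"lifetime"` on the
#'   same quencher grid.
#' @return list with `quencher_fraction`, per-point `static_component`,
#'   `dynamic_component` (tau0/tau), and `static_geomean`, the
#'   geometric mean of the static component over points with
#'   quencher > 0.
#' @export
classify_quenching <- function(intensity, lifetime) {
  mq_check(inherits(intensity, "stern_volmer") &&
             inherits(lifetime, "stern_volmer"),
           "invalid_argument", "inputs must be stern_volmer objects")
  mq_check(length(intensity$quencher_fraction) ==
             length(lifetime$quencher_fraction) &&
             all(abs(intensity$quencher_fraction -
                       lifetime$quencher_fraction) < 1e-9),
           "invalid_argument",
           "intensity and lifetime series must share the quencher grid")
  static <- intensity$ratio / lifetime$ratio
  pos <- intensity$quencher_fraction > 0
  structure(
    list(quencher_fraction = intensity$quencher_fraction,
         static_component = static,
         dynamic_component = lifetime$ratio,
         static_geomean = exp(mean(log(static[pos])))),
    class = "quenching_partition"
  )
}

#' @export
print.quenching_partition <- function(x, ...) {
  cat("Static/dynamic quenching partition\n")
  print(data.frame(Q = x$quencher_fraction,
                   static = round(x$static_component, 4),
                   dynamic = round(x$dynamic_component, 4)))
  cat(sprintf("geometric-mean static component (Q > 0): %.4f\n",
              x$static_geomean))
  invisible(x)
}
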