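# Protein-vesicle binding isotherm: mass-action model for a protein
# monomer occupying n lipids, fitted to titrations of toxin with
# quencher-free LUVs.

#' Fraction of membrane-bound protein
#'
#' Closed-form solution of the mass-action equilibrium in which one
#' protein monomer binds the membrane every `n` lipids with association
#' constant `K_a`:
#'
#' theta = 1 - (1/2) * \[ 1 - L/(n P) - 1/(Ka P)
#'                        + sqrt( (L/(n P) + 1/(Ka P) - 1)^2 + 4/(Ka P) ) \]
#'
#' where `L` and `P` are the total lipid and protein concentrations.
#' The expression is the physical root of the binding quadratic; values
#' are clamped to \[0, 1\] only to absorb floating-point round-off
#' (tolerance 1e-12), never to mask a model error.
#'
#' @param lipid_total total lipid concentration (M), >= 0; vectorized.
#' @param protein_total total protein concentration (M), > 0.
#' @param n stoichiometry: lipids per bound monomer, > 0.
#' @param K_a association constant (1/M), > 0.
#' @return fraction of bound protein in \[0, 1\], same length as
#'   `lipid_total`.
#' @export
#' @examples
#' bound_fraction(1.2e-5, 1e-7, n = 60, K_a = 1e8)  # ~0.9155
bound_fraction <- function(lipid_total, protein_total, n, K_a) {
  check_finite(lipid_total, "lipid_total", nonneg = TRUE)
  check_finite(protein_total, "protein_total", positive = TRUE)
  check_finite(n, "n", positive = TRUE)
  check_finite(K_a, "K_a", positive = TRUE)
  a <- lipid_total / (n * protein_total)
  b <- 1 / (K_a * protein_total)
  theta <- 1 - 0.5 * (1 - a - b + sqrt((a + b - 1)^2 + 4 * b))
  mq_check(all(theta > -1e-12 & theta < 1 + 1e-12), "numerical",
           "bound fraction outside [0,1] beyond round-off")
  pmin(pmax(theta, 0), 1)
}

#' Dilution-corrected concentrations for a vesicle titration
#'
#' Tracks total protein and lipid concentrations as lipid stock is
#' added stepwise to the cuvette: protein is diluted by the cumulative
#' volume, lipid accumulates from each addition.  Protein mass is
#' conserved (`protein_total * V_cum` constant).
#'
#' @param initial_protein protein concentration before additions (M).
#' @param initial_volume starting sample volume (any unit, e.g. uL).
#' @param additions data.frame with columns `added_volume` (same unit
#'   as `initial_volume`) and `lipid_stock` (M); one row per addition.
#'   May have zero rows.
#' @return data.frame with one row per titration point (the initial
#'   point first) and columns `protein_total`, `lipid_total`,
#'   `volume`.
#' @export
correct_dilution <- function(initial_protein, initial_volume, additions) {
  check_finite(initial_protein, "initial_protein", positive = TRUE)
  check_finite(initial_volume, "initial_volume", positive = TRUE)
  mq_check(is.data.frame(additions) &&
             all(c("added_volume", "lipid_stock") %in% names(additions)),
           "invalid_argument",
           "additions needs columns added_volume and lipid_stock")
  if (nrow(additions)) {
    check_finite(additions$added_volume, "added_volume", positive = TRUE)
    check_finite(additions$lipid_stock, "lipid_stock", positive = TRUE)
  }
  v_cum <- initial_volume + c(0, cumsum(additions$added_volume))
  lipid_moles <- c(0, cumsum(additions$added_volume * additions$lipid_stock))
  data.frame(
    protein_total = initial_protein * initial_volume / v_cum,
    lipid_total = lipid_moles / v_cum,
    volume = v_cum
  )
}

# Signal model tying the bound fraction to the measured emission:
# F = F_sol * (1 + (F_b_ratio - 1) * theta).  Adopted because titration
# tables report the bound/free emission ratio alongside n and Ka.
binding_signal <- function(lipid_total, protein_total, n, K_a, F_sol,
                           F_b_ratio) {
  F_sol * (1 + (F_b_ratio - 1) *
             bound_fraction(lipid_total, protein_total, n, K_a))
}

#' Fit the vesicle-titration binding isotherm
#'
#' Non-linear least squares fit of the binding model to a titration
#' curve, with signal model `F = F_sol * (1 + (F_b/F_sol - 1) * theta)`.
#' Parameters: stoichiometry `n`, association constant `K_a` (fitted on
#' a log10 scale for conditioning), solution emission `F_sol`, and the
#' bound/solution emission ratio `F_b_ratio`.  Residuals are
#' unweighted.
#'
#' Starting values: `F_sol` from the lowest-lipid point, `n` from the
#' lipid/protein ratio at half-maximal signal, `K_a = 1e8`.  Bounds:
#' `n` in (1, 1e4), `K_a` in (1e4, 1e14).
#'
#' @param curve a [titration_curve()] (or data.frame with columns
#'   `protein_total`, `lipid_total`, `intensity`).
#' @return an object of class `c("binding_fit", "quench_fit")` with
#'   coefficients `n`, `K_a`, `F_sol`, `F_b_ratio`.  A curve that does
#'   not reach an estimated bound fraction of 0.8 is flagged
#'   `"no_saturation"`; an intensity range indistinguishable from noise
#'   is flagged `"degenerate"`.
#' @export
fit_binding <- function(curve) {
  if (!inherits(curve, "titration_curve")) {
    curve <- titration_curve(curve$protein_total, curve$lipid_total,
                             curve$intensity)
  }
  L <- curve$lipid_total
  P <- curve$protein_total
  y <- curve$intensity

  f0 <- y[which.min(L)]
  rng <- diff(range(y))
  flags <- character()
  if (rng <= 1e-9 * max(abs(y))) {
    # No response to lipid at all: the isotherm parameters are
    # unidentifiable.  Return a flagged degenerate result.
    gof <- goodness_of_fit(y, rep(mean(y), length(y)), n_par = 2)
    return(new_quench_fit(
      "binding_fit",
      coefficients = c(n = NA_real_, K_a = NA_real_, F_sol = mean(y),
                       F_b_ratio = 1),
      se = c(n = NA_real_, K_a = NA_real_, F_sol = sd(y) / sqrt(length(y)),
             F_b_ratio = NA_real_),
      data = curve, fitted_values = rep(mean(y), length(y)), gof = gof,
      flags = c("degenerate", "unidentifiable")
    ))
  }

  half <- f0 + rng / 2 * sign(y[which.max(L)] - f0)
  i_half <- which.min(abs(y - half))
  n0 <- max(L[i_half] / P[i_half], 2)
  r0 <- max(y[which.max(L)] / f0, 1.05)

  par0 <- c(n = n0, logKa = 8, F_sol = f0, F_b_ratio = r0)
  lower <- c(n = 1, logKa = 4, F_sol = 1e-12, F_b_ratio = 1e-3)
  upper <- c(n = 1e4, logKa = 14, F_sol = Inf, F_b_ratio = Inf)

  resid_fn <- function(p) {
    y - binding_signal(L, P, p[["n"]], 10^p[["logKa"]], p[["F_sol"]],
                       p[["F_b_ratio"]])
  }
  res <- mq_nlslm(par0, resid_fn, lower = lower, upper = upper)
  if (res$info == 0 || res$info == 5) {
    mq_stop("fit_failure",
            paste0("binding fit did not converge: ", res$message),
            last_par = res$par, deviance = res$deviance)
  }
  p <- res$par
  K_a <- 10^p[["logKa"]]
  yhat <- binding_signal(L, P, p[["n"]], K_a, p[["F_sol"]], p[["F_b_ratio"]])
  gof <- goodness_of_fit(y, yhat, n_par = 4)

  theta_hat <- bound_fraction(L, P, p[["n"]], K_a)
  if (max(theta_hat) < 0.8) flags <- c(flags, "no_saturation")

  # delta-method SE for K_a from the log10-scale SE
  se <- res$se
  se_Ka <- se[["logKa"]] * K_a * log(10)
  new_quench_fit(
    "binding_fit",
    coefficients = c(n = unname(p[["n"]]), K_a = K_a,
                     F_sol = unname(p[["F_sol"]]),
                     F_b_ratio = unname(p[["F_b_ratio"]])),
    se = c(n = unname(se[["n"]]), K_a = unname(se_Ka),
           F_sol = unname(se[["F_sol"]]),
           F_b_ratio = unname(se[["F_b_ratio"]])),
    data = curve, fitted_values = yhat, gof = gof, flags = flags,
    extra = list(theta = theta_hat, convergence = res$message)
  )
}

#' @export
predict.binding_fit <- function(object, lipid_total = NULL,
                                protein_total = NULL, ...) {
  cf <- object$coefficients
  if (is.null(lipid_total)) return(object$fitted_values)
  if (is.null(protein_total)) protein_total <- object$data$protein_total[1]
  binding_signal(lipid_total, protein_total, cf[["n"]], cf[["K_a"]],
                 cf[["F_sol"]], cf[["F_b_ratio"]])
}

plot_info.binding_fit <- function(x) {
  list(x = x$data$lipid_total / x$data$protein_total,
       y = x$data$intensity, yhat = x$fitted_values,
       xlab = "L/P molar ratio", ylab = "Trp emission (a.u.)")
}

#' @export
simulate.binding_fit <- function(object, nsim = 1, seed = NULL, ...) {
  cf <- object$coefficients
  if (!is.null(seed)) set.seed(seed)
  replicate(nsim, make_titration(list(
    n = cf[["n"]], K_a = cf[["K_a"]], F_sol = cf[["F_sol"]],
    F_b_ratio = cf[["F_b_ratio"]],
    protein_total = object$data$protein_total[1],
    lp_grid = object$data$lipid_total / object$data$protein_total,
    noise_cv = 0
  )), simplify = FALSE)
}

#' Lipid/protein ratio needed to reach a target bound fraction
#'
#' Solves the binding isotherm for the total lipid at which the bound
#' fraction equals `threshold`, and reports it as an L/P molar ratio.
#' Used e.g. to check that saturation is reached below L/P = 80 so that
#' subsequent quenching work can assume complete binding.
#'
#' @param fit a `binding_fit`, or a named list/vector with `n` and
#'   `K_a`.
#' @param threshold target bound fraction, in (0, 1).
#' @param protein_total total protein concentration (M).
#' @return the smallest L/P molar ratio achieving the threshold.
#' @export
saturation_lp_ratio <- function(fit, threshold, protein_total) {
  cf <- if (inherits(fit, "binding_fit")) fit$coefficients else unlist(fit)
  check_finite(threshold, "threshold")
  mq_check(threshold > 0 && threshold < 1, "invalid_argument",
           "threshold must be in (0, 1)")
  check_finite(protein_total, "protein_total", positive = TRUE)
  n <- cf[["n"]]; K_a <- cf[["K_a"]]
  check_finite(n, "n", positive = TRUE)
  check_finite(K_a, "K_a", positive = TRUE)
  f <- function(L) bound_fraction(L, protein_total, n, K_a) - threshold
  upper <- n * protein_total
  while (f(upper) < 0) {
    upper <- upper * 10
    if (upper > 1e6) {
      mq_stop("out_of_range", "threshold unreachable within solubility")
    }
  }
  root <- uniroot(f, lower = 0, upper = upper, tol = 1e-14)$root
  root / protein_total
}

#' Mean distance between membrane-bound particles
#'
#' Estimates the mean spacing of bound monomers (or oligomers) from
#' their surface density.  The area available per particle is
#' `A = oligomer_size * lipid_per_protein * lipid_area` (all lipids in
#' both leaflets count by default), the surface density is
#' `sigma = 1/A`, and the center-to-center distance is
#' `r_av = sqrt(1/sigma) / 2 = sqrt(A) / 2`.  The edge-to-edge distance
#' subtracts one protein diameter.
#'
#' @param lipid_per_protein L/P molar ratio.
#' @param lipid_area mean lipid cross-sectional area (A^2); membrane
#'   mixtures span roughly 45--60 A^2.
#' @param oligomer_size protomers per bound particle (1 for monomers,
#'   8 for the octameric pore).
#' @param protein_radius protein radius (A), used for the edge-to-edge
#'   distance.
#' @param leaflet `"both"` (default) counts all lipids toward the
#'   area per particle; `"outer"` counts only the binding leaflet
#'   (halves the area).
#' @return list with `center_to_center` and `edge_to_edge` distances
#'   (Angstrom) and the intermediate `area_per_particle` and
#'   `surface_density`.
#' @export
#' @examples
#' # monomers at L/P 180: edge-to-edge ~25 A; octamers: > 100 A apart
#' mean_interparticle_distance(180, 50, 1, 11)
#' mean_interparticle_distance(180, 50, 8, 11)
mean_interparticle_distance <- function(lipid_per_protein, lipid_area,
                                        oligomer_size = 1,
                                        protein_radius = 11,
                                        leaflet = c("both", "outer")) {
  leaflet <- match.arg(leaflet)
  check_finite(lipid_per_protein, "lipid_per_protein", positive = TRUE)
  check_finite(lipid_area, "lipid_area", positive = TRUE)
  mq_check(lipid_area >= 30 && lipid_area <= 80, "invalid_argument",
           "lipid_area outside the physically sane 30-80 A^2 range")
  check_finite(oligomer_size, "oligomer_size", positive = TRUE)
  check_finite(protein_radius, "protein_radius", positive = TRUE)
  area <- oligomer_size * lipid_per_protein * lipid_area
  if (leaflet == "outer") area <- area / 2
  sigma <- 1 / area
  r_av <- sqrt(1 / sigma) / 2
  list(center_to_center = r_av,
       edge_to_edge = r_av - 2 * protein_radius,
       area_per_particle = area,
       surface_density = sigma)
}
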