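# Synthetic-data generators: each one is the exact forward model of
# its consuming fitter, driven by a scenario library of published
# sticholysin parameter sets, so every pipeline stage can be exercised
# and validated without instrument data.

# --- scenario library -------------------------------------------------

# Published parameter sets for the two wild-type sticholysins and four
# mutants, in membranes with cholesterol (DOPC:PSM:Chol 70:15:15) and
# without (DOPC:PSM 80:20).  "CC" marks the oxidized double-cysteine
# mutants unable to deploy the N-terminal helix.
stn_param_tables <- function() {
  binding <- rbind(
    data.frame(variant = c("StnI", "StnI-CC", "StnII", "StnII-CC",
                           "StnII-W43/110F", "StnII-W43/114F"),
               composition = "chol",
               n = c(55.3, 67.7, 58.1, 61.5, 67.9, 79.1),
               K_a = c(4.1, 4.2, 6.7, 9.1, 1.2, 6.1) * 1e8,
               F_b_ratio = c(1.75, 1.94, 1.72, 1.84, 1.73, 1.74)),
    data.frame(variant = c("StnI", "StnI-CC", "StnII", "StnII-CC",
                           "StnII-W43/110F"),
               composition = "nochol",
               n = c(63.2, 54.2, 60.8, 42.1, 60.0),
               K_a = c(1.1, 7.5, 0.4, 2.1, 0.5) * 1e8,
               F_b_ratio = c(1.45, 1.56, 1.25, 1.50, 1.28))
  )
  exposure <- rbind(
    data.frame(variant = c("StnI", "StnI-CC", "StnII", "StnII-CC",
                           "StnII-W43/110F", "StnII-W43/114F"),
               composition = "chol",
               L_n = c(2.49, 2.16, 1.15, 1.22, 2.40, 3.20),
               F_min = c(0.72, 0.64, 0.76, 0.53, 0.89, 0.64)),
    data.frame(variant = c("StnI", "StnI-CC", "StnII", "StnII-CC",
                           "StnII-W43/110F"),
               composition = "nochol",
               L_n = c(2.38, 3.26, 7.15, 3.06, 9.34),
               F_min = c(0.79, 0.67, 0.79, 0.75, 0.89))
  )
  depth <- rbind(
    data.frame(variant = c("StnI", "StnI-CC", "StnII", "StnII-CC",
                           "StnII-W43/110F", "StnII-W43/114F"),
               composition = "chol",
               h_m = c(15.0, 16.0, 15.6, 19.0, 15.5, 12.2),
               sigma = c(7.1, 8.9, 9.6, 11.6, 3.8, 8.2),
               S = c(5.2, 10.1, 5.3, 11.4, 2.3, 6.9)),
    data.frame(variant = c("StnI", "StnII", "StnII-CC", "StnII-W43/110F"),
               composition = "nochol",
               h_m = c(12.9, 13.1, 19.2, 13.5),
               sigma = c(6.6, 8.2, 13.0, 4.0),
               S = c(3.1, 5.3, 9.7, 3.1))
  )
  list(binding = binding, exposure = exposure, depth = depth)
}

#' Scenario library of sticholysin parameter sets
#'
#' One scenario per (toxin variant, membrane composition) pair, each
#' holding the published generating parameters for every data kind the
#' package simulates: the binding isotherm (`n`, `K_a`, `F_b_ratio`),
#' the boundary-lipid contact model (`L_n`, `F_min`), the
#' depth-distribution model (`h_m`, `sigma`, `S`), lifetime components
#' (`alpha`, `tau`, about 8/3/1.5 ns), and binding kinetics (`alpha1 ~
#' 0.85`, `tau1 = 3 s`, `tau2 = 60 s`).  Rows missing from the source
#' tables (variants that do not bind a composition) carry `NA` for that
#' stage.
#'
#' @param variant optional variant name (e.g. `"StnI"`, `"StnII"`,
#'   `"StnII-CC"`, `"StnII-W43/110F"`) to select a single scenario.
#' @param composition `"chol"` (DOPC:PSM:Chol 70:15:15) or `"nochol"`
#'   (DOPC:PSM 80:20).
#' @return with no arguments, a named list of all scenarios; otherwise
#'   the single matching scenario: a list with elements `name`,
#'   `variant`, `composition`, `binding`, `exposure`, `depth`,
#'   `lifetimes`, `kinetics`.
#' @export
#' @examples
#' stn_scenarios("StnI", "chol")$binding
#' names(stn_scenarios())
stn_scenarios <- function(variant = NULL, composition = NULL) {
  tabs <- stn_param_tables()
  combos <- unique(rbind(tabs$binding[c("variant", "composition")],
                         tabs$exposure[c("variant", "composition")],
                         tabs$depth[c("variant", "composition")]))
  pick <- function(tab, v, comp) {
    row <- tab[tab$variant == v & tab$composition == comp, , drop = FALSE]
    if (!nrow(row)) return(NULL)
    as.list(row[1, setdiff(names(row), c("variant", "composition"))])
  }
  scen <- lapply(seq_len(nrow(combos)), function(i) {
    v <- combos$variant[i]; comp <- combos$composition[i]
    list(name = paste(v, comp, sep = "_"),
         variant = v, composition = comp,
         binding = pick(tabs$binding, v, comp),
         exposure = pick(tabs$exposure, v, comp),
         depth = pick(tabs$depth, v, comp),
         lifetimes = list(alpha = c(0.2, 0.3, 0.5), tau = c(8, 3, 1.5)),
         kinetics = list(alpha1 = 0.85, tau1 = 3, tau2 = 60,
                         F_inf = 1.6, F_0_level = 1))
  })
  names(scen) <- vapply(scen, `[[`, "", "name")
  if (is.null(variant)) return(scen)
  mq_check(!is.null(composition), "invalid_argument",
           "give both variant and composition, or neither")
  key <- paste(variant, composition, sep = "_")
  mq_check(key %in% names(scen), "invalid_argument",
           sprintf("unknown scenario '%s'", key))
  scen[[key]]
}

# --- generators -------------------------------------------------------

#' Simulate a vesicle-titration curve
#'
#' Forward model of the binding isotherm plus signal model: emission
#' `F = F_sol * (1 + (F_b_ratio - 1) * theta(L, P))` over an L/P grid,
#' with optional multiplicative Gaussian noise.
#'
#' @param config list with `n`, `K_a`, `F_b_ratio` (e.g. the `binding`
#'   element of a [stn_scenarios()] entry) and optionally `F_sol`
#'   (default 1), `protein_total` (default 1e-7 M), `lp_grid` (default
#'   25 points spanning L/P 0--300), `noise_cv` (coefficient of
#'   variation of multiplicative noise; default 0), `seed`.
#' @return a [titration_curve()].
#' @export
make_titration <- function(config) {
  cfg <- modifyList(list(F_sol = 1, protein_total = 1e-7,
                         lp_grid = seq(0, 300, length.out = 25),
                         noise_cv = 0, seed = NULL), config)
  mq_check(!(cfg$noise_cv > 0 && is.null(cfg$seed)), "invalid_argument",
           "stochastic generation requires a seed")
  P <- rep(cfg$protein_total, length(cfg$lp_grid))
  L <- cfg$lp_grid * cfg$protein_total
  y <- binding_signal(L, P, cfg$n, cfg$K_a, cfg$F_sol, cfg$F_b_ratio)
  if (cfg$noise_cv > 0) {
    set.seed(cfg$seed)
    y <- y * (1 + rnorm(length(y), sd = cfg$noise_cv))
  }
  titration_curve(P, L, y,
                  meta = list(generator = "make_titration", config = cfg))
}

#' Simulate a boundary-lipid quenching series
#'
#' Forward model of [exposure_model()] on a quencher-fraction grid,
#' normalized to 1 at zero quencher, with optional additive Gaussian
#' noise (the zero point stays exactly 1 so the container invariant
#' holds, as it would after experimental normalization).
#'
#' @param config list with `L_n`, `F_min`, and optionally `q_grid`
#'   (default 0 to 0.7 in steps of 0.1), `noise_sd` (default 0),
#'   `seed`.
#' @return a [quenching_series()].
#' @export
make_quenching_series <- function(config) {
  cfg <- modifyList(list(q_grid = seq(0, 0.7, by = 0.1), noise_sd = 0,
                         seed = NULL), config)
  mq_check(!(cfg$noise_sd > 0 && is.null(cfg$seed)), "invalid_argument",
           "stochastic generation requires a seed")
  y <- exposure_model(cfg$q_grid, 1, cfg$F_min, cfg$L_n)
  if (cfg$noise_sd > 0) {
    set.seed(cfg$seed)
    y <- y + rnorm(length(y), sd = cfg$noise_sd)
    y[cfg$q_grid == 0] <- 1
    y <- pmax(y, 1e-6)
  }
  quenching_series(cfg$q_grid, y, response_kind = "intensity",
                   meta = list(generator = "make_quenching_series",
                               config = cfg))
}

#' Simulate a depth-dependent quenching profile
#'
#' Forward model of [depth_model()] evaluated at the quencher-catalog
#' depths, with optional additive Gaussian noise on QP (floored at 0).
#'
#' @param config list with `h_m`, `sigma`, `S`, and optionally
#'   `depths` (default [quencher_depths()]), `noise_sd` (default 0),
#'   `seed`.
#' @return a [depth_profile()].
#' @export
make_depth_profile <- function(config) {
  cfg <- modifyList(list(depths = unname(quencher_depths()),
                         noise_sd = 0, seed = NULL), config)
  mq_check(!(cfg$noise_sd > 0 && is.null(cfg$seed)), "invalid_argument",
           "stochastic generation requires a seed")
  qp <- depth_model(cfg$depths, cfg$h_m, cfg$sigma, cfg$S)
  if (cfg$noise_sd > 0) {
    set.seed(cfg$seed)
    qp <- pmax(qp + rnorm(length(qp), sd = cfg$noise_sd), 0)
  }
  depth_profile(cfg$depths, qp,
                meta = list(generator = "make_depth_profile", config = cfg))
}

# Gaussian synthetic IRF emulating a pulsed-diode-laser TCSPC response
# (FWHM ~0.5 ns).  Used both to generate decays and as the packaged
# reconvolution kernel when no measured IRF is available.
synthetic_irf <- function(t, t0 = 2, fwhm = 0.5, peak = 10000) {
  s <- fwhm / (2 * sqrt(2 * log(2)))
  y <- exp(-(t - t0)^2 / (2 * s^2))
  y / max(y) * peak
}

#' Simulate a TCSPC decay trace
#'
#' Convolves a multi-exponential decay with a Gaussian synthetic IRF
#' (FWHM 0.5 ns), scales to the target peak counts, and draws Poisson
#' counts per channel.  The IRF channel is itself Poisson-sampled at
#' its own peak target, as an acquired scatter trace would be.
#'
#' @param config list with `alpha` (amplitude fractions), `tau`
#'   (lifetimes, ns) and optionally `peak_counts` (default 12000),
#'   `irf_peak` (default 10000), `t_max` (default 45 ns), `dt`
#'   (default 0.025 ns), `irf_t0` (default 2 ns), `irf_fwhm`
#'   (default 0.5 ns), `baseline` (default 0 expected counts per
#'   channel), `poisson` (default TRUE), `seed`.
#' @return a [decay_trace()].
#' @export
make_decay <- function(config) {
  cfg <- modifyList(list(peak_counts = 12000, irf_peak = 10000,
                         t_max = 45, dt = 0.025, irf_t0 = 2,
                         irf_fwhm = 0.5, baseline = 0, poisson = TRUE,
                         seed = NULL), config)
  mq_check(!(isTRUE(cfg$poisson) && is.null(cfg$seed)), "invalid_argument",
           "stochastic generation requires a seed")
  mq_check(abs(sum(cfg$alpha) - 1) < 1e-9, "invalid_argument",
           "amplitude fractions must sum to 1")
  t <- seq(0, cfg$t_max, by = cfg$dt)
  irf_ideal <- synthetic_irf(t, cfg$irf_t0, cfg$irf_fwhm, cfg$irf_peak)
  dec <- decay_shape(t, cfg$alpha, cfg$tau)
  mdl <- pmax(irf_convolve(irf_ideal / sum(irf_ideal), dec), 0)
  mdl <- mdl / max(mdl) * cfg$peak_counts + cfg$baseline
  if (isTRUE(cfg$poisson)) {
    set.seed(cfg$seed)
    counts <- rpois(length(t), mdl)
    irf_counts <- rpois(length(t), irf_ideal)
  } else {
    counts <- mdl
    irf_counts <- irf_ideal
  }
  decay_trace(t, counts, irf_counts,
              meta = list(generator = "make_decay", config = cfg))
}

#' Simulate a binding-kinetics trace
#'
#' Rise-to-plateau double exponential with optional additive Gaussian
#' noise.
#'
#' @param config list with `alpha1`, `tau1`, `tau2` and optionally
#'   `F_inf` (default 1.6), `F_0_level` (default 1), `t_grid` (default
#'   0--300 s, 151 points), `noise_sd` (default 0), `seed`.
#' @return a [kinetic_trace()].
#' @export
make_kinetic_trace <- function(config) {
  cfg <- modifyList(list(F_inf = 1.6, F_0_level = 1,
                         t_grid = seq(0, 300, length.out = 151),
                         noise_sd = 0, seed = NULL), config)
  mq_check(!(cfg$noise_sd > 0 && is.null(cfg$seed)), "invalid_argument",
           "stochastic generation requires a seed")
  A_tot <- cfg$F_inf - cfg$F_0_level
  A1 <- cfg$alpha1 * A_tot
  A2 <- (1 - cfg$alpha1) * A_tot
  y <- kinetic_model(cfg$t_grid, cfg$F_inf, A1, A2, cfg$tau1, cfg$tau2)
  if (cfg$noise_sd > 0) {
    set.seed(cfg$seed)
    y <- y + rnorm(length(y), sd = cfg$noise_sd)
  }
  kinetic_trace(cfg$t_grid, y,
                meta = list(generator = "make_kinetic_trace", config = cfg))
}

#' Simulate a tryptophan emission spectrum
#'
#' Gaussian emission band plus an optional scattering blank (a
#' Rayleigh-type tail from the excitation side), with optional
#' additive noise.  The blank is returned alongside the spectrum so
#' that [correct_scattering()] can be exercised.
#'
#' @param config list with optionally `center` (default 335 nm),
#'   `fwhm` (default 55 nm), `amplitude` (default 1), `wl_grid`
#'   (default 305--450 nm at 1 nm), `blank_amp` (scattering amplitude
#'   at 305 nm; default 0), `noise_sd` (default 0), `seed`.
#' @return an [emission_spectrum()] with a `blank` column when
#'   `blank_amp > 0`.
#' @export
make_spectrum <- function(config = list()) {
  cfg <- modifyList(list(center = 335, fwhm = 55, amplitude = 1,
                         wl_grid = seq(305, 450, by = 1),
                         blank_amp = 0, noise_sd = 0, seed = NULL), config)
  mq_check(!(cfg$noise_sd > 0 && is.null(cfg$seed)), "invalid_argument",
           "stochastic generation requires a seed")
  s <- cfg$fwhm / (2 * sqrt(2 * log(2)))
  band <- cfg$amplitude * exp(-(cfg$wl_grid - cfg$center)^2 / (2 * s^2))
  blank <- if (cfg$blank_amp > 0) {
    cfg$blank_amp * (305 / cfg$wl_grid)^8  # steep scattering tail
  } else NULL
  y <- band + (blank %||% 0)
  if (cfg$noise_sd > 0) {
    set.seed(cfg$seed)
    y <- y + rnorm(length(y), sd = cfg$noise_sd)
  }
  emission_spectrum(cfg$wl_grid, y, blank = blank,
                    meta = list(generator = "make_spectrum", config = cfg))
}
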