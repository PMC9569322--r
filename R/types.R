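# Validated data containers.  Each is a data.frame with a subclass tag
# and a `meta` attribute; constructors enforce the invariants the
# fitters rely on.

#' Titration curve: fluorescence versus added lipid
#'
#' Holds one protein-vesicle titration: total protein and total lipid
#' concentration per point (both dilution-corrected, in molar units)
#' and the measured tryptophan emission.
#'
#' @param protein_total molar protein concentration per point (M), > 0.
#' @param lipid_total molar lipid concentration per point (M),
#'   non-decreasing; the first point may be 0.
#' @param intensity fluorescence emission per point (arbitrary units).
#' @param meta optional list of metadata (e.g. `composition`,
#'   `temperature_C`, `variant`).
#' @return a `titration_curve` data.frame.
#' @export
titration_curve <- function(protein_total, lipid_total, intensity,
                            meta = list()) {
  check_finite(protein_total, "protein_total", positive = TRUE)
  check_finite(lipid_total, "lipid_total", nonneg = TRUE)
  check_finite(intensity, "intensity")
  n <- length(intensity)
  mq_check(length(protein_total) == n && length(lipid_total) == n,
           "invalid_argument", "titration arrays must have equal length")
  mq_check(n >= 5, "invalid_argument",
           "a titration curve needs at least 5 points")
  mq_check(all(diff(lipid_total) >= 0), "validation",
           "lipid_total must be non-decreasing across points")
  out <- data.frame(protein_total = protein_total,
                    lipid_total = lipid_total,
                    intensity = intensity)
  attr(out, "meta") <- meta
  class(out) <- c("titration_curve", "data.frame")
  out
}

#' Quenching series: normalized emission versus quencher mole fraction
#'
#' @param quencher_fraction mole fraction of spin-labeled lipid in the
#'   membrane, strictly increasing, first point 0.
#' @param response normalized emission F/F0 (or lifetime ratio tau/tau0).
#'   The first point must be 1 within 1e-6.
#' @param response_kind `"intensity"` or `"lifetime"`.
#' @param meta optional metadata list.
#' @return a `quenching_series` data.frame.
#' @export
quenching_series <- function(quencher_fraction, response,
                             response_kind = c("intensity", "lifetime"),
                             meta = list()) {
  response_kind <- match.arg(response_kind)
  check_finite(quencher_fraction, "quencher_fraction", nonneg = TRUE)
  check_finite(response, "response", positive = TRUE)
  mq_check(length(quencher_fraction) == length(response),
           "invalid_argument", "array lengths differ")
  mq_check(all(diff(quencher_fraction) > 0), "validation",
           "quencher_fraction must be strictly increasing")
  mq_check(quencher_fraction[1] == 0, "validation",
           "first point must have quencher_fraction = 0")
  mq_check(all(quencher_fraction <= 1), "validation",
           "quencher_fraction must be a mole fraction in [0, 1]")
  mq_check(abs(response[1] - 1) <= 1e-6, "validation",
           "response must be normalized to 1 at zero quencher")
  out <- data.frame(quencher_fraction = quencher_fraction,
                    response = response)
  attr(out, "meta") <- meta
  attr(out, "response_kind") <- response_kind
  class(out) <- c("quenching_series", "data.frame")
  out
}

#' Depth-dependent quenching profile
#'
#' Quenching-profile values QP(h) = F0/F - 1 measured with quenchers at
#' known depths `h` from the bilayer center.
#'
#' @param quencher_depth depth of each quencher label from the bilayer
#'   center (Angstrom, > 0).
#' @param qp quenching-profile value per point, >= 0.
#' @param include logical mask of points to use when fitting (supports
#'   the "discarded data" alternative fits); defaults to all.
#' @param exclude_reason optional character reasons, recorded for
#'   excluded points.
#' @param meta optional metadata list.
#' @return a `depth_profile` data.frame.
#' @export
depth_profile <- function(quencher_depth, qp, include = NULL,
                          exclude_reason = NULL, meta = list()) {
  check_finite(quencher_depth, "quencher_depth", positive = TRUE)
  check_finite(qp, "qp", nonneg = TRUE)
  n <- length(qp)
  mq_check(length(quencher_depth) == n, "invalid_argument",
           "array lengths differ")
  if (is.null(include)) include <- rep(TRUE, n)
  mq_check(is.logical(include) && length(include) == n,
           "invalid_argument", "include mask must be logical, same length")
  out <- data.frame(quencher_depth = quencher_depth, qp = qp,
                    include = include)
  attr(out, "meta") <- meta
  attr(out, "exclude_reason") <- exclude_reason
  class(out) <- c("depth_profile", "data.frame")
  out
}

#' TCSPC decay trace
#'
#' @param channel_time time per bin (ns), strictly increasing, uniform
#'   spacing.
#' @param counts photon counts per bin (non-negative integers).
#' @param irf_counts instrument-response counts per bin (same grid).
#' @param meta optional metadata list.
#' @return a `decay_trace` data.frame.
#' @export
decay_trace <- function(channel_time, counts, irf_counts, meta = list()) {
  check_finite(channel_time, "channel_time")
  check_finite(counts, "counts", nonneg = TRUE)
  check_finite(irf_counts, "irf_counts", nonneg = TRUE)
  n <- length(channel_time)
  mq_check(length(counts) == n && length(irf_counts) == n,
           "invalid_argument", "array lengths differ")
  dt <- diff(channel_time)
  mq_check(all(dt > 0), "validation", "channel_time must be increasing")
  mq_check(max(dt) - min(dt) < 1e-9 * mean(dt) + 1e-12, "validation",
           "channel spacing must be uniform")
  out <- data.frame(channel_time = channel_time, counts = counts,
                    irf_counts = irf_counts)
  attr(out, "meta") <- meta
  class(out) <- c("decay_trace", "data.frame")
  out
}

#' Binding kinetics trace
#'
#' Time course of tryptophan emission (330 nm, 295 nm excitation) after
#' vesicle addition.
#'
#' @param time time per point (s), increasing; at least 20 points.
#' @param intensity emission per point (a.u.).
#' @param meta optional metadata list.
#' @return a `kinetic_trace` data.frame.
#' @export
kinetic_trace <- function(time, intensity, meta = list()) {
  check_finite(time, "time")
  check_finite(intensity, "intensity")
  mq_check(length(time) == length(intensity), "invalid_argument",
           "array lengths differ")
  mq_check(length(time) >= 20, "invalid_argument",
           "a kinetic trace needs at least 20 points")
  mq_check(all(diff(time) > 0), "validation", "time must be increasing")
  out <- data.frame(time = time, intensity = intensity)
  attr(out, "meta") <- meta
  class(out) <- c("kinetic_trace", "data.frame")
  out
}

#' Emission spectrum
#'
#' @param wavelength nm, strictly increasing at uniform step
#'   (305--450 nm at 1 nm is typical).
#' @param intensity emission per wavelength (a.u.), finite.
#' @param blank optional matched scattering-blank intensities on the
#'   same grid.
#' @param meta optional metadata list.
#' @return an `emission_spectrum` data.frame.
#' @export
emission_spectrum <- function(wavelength, intensity, blank = NULL,
                              meta = list()) {
  check_finite(wavelength, "wavelength", positive = TRUE)
  check_finite(intensity, "intensity")
  n <- length(wavelength)
  mq_check(length(intensity) == n, "invalid_argument",
           "array lengths differ")
  dl <- diff(wavelength)
  mq_check(all(dl > 0), "validation", "wavelength must be increasing")
  mq_check(max(dl) - min(dl) < 1e-6 * mean(dl) + 1e-9, "validation",
           "wavelength step must be uniform")
  out <- data.frame(wavelength = wavelength, intensity = intensity)
  if (!is.null(blank)) {
    check_finite(blank, "blank")
    mq_check(length(blank) == n, "invalid_argument",
             "blank must match the wavelength grid")
    out$blank <- blank
  }
  attr(out, "meta") <- meta
  class(out) <- c("emission_spectrum", "data.frame")
  out
}

#' Default spin-label quencher depth catalog
#'
#' Depths of the doxyl/TEMPO quencher groups from the bilayer center,
#' measured in pure POPC bilayers -- the best available approximation
#' for the mixed membranes usually studied.  Values can be overridden
#' per composition via the `override` argument.
#'
#' @param override optional named numeric vector of replacement or
#'   additional label depths (Angstrom).
#' @return named numeric vector, label -> depth from bilayer center (A).
#' @export
#' @examples
#' quencher_depths()
#' quencher_depths(override = c(`5-SLPC` = 12.5))
quencher_depths <- function(override = NULL) {
  depths <- c(`TEMPO-PC` = 18.2, `5-SLPC` = 12.1, `7-SLPC` = 11.5,
              `10-SLPC` = 10.1, `12-SLPC` = 6.4, `14-SLPC` = 2.9)
  if (!is.null(override)) {
    check_finite(override, "override", positive = TRUE)
    mq_check(!is.null(names(override)) && all(nzchar(names(override))),
             "invalid_argument", "override must be a named vector")
    depths[names(override)] <- override
  }
  mq_check(!anyDuplicated(names(depths)), "invalid_argument",
           "quencher names must be unique")
  depths
}
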