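---
title: "Models and methods: membrane binding and tryptophan quenching analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: membrane binding and tryptophan quenching analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memquench)
```

memquench implements the quantitative fluorescence analyses used to
characterise how alpha-pore-forming toxins such as the sticholysins
(StnI, StnII, from *Stichodactyla helianthus*) interact with lipid
membranes.  The experimental readout throughout is the intrinsic
tryptophan emission of the toxin: it rises on membrane binding, and it
is quenched on contact with doxyl- or TEMPO-labeled
phosphatidylcholine (PC) analogues placed in the bilayer.  Three core
models turn those signals into numbers; a layer of supporting
photophysics keeps the inputs honest; and a synthetic-data module
generates every data kind from known parameters so each fitter can be
validated end to end.

## The binding isotherm

Titrating toxin (typically 100 nM) with quencher-free large
unilamellar vesicles (LUVs) raises the tryptophan emission toward a
plateau.  We model one protein monomer occupying a patch of $n$
lipids with association constant $K_a$ (M$^{-1}$).  Mass action gives
the bound fraction in closed form:

$$\theta(L_T, P_T) = 1 - \tfrac{1}{2}\Big[\,1 - \tfrac{L_T}{nP_T}
  - \tfrac{1}{K_a P_T} + \sqrt{\big(\tfrac{L_T}{nP_T} +
  \tfrac{1}{K_a P_T} - 1\big)^2 + \tfrac{4}{K_a P_T}}\,\Big],$$

with $L_T$, $P_T$ the total lipid and protein concentrations,
dilution-corrected for each LUV addition (`correct_dilution()`).
`bound_fraction()` is the exact physical root of the underlying
quadratic; the test suite verifies it against an independent numeric
mass-action solver to below $10^{-9}$ across a 20 x 20 grid of lipid
and affinity values.

The instrument measures intensity, not $\theta$.  Published tables
report the emission increase $F_b/F_{sol}$ alongside $n$ and $K_a$, so
the signal model is taken as linear in the bound fraction,

$$F = F_{sol}\,\big(1 + (F_b/F_{sol} - 1)\,\theta\big),$$

and `fit_binding()` fits $(n, K_a, F_{sol}, F_b/F_{sol})$ to the raw
intensities by unweighted nonlinear least squares (no weighting scheme
is stated for the source experiments, and titration points have
similar counting statistics).  $K_a$ is fitted on a log10 scale for
conditioning, with bounds $n \in (1, 10^4)$ and
$K_a \in (10^4, 10^{14})$ M$^{-1}$; starting values are $F_{sol}$ from
the zero-lipid point, $n$ from the lipid/protein ratio at half-maximal
signal, and $K_a = 10^8$ M$^{-1}$.  These starts converge across the
whole published parameter range (affinities 0.4-9.1 x 10^8 M^-1,
stoichiometries 42-79).  A fit whose estimated bound fraction never
reaches 0.8 is flagged `no_saturation`; a flat curve returns a flagged
degenerate result rather than an arbitrary parameter vector.

Two small utilities round this module out.  `saturation_lp_ratio()`
root-solves the isotherm for the lipid-to-protein ratio reaching a
target bound fraction -- under the published StnI parameters the
emission is >95% saturated below L/P = 80, which is what makes an
L/P of 120 a safe background for the quenching work.
`mean_interparticle_distance()` converts an L/P ratio and a mean lipid
cross-sectional area (45-60 A^2 depending on composition; default
50 A^2) into the mean spacing of bound particles.  We compute the
area per particle $A$ = oligomer size x L/P x lipid area, surface
density $\sigma = 1/A$, and center-to-center distance
$r_{av} = \sqrt{1/\sigma}/2$.  Note the dimensional point: a distance
must scale as $\sqrt{A}$, i.e. $\sqrt{1/\sigma}$, not $\sqrt{\sigma}$;
implemented this way the formula reproduces the ~25 A edge-to-edge
monomer spacing (protein radius 11 A, subtracted once per neighbouring
protein) and >100 A octamer spacing quoted for these systems.  Both
leaflets count toward the area per particle by default
(`leaflet = "both"`), which is the convention under which those quoted
distances come out; `leaflet = "outer"` is available.  The protein
radius is a parameter because no value is printed in the sources the
estimate comes from.

## Boundary-lipid contacts from quenching

With binding saturated, increasing the mole fraction $[Q]$ of
spin-labeled PC in the membrane quenches the emission of the
membrane-inserted tryptophans on contact.  Treating the $L_n$ lipid
sites adjacent to the accessible fluorophores as independently and
randomly occupied by quencher lipid with probability $[Q]$, the
surviving emission is

$$F([Q]) = (F_0 - F_{min})\,(1 - [Q])^{L_n} + F_{min},$$

where $F_{min}$ is the emission left in pure quencher lipid -- the
inaccessible population (buried tryptophans and those shielded by
protein-protein or protein-lipid contacts).  `fit_exposure()` fits
$(L_n, F_{min})$ to normalized series with $F_0$ fixed at 1: the data
are normalized to their zero-quencher point, so a free overall scale
would be redundant.  $[Q]$ is handled as a mole fraction in $[0,1]$
internally (the $(1-[Q])$ term only makes sense for fractions); the
CSV reader accepts mol% columns and converts, with a `fraction`
override.  Initialization is $F_{min} = \min(F/F_0)$, $L_n = 2$, with
bounds $L_n \in (0.01, 50)$, $F_{min} \in [0, 1)$.  The accessibility
readout is $F_{min}$ itself; no extra accessible-fraction parameter is
introduced.

The identifiability of $L_n$ degrades as it grows: a curve with many
contact sites saturates within the first few quencher steps, leaving
few informative points.  The tests quantify this with additive noise
(sd 0.01 on $F/F_0$): the median relative error at $L_n \approx 2.4$
stays under 15%, and is smaller than at $L_n \approx 9.3$, mirroring
the large uncertainties published for the high-$L_n$ rows.  This is a
property of the model, not of the optimizer.

`stern_volmer()` converts a series to $F_0/F$ (or $\tau_0/\tau$ for
lifetime data) for display and comparison, and
`classify_quenching()` forms the pointwise ratio
$(F_0/F)/(\tau_0/\tau)$: dynamic (collisional) quenching shortens the
lifetime, so whatever steady-state quenching the lifetime ratio does
not explain behaves as static quenching.  For sticholysins the
steady-state ratios far exceed the lifetime ratios -- contact
quenching by essentially immobile boundary lipids appears static even
though the underlying mechanism is collisional.  Eq.-2-type analysis
is therefore applied to steady-state data only; lifetime series are
kept to Stern-Volmer display.  A partially accessible population also
bends $F_0/F$ away from linearity; the suite checks the always-true
form of that statement (the two-population curve lies below the
fully-accessible one and below $1/F_{min}$) and visible downward
curvature over the upper quencher range when $L_n \ge 2$ -- at
$L_n \approx 1$ the curvature is genuinely not downward, which matches
the hedged way the effect is reported for those rows.

## Depth of the tryptophans: distribution analysis

Placing the quencher at different positions along the PC acyl chains
(or on the headgroup) samples the quenching profile
$QP(h) = F_0/F - 1$ at known depths $h$ from the bilayer center.  The
label catalog, measured in pure POPC bilayers (the best available
approximation, overridable per composition via
`quencher_depths(override=)`): TEMPO-PC 18.2, 5-SLPC 12.1, 7-SLPC
11.5, 10-SLPC 10.1, 12-SLPC 6.4, 14-SLPC 2.9 A.

The distribution analysis models the transverse position of the
fluorophore as Gaussian with mean depth $h_m$, width $\sigma$, and
area $S$ (accessibility), mirrored about the bilayer center to account
for trans-leaflet quenching of deep fluorophores:

$$QP(h) = \frac{S}{\sigma\sqrt{2\pi}}\left[
  e^{-\frac{(h-h_m)^2}{2\sigma^2}} +
  e^{-\frac{(h+h_m)^2}{2\sigma^2}}\right].$$

The deviations in the exponents are squared -- a non-squared deviation
does not define a Gaussian, breaks the $QP(h) = QP(-h)$ symmetry of
the mirrored form, and integrates to nothing meaningful; with squared
deviations the profile integrates to exactly $2S$, which the tests
verify by quadrature to $10^{-6}$ relative error.  The code refers to
the model by name (mirrored-Gaussian distribution analysis) rather
than by an equation number.  Because $\pm h_m$ give identical
profiles, $h_m \ge 0$ is the canonical branch (tie-break).

`fit_depth()` estimates $(h_m, \sigma, S)$ by least squares, starting
from a coarse grid scan so the gradient refinement cannot be captured
by a wrong basin; `depth_grid_search()` also serves as an exhaustive
0.1-A-step oracle over $h_m \in [0,25]$, $\sigma \in [1,15]$,
$S \in [0.5,15]$ (the model is linear in $S$, which makes the ~5
million grid points cheap).  One caveat the tests make explicit: when
$h_m$ is small relative to $\sigma$ the two mirrored Gaussians merge
and the parameters stop being separately identifiable from six sample
depths -- along that ridge only the global SSE, not the individual
parameters, is a meaningful comparison between optimizers.  The
published fits all sit in the identifiable regime.

Points can be excluded from a fit through the `include` mask of
`depth_profile()`, with a recorded reason -- supporting the alternative
"discarded data" analyses used when a point deviates from the trend or
is inconsistent across variants.  The exclusions and reasons are
carried on the fit object, so a report shows exactly what was dropped.
For profiles too weak to constrain the model on their own,
`fit_depth(start=)` accepts a warm start from another fit (e.g. the
same variant in a different membrane system); this reproduces the
guidance mechanism described for the one published row whose
unconstrained fit failed, without claiming to reproduce its exact
procedure, which is unstated.  `compare_depths()` differences two
fitted $h_m$ values with uncertainties combined in quadrature -- the
cholesterol-removal comparison (~2 A deeper without Chol for the
wild-type toxins) is one subtraction of two such fits.

## Supporting photophysics

**TCSPC lifetimes.**  `fit_decay()` fits multi-exponential decays by
iterative reconvolution: the model is the measured instrument response
convolved with $\sum_i A_i e^{-t/\tau_i}$ plus a constant baseline.
The packaged synthetic IRF is Gaussian with 0.5 ns FWHM, the class of
response produced by a ~297 nm pulsed diode laser; `make_decay()`
Poisson-samples both the decay (12,000 peak counts) and the IRF
(10,000 peak counts), as acquired scatter traces would be.  The
default channel width is 25 ps, a typical hardware resolution for
this instrument class (peak counts, not channel width, are what the
acquisition protocol fixes).  Weighting is Poisson, and here a
numerical choice matters: weights taken from the observed counts
(Neyman, `weighting = "neyman"`) systematically bias poorly determined
lifetimes low -- a few percent on the middle component of an
8/3/1.5 ns triple decay at these counts -- because upward fluctuations
are downweighted.  The default is therefore iterated model-based
(Pearson) weighting, which removes that bias at identical cost.
Sticholysin decays need three components (about 8, 3 and 1.5 ns);
adjacent fitted lifetimes within 20% of each other are flagged
`component_collapse` (use fewer components), and a lifetime collapsing
to the channel width flags `degenerate`.  Single-trace recovery of the
middle lifetime is Fisher-information-limited to roughly 7% scatter at
12,000 peak counts, so recovery checks average the fitted lifetimes
over 10 seeded replicate decays, an enlarged version of the n = 2-3
replication used experimentally.  `intensity_weighted_tau()` computes
$\bar\tau = \sum \alpha_i \tau_i^2 / \sum \alpha_i \tau_i$, the
average comparable with steady-state intensities and the one used in
$\tau_0/\tau$; the amplitude-weighted mean is reported for
transparency but never enters $\tau_0/\tau$.

**Binding kinetics.**  The emission rise after vesicle addition is
fitted as a conventional rise-to-plateau double exponential,
$F(t) = F_\infty - A_1 e^{-t/\tau_1} - A_2 e^{-t/\tau_2}$
(`fit_kinetics()`), components ordered $\tau_1 < \tau_2$.  The fast
phase (typically $\alpha_1 > 0.8$, $\tau_1 < 5$ s) reflects the
water-to-membrane transition, the slow one ($\tau_2 \sim$ 50-70 s)
oligomerization and rearrangement.  Non-rising traces, collapsed slow
amplitudes, and rise times below the sampling interval are flagged
rather than silently reported.

**Spectra.**  `correct_scattering()` subtracts a matched
vesicle-only blank (recorded with non-binding pure-POPC LUVs at the
same lipid load), flooring at zero.  `spectral_shape()` reports
$\lambda_{max}$ from a local quadratic fit in a +/-5 nm window around
the maximum -- sub-nanometer resolution on 1 nm sampled data, needed
to resolve shifts of 0-2 nm -- and FWHM from linear interpolation of
the half-maximum crossings.  The exact spectral-shape method used in
the source experiments is described only in supplementary material we
treat as unavailable; this polynomial/interpolation approach is our
own documented stand-in, validated on synthetic Gaussian bands (center
and width recovered to 0.2 nm).  Maxima at the window edge raise an
error; exact ties resolve to the shorter wavelength with a flag.

## The synthetic-data module

Every generator is the exact forward model of its consuming fitter:
`make_titration()` (isotherm + signal model over an L/P grid of 25
points, 0-300, protein 100 nM), `make_quenching_series()` (contact
model on $[Q] = 0, 0.1, \ldots, 0.7$), `make_depth_profile()`
(mirrored Gaussian at the six catalog depths), `make_decay()`
(reconvolved multi-exponential with Poisson counts),
`make_kinetic_trace()` (double-exponential rise, 151 points over
300 s) and `make_spectrum()` (Gaussian band, 305-450 nm at 1 nm, with
an optional steep scattering tail as the blank).  Noise defaults:
multiplicative Gaussian CV 2% for titration intensities, additive
sd 0.01 on normalized quenching responses, additive sd 0.05 on QP,
Poisson for all counts -- scales chosen so the spread of fitted
parameters is qualitatively comparable to the published
uncertainties.  Any stochastic generation requires an explicit seed;
refusing to generate unseeded noise keeps every simulated dataset
reproducible.

`stn_scenarios()` ships one parameter set per published (variant,
composition) row -- two wild types, the two oxidized double-cysteine
mutants that cannot deploy the N-terminal helix, and the two
tryptophan substitution mutants, in DOPC:PSM:Chol 70:15:15 and
DOPC:PSM 80:20 -- so tests and scripts can address rows by name.
Variant/composition pairs that do not bind (and hence have no
published row) carry `NULL` for that stage.

What the generators deliberately do not emulate: replicate structure
beyond independent seeds (the experimental pooling of n = 2-3 is
unstated), instrumental drift, inner-filter effects (avoided
experimentally by keeping optical density < 0.05), lateral lipid
demixing, or any molecular detail of the membrane.  Passing round-trip
tests therefore demonstrate estimator correctness under the models'
own assumptions -- they cannot validate the models against real
membranes.

## Numerical choices, in one place

* All nonlinear fits use Levenberg-Marquardt (minpack) with box
  bounds; tolerances 1e-12 on both function and parameter change.
* Goodness of fit on every result: signed residual trace, RMSD, and
  reduced chi-square (unit weights where no weighting applies, the
  fit's weights otherwise).
* Standard errors come from the local Jacobian at the optimum; the
  $K_a$ error is mapped from the log10 scale by the delta method.
* Degenerate inputs (flat curves, all-zero profiles, scatter-only
  decays, non-rising kinetics) return flagged results or structured
  error conditions (`mq_*` classes), never silent numbers.
* Problem sizes used by the test suite: 20 x 20 oracle grids, 200
  random exposure round-trips, 100-replicate noise studies for the
  binding and depth stages, 10-replicate averages for TCSPC recovery,
  20 seeded profiles against the exhaustive depth grid.

## Limitations

* The signal model linking the bound fraction to intensity is linear;
  if bound-state emission depended on surface density the recovered
  $F_b/F_{sol}$ would absorb that.
* No global (multi-curve) fitting across toxin variants, no binding
  cooperativity, no oligomerization equilibria; each curve is fitted
  independently.
* The contact model assumes independent random occupancy of boundary
  sites; preferential lipid interactions violate that silently and
  show up only as effective $L_n$ shifts.
* Label depths are POPC values; compositions with cholesterol may
  shift them, so absolute depths carry that systematic, while
  *relative* comparisons (with vs without Chol) are robust.
* No parallax-method estimator and no lateral-diffusion simulation;
  the quenching-rate arguments that justify the static-quenching
  interpretation are context for the models, not computations in them.
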