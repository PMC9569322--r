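# memquench

Quantitative fluorescence analysis of pore-forming toxin / membrane
interactions, built around the tryptophan emission of sticholysins
(StnI, StnII and mutants) binding sphingomyelin-containing lipid
vesicles.  For membrane biophysicists who have titration curves,
quencher series, depth-quenching profiles, TCSPC decays, binding time
courses or emission spectra in hand and want the corresponding model
parameters with uncertainties and goodness of fit.

Three core models:

* **Binding isotherm** — one toxin monomer occupies *n* lipids with
  association constant *K*<sub>a</sub>; the bound fraction is the
  closed-form mass-action root

  θ(L<sub>T</sub>, P<sub>T</sub>) = 1 − ½ [ 1 − L<sub>T</sub>/(nP<sub>T</sub>) − 1/(K<sub>a</sub>P<sub>T</sub>)
  + √( (L<sub>T</sub>/(nP<sub>T</sub>) + 1/(K<sub>a</sub>P<sub>T</sub>) − 1)² + 4/(K<sub>a</sub>P<sub>T</sub>) ) ]

  and the measured signal is F = F<sub>sol</sub>(1 + (F<sub>b</sub>/F<sub>sol</sub> − 1) θ).
  `fit_binding()` returns (*n*, *K*<sub>a</sub>, F<sub>sol</sub>, F<sub>b</sub>/F<sub>sol</sub>).

* **Boundary-lipid contacts** — quenching by spin-labeled PC at
  membrane mole fraction [Q]:

  F([Q]) = (F₀ − F<sub>min</sub>)(1 − [Q])<sup>L<sub>n</sub></sup> + F<sub>min</sub>

  `fit_exposure()` returns the number of annular PC lipids
  L<sub>n</sub> in contact with the accessible tryptophans and the
  non-quenchable fraction F<sub>min</sub>.

* **Depth distribution** — the quenching profile QP(h) = F₀/F − 1,
  sampled with labels at known depths h from the bilayer center, is
  fitted with mirrored Gaussians

  QP(h) = S/(σ√2π) [ e^(−(h−h<sub>m</sub>)²/2σ²) + e^(−(h+h<sub>m</sub>)²/2σ²) ]

  `fit_depth()` returns the mean tryptophan depth h<sub>m</sub>, width
  σ and area S (accessibility).

Around them: `fit_decay()` (TCSPC multi-exponential lifetimes by
iterative reconvolution), `intensity_weighted_tau()`,
`stern_volmer()` / `classify_quenching()` (static vs dynamic
quenching), `fit_kinetics()` (bi-exponential binding kinetics),
`correct_scattering()` / `spectral_shape()` (λ<sub>max</sub>, FWHM),
`mean_interparticle_distance()` (surface-density geometry), CSV
readers/writers and a `run_pipeline()` orchestrator, plus a synthetic
data module (`make_*`, `stn_scenarios()`) holding one published
parameter set per toxin/membrane combination.

## Worked example

Simulate a StnII titration in cholesterol-containing membranes
(DOPC:PSM:Chol 70:15:15) with 2% measurement noise, fit the isotherm,
then fit the matching quencher series and depth profile:

```r
library(memquench)
scen <- stn_scenarios("StnII", "chol")

tc  <- make_titration(modifyList(scen$binding,
                                 list(noise_cv = 0.02, seed = 42)))
fit <- fit_binding(tc)
fit
#> <binding_fit>
#>   n            59.99 +/- 5.5
#>   K_a          2.207e+09 +/- 5.7e+09
#>   F_sol        1.017 +/- 0.037
#>   F_b_ratio    1.69 +/- 0.064
#>   RMSD = 0.04239, chi2_red = 0.002139 (n = 25, p = 4)

saturation_lp_ratio(fit, 0.95, 1e-7)
#> [1] 62.15279
```

The fitted stoichiometry (*n* ≈ 60 lipids per bound monomer) and
emission increase (≈ 1.7-fold) recover the generating values (58.1,
1.72) within their standard errors; the affinity is the least
constrained parameter at this noise level, which the ±-range makes
explicit.  Binding is >95% complete below L/P ≈ 62, so quenching
experiments run at L/P 120 probe fully bound toxin.

```r
qs <- make_quenching_series(modifyList(scen$exposure,
                                       list(noise_sd = 0.01, seed = 42)))
fit_exposure(qs)
#> <exposure_fit>
#>   L_n          1.06 +/- 0.18
#>   F_min        0.7558 +/- 0.027
#>   RMSD = 0.005328, chi2_red = 3.785e-05 (n = 8, p = 2)

fit_depth(make_depth_profile(scen$depth))
#> <depth_fit>
#>   h_m          15.6 +/- 2.5e-15
#>   sigma        9.6 +/- 2e-15
#>   S            5.3 +/- 1.1e-15
#>   RMSD = 1.963e-17, chi2_red = 7.704e-34 (n = 6, p = 3)
```

Read: with cholesterol present, only ~1 PC lipid contacts StnII's
accessible tryptophans (L<sub>n</sub> ≈ 1.1) and ~76% of the emission
is not quenchable at all; the tryptophans sit ~15.6 Å from the bilayer
center.  A noise-free profile refits its generating parameters to
machine precision, which is the round-trip property the test suite
enforces for every published row.

A thin command-line wrapper over the same functions is installed at
`inst/cli/memquench.R`:

```sh
Rscript inst/cli/memquench.R simulate StnI_chol --kind quenching --out q.csv
Rscript inst/cli/memquench.R fit-exposure --in q.csv --json fit.json
```

## Package layout

* `R/binding.R` — isotherm, dilution correction, saturation, geometry
* `R/exposure.R` — contact model, Stern–Volmer, static/dynamic split
* `R/depth.R` — distribution analysis + exhaustive grid oracle
* `R/decay.R`, `R/kinetics.R`, `R/spectrum.R` — photophysics
* `R/synthetic.R` — generators and the published scenario library
* `R/io.R` — CSV schemas, JSON reports, pipeline
* `vignettes/membrane-quenching.Rmd` — models, assumptions, numerical
  choices, limitations
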