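Package: memquench
Title: Membrane Binding and Tryptophan Quenching Analysis for
    Pore-Forming Toxins
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits the fluorescence models used to characterise the
    interaction of sticholysins (and similar alpha-pore-forming toxins)
    with lipid vesicles: a mass-action binding isotherm for
    protein-vesicle titrations (stoichiometry n, association constant
    Ka, bound/free emission ratio), a boundary-lipid contact model for
    quenching by spin-labeled phosphatidylcholine (number of annular PC
    lipids L_n and non-quenchable fraction F_min), and the mirrored
    Gaussian distribution analysis of depth-dependent quenching (mean
    tryptophan depth h_m, width sigma, area S).  Supporting photophysics
    tools cover multi-exponential TCSPC lifetime fitting by iterative
    reconvolution, intensity-weighted average lifetimes, Stern-Volmer
    representations, bi-exponential binding kinetics, scattering-blank
    correction, and spectral shape metrics (lambda_max, FWHM).  A
    synthetic-data module generates every supported data kind from known
    parameters so the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    graphics,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
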