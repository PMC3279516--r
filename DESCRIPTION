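Package: myoelastica
Title: Mechanics, Elasticity and Geometry of Modular Ig-Helix Protein Filaments
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and analysis of single-molecule force
    spectroscopy on modular immunoglobulin/alpha-helix filaments such as the
    C-terminal myomesin My9-My13 tail-to-tail dimer. Provides worm-like-chain
    elasticity, equilibrium two-state helical linkers that produce a force
    plateau near 30 pN, Bell-Evans stochastic Ig-domain unfolding under
    constant-velocity pulling with cantilever coupling and noise, saw-tooth
    event detection, fixed-persistence worm-like-chain segment fitting with
    contour-length increments, the contour-length transformation of plateau
    data with Gaussian peak-spacing analysis, filament extension arithmetic
    (per-residue axial rises, extension ratios), and structural geometry of
    composite filament models: least-squares superposition, domain centroid
    distance spectra, tilt/twist angles, pair-distance distributions p(r),
    and a synthetic superhelix builder.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Config/testthat/edition: 3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    zoo
Suggests:
    testthat (>= 3.0.0)
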