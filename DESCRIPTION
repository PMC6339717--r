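Package: relkin
Title: Comparative Drug-Release Kinetics by Weighted Chi-Square Model Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits six empirical drug-release models (zero-order, first-order,
    Higuchi, Hixson-Crowell, Korsmeyer-Peppas power law, and the flat-geometry
    Hopfenberg law) to cumulative dissolution-time profiles with per-point
    error bars by weighted chi-square minimization, and ranks them by the
    minimum chi-square per degree of freedom. Ships five published dissolution
    profiles for doxorubicin- and mitoxantrone-loaded layer-by-layer liposomal
    nanoparticles, simvastatin-loaded PLGA nanoparticles, and
    poly(epsilon-caprolactone) nanocapsules. Includes a mechanistic companion:
    the closed-form solution of the one-dimensional semi-infinite diffusion
    equation with a power-law boundary concentration, built on repeated
    integrals of the complementary error function of arbitrary real order,
    together with a Crank-Nicolson finite-difference solver that certifies it.
    A seeded synthetic-profile generator supports parameter-recovery and
    model-selection consistency experiments.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    minpack.lm,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
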