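Package: seedshield
Title: Desorption Kinetics and Bioassay Statistics for Insecticidal
    Seed-Protection Biofilms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantitative analysis toolkit for composite seed-protection
    biofilms that release an insecticidal compound by Fickian diffusion.
    Implements the one-dimensional slab desorption model and extraction of
    the diffusivity, evaporation constant and initial desorption flux from
    mass-loss curves; Abbott-corrected mortality and pLD50 estimation by
    linear interpolation on the log-dose scale; two-level full factorial
    (2^3) effect models with coded contrasts, leave-one-out prediction
    diagnostics and contour grids; diffusion-activity correlation and
    principal component analysis; a battery of 2x2 contingency-table
    association coefficients (phi, Cramer's V, Tschuprow's T, Yule's Q and
    Y, Goodman-Kruskal lambda, Cohen's kappa); and conversion of docking
    binding affinities to pKi and ligand efficiency.  Seeded synthetic-data
    generators emulate each assay so every stage is testable without
    laboratory inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
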