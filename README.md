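# seedshield

Quantitative analysis of insecticidal seed-protection biofilms: controlled
release of an active compound from a thin composite film (collagen +
chitosan + a cyanobacterial alkaloid), its insecticidal activity against
pea pests (*Sitona lineatus*, *Bruchus pisorum*), and the statistical
links between the two.

The package is aimed at formulation and crop-protection scientists who need
to go from bench tables — mass-loss curves, dose–mortality counts, a 2³
formulation design, species-by-sex mortality counts, docking scores — to
the derived quantities those assays are run for, with every step seeded,
tested and reproducible.

## What it computes

**Desorption kinetics (Fick slab model).** A film of thickness *e* releasing
through one face follows, to its leading diffusion mode,

```
Mt/M0 = exp(−D π² t / e²),    K = π² D / e²,    F = (M0/S) · K
```

with diffusivity *D* (mm²/day), evaporation constant *K* (1/day) and
initial desorption flux *F* (g/(day·cm²)). `fit_diffusivity()` regresses
ln(Mt/M0) on *t* and converts the slope; `mass_fraction()` and
`concentration_profile()` evaluate the model, including the full odd-mode
series.

**Bioassay.** `corrected_mortality()` applies the Abbott correction
CM% = (MOI − MOC)/(100 − MOC) × 100, and `pld50()` locates
pLD50 = ln(LD50) by piecewise-linear interpolation of CM% against ln(dose)
at the first upward crossing of 50%.

**Formulation optimisation.** `factorial_fit()` estimates the full
third-order coded model
y = μ0 + μA·A + μB·B + μC·C + μAB·AB + μAC·AC + μBC·BC + μABC·ABC
on the 2³ design (A collagen, B chitosan, C active compound) by orthogonal
contrasts; `glance()` reports R², adjusted and PRESS-based predicted R²,
CV% and adequate precision (with honest `NA` flags on saturated fits);
`contour_grid()`/`autoplot()` produce response-surface slices.

**Association analysis.** `correlation_matrix()` and `pca_correlation()`
relate diffusion parameters to activity across formulations;
`chi2_independence()` and `association_coefficients()` compute the full
2×2 battery (φ, contingency coefficient, Cramér's V, Tschuprow's T,
Goodman–Kruskal λ, Cohen's κ, Yule's Q and Y) for species-by-sex
mortality counts.

**Docking post-processing.** `pki_from_affinity()` converts a binding free
energy via ΔG = −RT·ln(Ki) (R = 1.9872×10⁻³ kcal/(mol·K), T = 298.15 K),
and `ligand_efficiency()` reports |ΔG| per heavy atom.

Seeded generators (`simulate_desorption()`, `simulate_bioassay()`,
`simulate_factorial()`, `simulate_contingency()`) produce synthetic inputs
with the statistical structure each stage assumes, so the whole pipeline is
testable without wet-lab data. The study's printed tables ship as plain-CSV
fixtures, loaded by `cb3c_fixtures()`.

## Worked example

```r
library(seedshield)
fx <- cb3c_fixtures()

# formulation model for Sitona lineatus
fit <- factorial_fit(fx$design, pLD50_SL)
fit
#> 2^3 factorial fit of pLD50_SL
#>   pLD50_SL = 4.28 -0.03 A -0.04 B +0.16 C +0.01 AB -0.01 AC -0.02 BC +0.01 ABC
#>   n = 8 runs x 1 replicate(s), residual df = 0 (saturated)
```

The active compound (C) is the only sizeable effect (+0.16 per coded
unit); collagen and chitosan (A, B) slightly depress activity. With eight
runs and eight terms the fit is saturated, so residual-based diagnostics
are flagged rather than invented.

```r
round(correlation_matrix(cb3c_variable_matrix(fx)), 3)
#>              D     K     F pLD50_SL pLD50_BP
#> D        1.000 1.000 0.603    0.829    0.741
#> K        1.000 1.000 0.603    0.828    0.740
#> F        0.603 0.603 1.000    0.755    0.867
#> pLD50_SL 0.829 0.828 0.755    1.000    0.970
#> pLD50_BP 0.741 0.740 0.867    0.970    1.000
```

Fast-diffusing films are the active ones: r(D, pLD50) ≈ 0.83 for
*S. lineatus*.

```r
# recover the diffusivity of the best film from a noisy synthetic curve
curve <- simulate_desorption(D = 3.82e-6, e = 0.12,
                             times = seq(0, 2000, by = 100),
                             sigma = 0.02, seed = 42)
fit_diffusivity(curve, e = 0.12)
#> Slab desorption fit (ln fraction ~ time)
#>   n = 17 points in window (0.01, 0.99]
#>   D = 3.841e-06 mm^2/day   K = 0.002633 /day   R^2 = 0.9997
#>   flags: first-term-window

docking_summary(fx$docking)
#> # A tibble: 2 × 4
#>   target affinity_kcal_mol   pki ligand_efficiency
#> 1 8Z9Z               -10.3  7.55             0.429
#> 2 4F7F                -7.9  5.79             0.329
```

The recovered D (3.84×10⁻⁶ mm²/day) sits within 1% of the generating value
under 2% multiplicative noise, and the docking conversion shows the
olfactory-receptor complex (8Z9Z) binding the alkaloid far more favourably
than the small odorant-binding protein (4F7F).

A command-line wrapper over the same functions is installed at
`inst/cli/seedshield.R` (`Rscript seedshield.R doe --in design.csv --out out/`).

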