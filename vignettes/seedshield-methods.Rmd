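---
title: "Models and methods behind seedshield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind seedshield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedshield)
```

seedshield analyses insecticidal seed-protection biofilms along four
coupled axes: how fast the active compound leaves the film (Fickian
desorption), how toxic the film is to the target pests (quantal bioassay),
how the formulation drives both (2³ factorial design), and how release and
activity relate statistically (correlation, PCA, contingency analysis).
This vignette documents the models, the defaults and the numerical
decisions, in the package's own words.

## 1. Slab desorption model

The film is idealised as a thin flat sheet of thickness $e$ (mm), loaded
uniformly at $t=0$, releasing through one face where the ambient
concentration is held at zero, with constant diffusivity $D$
(mm²·day⁻¹). Separation of variables on the diffusion equation
$\partial C/\partial t = D\,\partial^2 C/\partial y^2$ with zero-value
boundary modes gives odd sine modes $\sin((2m+1)\pi y/e)$ decaying as
$\exp(-D(2m+1)^2\pi^2 t/e^2)$ (`concentration_profile()`). Keeping only the
leading mode of the integrated mass yields the working law

$$\frac{M_t}{M_0} = \exp\!\left(-\frac{D\pi^2}{e^2}\,t\right)
  = e^{-Kt}, \qquad K = \frac{\pi^2 D}{e^2},$$

a single-exponential decay with *evaporation constant* $K$ (day⁻¹). The
initial desorption flux per unit area is the $t\to 0$ release rate,
$F = (M_0/S)\,K$ (g·day⁻¹·cm⁻²), reported positive by convention.

**Series normalisation.** `mass_fraction(mode = "series")` offers two weight
conventions. `normalize = "mass"` uses the Fourier weights
$8/((2m+1)^2\pi^2)$, which sum to one: the fraction is exactly 1 at $t=0$
and equals the spatial integral of the concentration profile (the tests
verify this against numerical quadrature). `normalize = "leading"` (the
default) rescales so the leading coefficient is 1; the series then reduces
*exactly* to the working first-term law as $t$ grows — once the fraction
has fallen below one half the two differ by under $10^{-3}$ relative — at
the price of slightly exceeding 1 near $t=0$. The classical one-sided slab
solution with $4e^2$ in the exponents is available as `mode = "textbook"`
for comparison; the package's parameter chain ($D \to K$) is defined by the
first-term law above, which is the only convention consistent with the
bundled desorption table. Truncation is a fixed `n_terms` (default 200,
far beyond visible change at double precision for the time scales of
interest) rather than adaptive, for testability.

**Fitting.** `fit_diffusivity()` regresses $\ln(M_t/M_0)$ on $t$ by
ordinary least squares with a *free* intercept and converts the slope:
$D = -\text{slope}\cdot e^2/\pi^2$. Defaults and edge rules:

* **Window** `(0.01, 0.99]` on the fraction scale: drops late points where
  multiplicative noise dominates the log, and points at exactly 1.
  At least 3 points must remain.
* **Flat curves** (zero variance) are detected before windowing and
  returned with slope 0, `D = NA` and flag `"no desorption detected"` —
  a constant curve carries no kinetic information, and silently estimating
  from it would be worse than refusing.
* **Rising curves** (non-negative slope) are flagged, never converted into
  a non-positive diffusivity.
* A `"first-term-window"` flag is raised when fitted points have fraction
  above one half, where the dropped higher modes matter most; users
  wanting strict first-term validity can truncate to late times.
* The intercept is left free rather than forced through zero: it absorbs
  early-time series error and makes the slope estimate robust to it.

Units are fixed throughout as mm, day, g and cm² (for flux); the bundled
desorption table is stored at its display scales (×10⁶, ×10³, ×10⁵) and
converted to base units on load.

## 2. Bioassay: Abbott correction and pLD50

Observed treated mortality (MOI, %) is corrected for background control
mortality (MOC, %) by $CM = (MOI - MOC)/(100 - MOC)\times 100$. Negative
corrected values (treated below control) are clamped to 0 and flagged; a
control mortality of 100% invalidates the assay and errors.

pLD50 is defined as $\ln(\mathrm{LD50})$ and located *non-parametrically*:
corrected mortality is averaged across replicates within each dose, plotted
against $\ln(\text{dose})$, and the first upward crossing of 50% is
linearly interpolated. Exact 50% hits resolve to the lowest such dose.
If CM never crosses 50% the estimate is refused (an "out of range" error)
rather than extrapolated. No probit/logit model is fitted — the linear
interpolation *is* the procedure; model-based LD50 estimation is a
deliberate non-goal. Two consequences the tests exercise: rescaling all
doses by $c$ shifts pLD50 by exactly $\ln c$, and duplicated dose rows with
identical counts are inert.

## 3. 2³ factorial formulation model

The three formulation factors — collagen (1%/2%), chitosan (1%/2%) and the
active compound (0.1%/0.5%) — are coded to $\pm 1$ and the full third-order
model

$$y = \mu_0 + \mu_A A + \mu_B B + \mu_C C + \mu_{AB}AB + \mu_{AC}AC
      + \mu_{BC}BC + \mu_{ABC}ABC$$

is fitted by least squares. On the orthogonal design
($X^\top X = 8I$) this equals the classical contrast estimates — each
coefficient is half the difference of means between its $+1$ and $-1$
level — which the tests verify against a direct normal-equation solve.
Coefficients are reported at full precision plus a half-up 2-decimal
rounding for comparison with published effect models.

With 8 runs, one replicate and 8 terms the model is **saturated**: fitted
values equal observations, $R^2 = 1$, and the residual degrees of freedom
are zero. The package reports SD (root-MSE), CV%, adjusted $R^2$, the
model F test and adequate precision only when residual df $> 0$
(replicated input), and flags them `NA` with `saturated = TRUE` otherwise.
Predicted $R^2$ uses brute-force leave-one-out PRESS (refit, predict the
held-out run); on a single-replicate saturated design those refits are
rank-deficient, so predicted $R^2$ is likewise `NA` rather than a made-up
number. Published diagnostics of this family depend on an unstated
error-pooling choice and are deliberately not asserted.

`contour_grid()` slices the fitted surface over a factor pair with the
third factor held at $-1$ by default — the level of the best-performing
region (low collagen, low chitosan) — since the published contour figures
do not state the fixed level.

## 4. Association analysis

**Correlation / PCA.** The 8 formulations × 5 variables matrix
($D, K, F$, and pLD50 for both species) feeds a Pearson correlation matrix
and a correlation-mode PCA (variables standardised with the sample $n-1$
convention). Eigenvalues sum to the number of variables; loadings are
oriented so each component's largest-magnitude entry is positive. Note
that $K = \pi^2 D/e^2$ is exactly proportional to $D$, so $r(K,\cdot)$ and
$r(D,\cdot)$ coincide on exact values; on rounded published values they can
differ in the third decimal, and the tests tolerate exactly that.

**Contingency battery.** For the 2×2 species-by-sex mortality counts the
package computes the plain and Yates-corrected $\chi^2$ (both always
reported, since the continuity correction can drive a near-null statistic
to exactly 0 with $p = 1$), and the coefficient battery in closed form:
$\phi = \sqrt{\chi^2/N}$, $C = \sqrt{\chi^2/(\chi^2+N)}$, Cramér's $V$,
Tschuprow's $T$ (all equal for 2×2), Goodman–Kruskal $\lambda$, Cohen's
$\kappa$, Yule's $Q = (ad-bc)/(ad+bc)$ and $Y$. Two documented choices:

* $\lambda$ is directional. The battery's headline `lambda` is the
  *column-given-row* variant (predicting sex from species), which is the
  quantity that vanishes when every species has the same modal sex — the
  behaviour the published coefficient table shows. The row-given-column
  and symmetric variants are also returned; on the bundled counts the
  symmetric value is 0.005, not 0.
* $\kappa$ treats the species×sex table as an agreement table. That usage
  is unusual (the two classifications are not raters of the same items);
  it is provided as a descriptive statistic only.

## 5. Docking post-processing

Binding free energies are converted by the standard relation
$\Delta G = -RT\ln K_i$, so $pK_i = -\Delta G/(\ln 10\cdot RT)$ with
$R = 1.9872\times 10^{-3}$ kcal·mol⁻¹·K⁻¹ and $T = 298.15$ K — the one
standard convention that reproduces both bundled pKi values from both
bundled affinities at 2 decimals. Ligand efficiency is
$|\Delta G|/N_\text{heavy}$ with a default heavy-atom count of 24
(C₁₉H₁₀N₂O₃); no structure parsing is attempted — the count is a plain
input.

## 6. Synthetic-data generators

Every generator is a pure function of its parameters and an integer seed
(`withr::with_seed`, leaving the global RNG untouched), so all pipeline
stages are testable offline:

* `simulate_desorption()` — the first-term law plus noise; default 2%
  *multiplicative* Gaussian noise, chosen because late-curve fractions
  span orders of magnitude so additive noise would be either negligible
  early or overwhelming late. Noisy values are clipped to (0, 1] and the
  clip count is recorded.
* `simulate_bioassay()` — logistic tolerance in $\ln(\text{dose})$
  (location $\ln \mathrm{LD50}$, slope $b$), observed mortality mixed with
  background as $c + (1-c)p$ — the model under which the Abbott correction
  is exact. The logistic form is a choice: the estimation procedure only
  assumes interpolation, not this generating law. Defaults (10 insects per
  dose, triplicate, small background mortality) mirror the bench protocol.
* `simulate_factorial()` — the coded model evaluated on all 8 runs plus
  i.i.d. Gaussian residuals.
* `simulate_contingency()` — per-species binomial sex split, then binomial
  deaths per cell; defaults (100 insects per species, balanced sexes, cell
  mortalities 0.88–0.98) mirror the confirmation assay on the optimised
  film.

What the generators do **not** emulate: overdispersion between replicate
assays, time-to-death structure, film-to-film manufacturing variability,
and any dependence of mortality on the desorption kinetics. Passing
recovery tests therefore demonstrates the estimators are correct *under
the stated models*, not that real assays meet those models.

## 7. Problem sizes and test design

The recovery experiments run at sizes chosen to make Monte-Carlo
assertions sharp but the suite quick: 200 seeded curves for the
diffusivity-recovery property (median relative error < 5% at 2% noise),
500 simulated assays for pLD50 unbiasedness (within 3 standard errors),
200 simulated designs for coefficient recovery, 500 null tables for the
association-under-independence check. Fixed-seed substreams are derived
from one master seed per experiment, so every run is exactly repeatable.

## 8. Known limitations

* The flux $F$ requires the film load per area ($M_0/S$), which is not
  part of the bundled tables; `initial_flux()` therefore only computes on
  user-supplied values, and the bundled $F$ column is carried as data.
* One printed interaction term of the second species' effect model (BC)
  differs by one rounding unit from the exact contrast of the bundled
  responses; the package reports the exact contrast.
* The desorption model assumes one-dimensional release, constant $D$ and
  a non-swelling film; none of these are checked from data.
* pLD50 = ln(LD50) means *larger* values indicate a *larger* lethal dose;
  the package computes the quantity as defined and attaches no potency
  interpretation.
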