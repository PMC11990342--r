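#' Fraction of compound remaining in a slab film
#'
#' Evaluates the one-dimensional Fickian desorption law for a thin flat film
#' of thickness `e` that releases its load through one face.  The default
#' `"first-term"` mode is the single-exponential law
#' \deqn{M_t/M_0 = \exp(-D \pi^2 t / e^2),}
#' i.e. a first-order decay with evaporation constant \eqn{K = \pi^2 D/e^2}.
#' `"series"` mode evaluates the odd-mode partial sum with decay exponents
#' \eqn{D (2m+1)^2 \pi^2 t / e^2}; with `normalize = "leading"` (default)
#' the series is scaled so its leading term equals the first-term law (the
#' two modes then agree to well under 1% once the fraction has fallen below
#' one half), while `normalize = "mass"` uses the Fourier mass weights
#' \eqn{8/((2m+1)^2 \pi^2)} that sum to one, so the fraction is exact at
#' \eqn{t = 0} and matches the integrated concentration profile.
#' `"textbook"` mode is the classical one-sided slab solution whose
#' exponents carry \eqn{4 e^2}; it is provided for comparison only.
#'
#' @param t Time in days (vectorised, `t >= 0`).
#' @param D Diffusivity in mm^2/day (`> 0`).
#' @param e Film thickness in mm (`> 0`).
#' @param mode One of `"first-term"`, `"series"`, `"textbook"`.
#' @param n_terms Number of series terms (`>= 1`); ignored in first-term
#'   mode.
#' @param normalize Series weight convention, `"leading"` or `"mass"`.
#' @return Numeric vector of mass fractions, same length as `t`.
#' @examples
#' mass_fraction(0, D = 3.82e-6, e = 0.12)           # 1
#' mass_fraction(381.9, D = 3.82e-6, e = 0.12)       # ~ exp(-1)
#' @export
mass_fraction <- function(t, D, e,
                          mode = c("first-term", "series", "textbook"),
                          n_terms = 200,
                          normalize = c("leading", "mass")) {
  mode <- match.arg(mode)
  normalize <- match.arg(normalize)
  if (any(t < 0)) abort("t must be >= 0", class = "seedshield_domain_error")
  if (D <= 0 || e <= 0) abort("D and e must be > 0", class = "seedshield_domain_error")
  if (n_terms < 1) abort("n_terms must be >= 1", class = "seedshield_domain_error")
  K <- pi^2 * D / e^2
  if (mode == "first-term") {
    return(exp(-K * t))
  }
  m <- seq_len(n_terms) - 1
  odd <- 2 * m + 1
  rate <- if (mode == "textbook") K * odd^2 / 4 else K * odd^2
  w <- 8 / (odd^2 * pi^2)
  if (mode == "series" && normalize == "leading") w <- 1 / odd^2
  # outer product: rows = times, cols = modes
  vapply(t, function(ti) sum(w * exp(-rate * ti)), numeric(1))
}

#' Evaporation constant of the first-term desorption law
#'
#' `K = pi^2 * D / e^2`: the first-order rate constant of the leading mode
#' of slab desorption.
#'
#' @param D Diffusivity, mm^2/day (`> 0`, vectorised).
#' @param e Film thickness, mm (`> 0`).
#' @return K in 1/day.
#' @examples
#' evaporation_constant(3.82e-6, 0.12)   # 2.618e-3
#' @export
evaporation_constant <- function(D, e) {
  if (any(D <= 0) || any(e <= 0)) {
    abort("D and e must be > 0", class = "seedshield_domain_error")
  }
  pi^2 * D / e^2
}

#' Initial desorption flux per unit film area
#'
#' Magnitude of the initial mass-release rate per unit area implied by the
#' first-term law: the derivative of \eqn{M(t) = M_0 e^{-Kt}} at \eqn{t=0}
#' divided by the film area, `F = (M0 / S) * K`, reported positive.
#'
#' @param K Evaporation constant, 1/day (`> 0`).
#' @param M0 Initial mass of active compound in the film, g (`>= 0`).
#' @param S Film surface area, cm^2 (`> 0`).
#' @return F in g/(day cm^2).
#' @export
initial_flux <- function(K, M0, S) {
  if (missing(M0) || missing(S) || is.null(M0) || is.null(S) ||
      anyNA(M0) || anyNA(S)) {
    abort("M0 and S must be supplied to compute the initial flux",
          class = "seedshield_config_error")
  }
  if (any(K <= 0)) abort("K must be > 0", class = "seedshield_domain_error")
  if (any(M0 < 0) || any(S <= 0)) {
    abort("require M0 >= 0 and S > 0", class = "seedshield_domain_error")
  }
  (M0 / S) * K
}

#' Concentration profile across the film
#'
#' Separation-of-variables solution of the diffusion equation on a slab
#' with uniform initial concentration `C0 - Cstar` and zero concentration at
#' the releasing face: odd sine modes \eqn{\sin((2m+1)\pi y/e)} with decay
#' factors \eqn{\exp(-D (2m+1)^2 \pi^2 t / e^2)}.  The spatial integral of
#' this profile reproduces the `"series"` mass law with mass weights.
#'
#' @param y Position in the film, mm, in `[0, e]` (vectorised).
#' @param t Time, days (scalar, `>= 0`).
#' @param D Diffusivity, mm^2/day.
#' @param e Film thickness, mm.
#' @param n_terms Series truncation (default 200).
#' @param C0 Initial concentration (default 1).
#' @param Cstar Saturation concentration of the surrounding medium
#'   (default 0).
#' @return Numeric vector of concentrations at positions `y`.
#' @export
concentration_profile <- function(y, t, D, e, n_terms = 200, C0 = 1, Cstar = 0) {
  if (any(y < 0 | y > e)) {
    abort("y must lie within [0, e]", class = "seedshield_domain_error")
  }
  if (t < 0) abort("t must be >= 0", class = "seedshield_domain_error")
  if (D <= 0 || e <= 0 || n_terms < 1) {
    abort("require D > 0, e > 0, n_terms >= 1", class = "seedshield_domain_error")
  }
  K <- pi^2 * D / e^2
  m <- seq_len(n_terms) - 1
  odd <- 2 * m + 1
  amp <- (4 / (odd * pi)) * exp(-K * odd^2 * t)
  vapply(y, function(yi) (C0 - Cstar) * sum(amp * sin(odd * pi * yi / e)),
         numeric(1))
}

#' Estimate diffusivity from a desorption curve
#'
#' Fits an ordinary least-squares line to \eqn{\ln(M_t/M_0)} against time
#' and converts the slope to the diffusivity via the first-term law:
#' \eqn{D = -\mathrm{slope} \cdot e^2/\pi^2}.  The evaporation constant
#' `K = pi^2 D / e^2` (equal to minus the slope) is recomputed, never stored
#' independently, and the initial flux `F = (M0/S) K` is reported when the
#' film load and area are supplied.
#'
#' Points are restricted to a fraction window before fitting (default
#' `(0.01, 0.99]`), which drops late-time noise-dominated points and the
#' earliest times where the first-term law is least accurate.  The
#' intercept is left free.  Fits with non-negative slope are flagged rather
#' than silently returning a non-positive diffusivity, and a
#' `"first-term-window"` flag is raised when the window retains points with
#' fraction above one half, where series truncation error is largest.
#'
#' @param curve Tibble with columns `time_days` and `fraction`.
#' @param e Film thickness, mm.
#' @param window Length-2 numeric, the half-open fraction window
#'   `(lower, upper]` used for fitting.
#' @param M0,S Optional film load (g) and area (cm^2) for the flux.
#' @return An object of class `"diffusion_fit"` with elements `D`, `K`,
#'   `F`, `slope`, `intercept`, `r.squared`, `n`, `window`, `flags`.
#' @examples
#' curve <- simulate_desorption(D = 2e-6, e = 0.12,
#'                              times = seq(50, 2000, length.out = 20),
#'                              noise = "none", seed = 1)
#' fit_diffusivity(curve, e = 0.12)
#' @export
fit_diffusivity <- function(curve, e, window = c(0.01, 0.99), M0 = NULL, S = NULL) {
  validate_desorption_curve(curve)
  if (e <= 0) abort("e must be > 0", class = "seedshield_domain_error")
  # a perfectly flat curve carries no kinetic signal at all; flag it before
  # windowing (a constant fraction of 1.0 would otherwise leave no points)
  if (stats::sd(curve$fraction) == 0) {
    return(structure(
      list(D = NA_real_, K = NA_real_, F = NA_real_, slope = 0,
           intercept = log(curve$fraction[1]), r.squared = NA_real_,
           n = nrow(curve), window = window,
           flags = "no desorption detected", data = curve, lm = NULL),
      class = "diffusion_fit"
    ))
  }
  keep <- curve$fraction > window[1] & curve$fraction <= window[2]
  pts <- curve[keep, ]
  if (any(pts$fraction <= 0)) {
    abort("non-positive fractions inside the fit window; truncate the curve first",
          class = "seedshield_domain_error")
  }
  flags <- character(0)
  if (nrow(pts) < 3) {
    abort(paste0("only ", nrow(pts), " usable points after windowing; >= 3 required"),
          class = "seedshield_fit_error")
  }
  fit <- lm(log(fraction) ~ time_days, data = pts)
  slope <- unname(coef(fit)[["time_days"]])
  intercept <- unname(coef(fit)[["(Intercept)"]])
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (slope >= 0) {
    flags <- c(flags, if (slope == 0) "no desorption detected"
               else "negative diffusivity (rising curve)")
    D <- NA_real_
    K <- NA_real_
  } else {
    D <- -slope * e^2 / pi^2
    K <- pi^2 * D / e^2
    if (any(exp(-K * pts$time_days) > 0.5)) {
      flags <- c(flags, "first-term-window")
    }
  }
  Fflux <- if (!is.null(M0) && !is.null(S) && !is.na(K)) initial_flux(K, M0, S)
           else NA_real_
  structure(
    list(D = D, K = K, F = Fflux, slope = slope, intercept = intercept,
         r.squared = r2, n = nrow(pts), window = window, flags = flags,
         data = pts, lm = fit),
    class = "diffusion_fit"
  )
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat("Slab desorption fit (ln fraction ~ time)\n")
  cat(sprintf("  n = %d points in window (%g, %g]\n", x$n, x$window[1], x$window[2]))
  cat(sprintf("  D = %.4g mm^2/day   K = %.4g /day   R^2 = %.4f\n",
              x$D, x$K, x$r.squared))
  if (!is.na(x$F)) cat(sprintf("  F = %.4g g/(day cm^2)\n", x$F))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @rdname fit_diffusivity
#' @param x A `diffusion_fit` object.
#' @param ... Unused.
#' @method tidy diffusion_fit
#' @export
tidy.diffusion_fit <- function(x, ...) {
  tibble(
    term = c("slope", "intercept"),
    estimate = c(x$slope, x$intercept)
  )
}

#' @rdname fit_diffusivity
#' @method glance diffusion_fit
#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble(
    D = x$D, K = x$K, F = x$F,
    r.squared = x$r.squared, nobs = x$n,
    flags = paste(x$flags, collapse = "; ")
  )
}

#' @rdname fit_diffusivity
#' @param object A `diffusion_fit` object.
#' @method autoplot diffusion_fit
#' @export
autoplot.diffusion_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$time_days, y = log(.data$fraction))) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "time (days)", y = "ln(Mt/M0)",
                  title = "Desorption log-linear fit",
                  subtitle = sprintf("D = %.3g mm²/day, R² = %.3f",
                                     object$D, object$r.squared))
}
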