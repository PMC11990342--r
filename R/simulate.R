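#' Simulate a slab desorption mass-loss curve
#'
#' Generates a time series of remaining mass fractions Mt/M0 from the
#' first-term slab desorption law (optionally the full odd-mode series),
#' with configurable measurement noise.  With `noise = "none"` the curve
#' satisfies the generating law exactly.  Noisy values are clipped back to
#' (0, 1]; the number of clipped points is recorded in the
#' `"n_clipped"` attribute.
#'
#' Defaults mirror bench conditions for a thin composite film: 2%
#' multiplicative noise, appropriate where mass fractions span orders of
#' magnitude late in the curve.
#'
#' @param D Diffusivity, mm^2/day (`> 0`).
#' @param e Film thickness, mm (`> 0`).
#' @param times Strictly increasing time grid in days, `>= 2` points,
#'   starting at `t >= 0`.
#' @param noise `"none"`, `"additive"` or `"multiplicative"` Gaussian.
#' @param sigma Noise standard deviation (`>= 0`); relative for
#'   multiplicative noise.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and this seed.
#' @param mode,n_terms Passed to [mass_fraction()].
#' @return Tibble with columns `time_days`, `fraction`; attributes
#'   `n_clipped` and `spec`.
#' @examples
#' simulate_desorption(D = 3.82e-6, e = 0.12, times = c(0, 100, 400),
#'                     noise = "none", seed = 1)
#' @export
simulate_desorption <- function(D, e, times,
                                noise = c("multiplicative", "additive", "none"),
                                sigma = 0.02, seed = 1,
                                mode = "first-term", n_terms = 200) {
  noise <- match.arg(noise)
  if (D <= 0 || e <= 0) abort("require D > 0 and e > 0",
                              class = "seedshield_validation_error")
  if (sigma < 0) abort("sigma must be >= 0", class = "seedshield_validation_error")
  if (length(times) < 2 || any(diff(times) <= 0) || times[1] < 0) {
    abort("times must be a strictly increasing grid of >= 2 non-negative values",
          class = "seedshield_validation_error")
  }
  frac <- mass_fraction(times, D, e, mode = mode, n_terms = n_terms)
  if (noise != "none" && sigma > 0) {
    eps <- withr::with_seed(seed, rnorm(length(times), 0, sigma))
    frac <- if (noise == "additive") frac + eps else frac * (1 + eps)
  }
  n_clipped <- sum(frac > 1 | frac < .Machine$double.eps)
  frac <- pmin(pmax(frac, .Machine$double.eps), 1)
  out <- tibble(time_days = as.double(times), fraction = frac)
  attr(out, "n_clipped") <- n_clipped
  attr(out, "spec") <- list(D = D, e = e, noise = noise, sigma = sigma,
                            seed = seed, mode = mode)
  out
}

#' Simulate a quantal dose-mortality assay
#'
#' Draws binomial death counts for a grid of doses and a control group.
#' The underlying tolerance curve is logistic in ln(dose): an insect
#' exposed at dose d dies with probability
#' `plogis(slope * (ln d - ln ld50))`, and observed treated mortality mixes
#' in background control mortality as `c + (1 - c) * p` (the model under
#' which the Abbott correction is exact).  `slope = Inf` gives a step
#' tolerance at `ld50`.
#'
#' Defaults follow the bench protocol: 10 insects per dose, triplicate,
#' with a small background mortality.
#'
#' @param doses Strictly positive dose grid (concentration units).
#' @param n_per_dose Insects exposed per dose per replicate (`>= 1`).
#' @param replicates Number of replicate series.
#' @param control_mortality Background mortality probability in `[0, 1)`.
#' @param ld50 True LD50 (same units as `doses`).
#' @param slope Logistic slope in ln-dose (`> 0`, may be `Inf`).
#' @param seed Integer seed.
#' @return Tibble with columns `dose`, `replicate`, `exposed`, `dead`,
#'   `is_control`; control rows carry `dose = 0`.
#' @examples
#' simulate_bioassay(doses = c(0.25, 0.5, 1, 2, 4), seed = 7)
#' @export
simulate_bioassay <- function(doses, n_per_dose = 10, replicates = 3,
                              control_mortality = 0.05, ld50 = 1, slope = 2,
                              seed = 1) {
  if (any(doses <= 0)) abort("doses must be strictly positive",
                             class = "seedshield_validation_error")
  if (n_per_dose < 1 || replicates < 1) {
    abort("n_per_dose and replicates must be >= 1",
          class = "seedshield_validation_error")
  }
  if (control_mortality < 0 || control_mortality >= 1) {
    abort("control_mortality must lie in [0, 1)",
          class = "seedshield_validation_error")
  }
  if (ld50 <= 0 || slope <= 0) {
    abort("require ld50 > 0 and slope > 0", class = "seedshield_validation_error")
  }
  doses <- sort(doses)
  p_tol <- if (is.infinite(slope)) {
    ifelse(doses > ld50, 1, ifelse(doses < ld50, 0, 0.5))
  } else {
    stats::plogis(slope * (log(doses) - log(ld50)))
  }
  p_obs <- control_mortality + (1 - control_mortality) * p_tol
  grid <- tidyr::expand_grid(replicate = seq_len(replicates), dose = doses)
  grid <- dplyr::left_join(grid, tibble(dose = doses, p = p_obs), by = "dose")
  out <- withr::with_seed(seed, {
    treated <- dplyr::mutate(
      grid,
      exposed = as.integer(n_per_dose),
      dead = rbinom(dplyr::n(), n_per_dose, .data$p),
      is_control = FALSE
    )
    control <- tibble(
      replicate = seq_len(replicates), dose = 0,
      exposed = as.integer(n_per_dose),
      dead = rbinom(replicates, n_per_dose, control_mortality),
      is_control = TRUE
    )
    dplyr::bind_rows(dplyr::select(treated, !"p"), control)
  })
  out <- dplyr::select(out, "dose", "replicate", "exposed", "dead", "is_control")
  dplyr::arrange(out, .data$is_control, .data$dose, .data$replicate)
}

#' Simulate 2^3 factorial responses
#'
#' Evaluates the full third-order coded-factor model
#' \deqn{y = \mu_0 + \mu_A A + \mu_B B + \mu_C C + \mu_{AB} AB + \mu_{AC} AC
#'       + \mu_{BC} BC + \mu_{ABC} ABC}
#' on every +/-1 combination and adds Gaussian residual noise.
#'
#' @param coefficients Numeric vector of the 8 model coefficients, in the
#'   order `mu0, A, B, C, AB, AC, BC, ABC` (names optional).
#' @param sigma Residual standard deviation (`>= 0`).
#' @param replicates Replicate responses per run (`>= 1`).
#' @param seed Integer seed.
#' @return Tibble with columns `biofilm`, `A`, `B`, `C`, `replicate`,
#'   `response`.
#' @examples
#' simulate_factorial(c(4.28, -0.03, -0.04, 0.16, 0.01, -0.01, -0.02, 0.01),
#'                    sigma = 0, seed = 1)
#' @export
simulate_factorial <- function(coefficients, sigma = 0.02, replicates = 1,
                               seed = 1) {
  if (length(coefficients) != 8) {
    abort("exactly 8 coefficients required (full third-order 2^3 model)",
          class = "seedshield_validation_error")
  }
  if (sigma < 0 || replicates < 1) {
    abort("require sigma >= 0 and replicates >= 1",
          class = "seedshield_validation_error")
  }
  design <- tidyr::expand_grid(A = c(-1, 1), B = c(-1, 1), C = c(-1, 1))
  # standard run order: C slowest to match the bench table layout
  design <- dplyr::arrange(design, .data$C, .data$B, .data$A)
  X <- with(design, cbind(1, A, B, C, A * B, A * C, B * C, A * B * C))
  mu <- as.numeric(X %*% as.numeric(coefficients))
  out <- tidyr::expand_grid(run = seq_len(8), replicate = seq_len(replicates))
  out <- dplyr::bind_cols(design[out$run, ], out["replicate"])
  out$biofilm <- paste0("CB3C-", rep(seq_len(8), each = replicates))
  out$response <- rep(mu, each = replicates) +
    if (sigma > 0) withr::with_seed(seed, rnorm(nrow(out), 0, sigma)) else 0
  dplyr::select(out, "biofilm", "A", "B", "C", "replicate", "response")
}

#' Simulate species-by-sex mortality counts
#'
#' Draws a 2x2 contingency table of dead insects.  For each species the
#' number of males among the exposed is binomial with the given sex ratio;
#' deaths are then binomial within each species-by-sex cell.
#'
#' Defaults mirror the confirmation assay on the optimised film: 100
#' insects per species at a balanced sex ratio, with high cell mortalities.
#'
#' @param species Character vector of species labels.
#' @param n_exposed Insects exposed per species.
#' @param male_prop Probability that an exposed insect is male, per species.
#' @param mortality Matrix (species x sex) of death probabilities, columns
#'   male then female.
#' @param seed Integer seed.
#' @return Tibble with columns `species`, `male`, `female` (dead counts)
#'   and attribute `exposed` (males/females at risk per species).
#' @examples
#' simulate_contingency(seed = 3)
#' @export
simulate_contingency <- function(species = c("Sitona lineatus", "Bruchus pisorum"),
                                 n_exposed = c(100, 100),
                                 male_prop = c(0.5, 0.5),
                                 mortality = rbind(c(0.98, 0.88), c(0.96, 0.90)),
                                 seed = 1) {
  k <- length(species)
  mortality <- matrix(mortality, nrow = k)
  if (length(n_exposed) != k || length(male_prop) != k ||
      nrow(mortality) != k || ncol(mortality) != 2) {
    abort("argument lengths must match the number of species",
          class = "seedshield_validation_error")
  }
  if (any(male_prop < 0 | male_prop > 1) || any(mortality < 0 | mortality > 1)) {
    abort("proportions and probabilities must lie in [0, 1]",
          class = "seedshield_validation_error")
  }
  withr::with_seed(seed, {
    males <- rbinom(k, n_exposed, male_prop)
    females <- n_exposed - males
    dead_m <- rbinom(k, males, mortality[, 1])
    dead_f <- rbinom(k, females, mortality[, 2])
    out <- tibble(species = species, male = dead_m, female = dead_f)
    attr(out, "exposed") <- tibble(species = species, male = males,
                                   female = females)
    out
  })
}
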