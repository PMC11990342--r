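test_that("first-term mass fraction matches its closed form", {
  expect_equal(mass_fraction(0, D = 3.82e-6, e = 0.12), 1)
  # one mean lifetime t = e^2/(pi^2 D)
  t_star <- 0.12^2 / (pi^2 * 3.82e-6)
  expect_equal(mass_fraction(t_star, D = 3.82e-6, e = 0.12), exp(-1))
  # K for another film times t = 1000 days
  expect_equal(mass_fraction(1000, D = 1.15e-6, e = 0.12),
               exp(-evaporation_constant(1.15e-6, 0.12) * 1000))
  expect_equal(round(mass_fraction(1000, D = 1.15e-6, e = 0.12), 4), 0.4547)
  expect_error(mass_fraction(-1, 1e-6, 0.12), class = "seedshield_domain_error")
  expect_error(mass_fraction(1, 1e-6, 0.12, mode = "series", n_terms = 0),
               class = "seedshield_domain_error")
})

test_that("mass fraction is strictly decreasing in t and in D", {
  t <- seq(0, 4000, by = 100)
  f <- mass_fraction(t, D = 1.5e-6, e = 0.12)
  expect_true(all(diff(f) < 0))
  Ds <- seq(0.5e-6, 4e-6, length.out = 12)
  fD <- vapply(Ds, function(d) mass_fraction(500, d, 0.12), numeric(1))
  expect_true(all(diff(fD) < 0))
})

test_that("series mode agrees with the first-term law once the fraction is small", {
  D <- 2e-6; e <- 0.12
  K <- evaporation_constant(D, e)
  t_late <- seq(log(2) / K, 5 / K, length.out = 20)  # fraction <= 0.5
  s <- mass_fraction(t_late, D, e, mode = "series", n_terms = 200)
  f1 <- mass_fraction(t_late, D, e)
  expect_true(all(abs(s - f1) / f1 < 0.01))
  # series terms decay monotonically in magnitude at any t > 0
  odd <- 2 * (0:9) + 1
  terms <- (1 / odd^2) * exp(-K * odd^2 * 200)
  expect_true(all(diff(terms) < 0))
})

test_that("evaporation constant follows K = pi^2 D / e^2", {
  expect_equal(round(evaporation_constant(3.82e-6, 0.12) * 1e3, 2), 2.62)
  expect_equal(round(evaporation_constant(0.15e-6, 0.12) * 1e3, 2), 0.10)
  expect_equal(evaporation_constant(1, pi), 1)
  expect_error(evaporation_constant(-1, 0.12), class = "seedshield_domain_error")
})

test_that("initial flux is the t -> 0 desorption rate per unit area", {
  expect_equal(initial_flux(2.62e-3, M0 = 1, S = 1), 2.62e-3)
  expect_equal(initial_flux(1, M0 = 0, S = 3), 0)
  expect_error(initial_flux(1, M0 = NULL, S = 1),
               class = "seedshield_config_error")
  # numerical-derivative oracle: d/dt of M0 exp(-Kt) at t -> 0 equals -S F
  K <- 1e-3; M0_over_S <- 0.5; S <- 2; M0 <- M0_over_S * S
  h <- 1e-6
  dMdt <- (M0 * exp(-K * h) - M0) / h
  expect_equal(abs(dMdt), S * initial_flux(K, M0, S), tolerance = 1e-6)
})

test_that("concentration profile honours its boundary and mass balance", {
  D <- 2e-6; e <- 0.12
  expect_lt(abs(concentration_profile(e, t = 1, D, e, n_terms = 200)), 1e-6)
  # t -> infinity: everything desorbed
  y <- seq(0, e, length.out = 11)
  expect_true(all(abs(concentration_profile(y, t = 1e7, D, e)) < 1e-12))
  # t = 0 partial sums approach the uniform initial condition pointwise
  mid <- concentration_profile(e / 2, t = 0, D, e, n_terms = 2000, C0 = 3)
  expect_equal(mid, 3, tolerance = 1e-3)
  expect_error(concentration_profile(-0.01, 1, D, e),
               class = "seedshield_domain_error")
  # quadrature oracle: integrated profile tracks the series mass law
  t0 <- 150
  f_int <- stats::integrate(function(yy) concentration_profile(yy, t0, D, e,
                                                               n_terms = 200),
                            0, e, rel.tol = 1e-10)$value / e
  f_series <- mass_fraction(t0, D, e, mode = "series", n_terms = 200,
                            normalize = "mass")
  expect_equal(f_int, f_series, tolerance = 1e-3)
})

test_that("diffusivity is recovered exactly from a noiseless curve", {
  curve <- simulate_desorption(D = 2e-6, e = 0.12,
                               times = seq(100, 2000, length.out = 20),
                               noise = "none", seed = 1)
  fit <- fit_diffusivity(curve, e = 0.12)
  expect_lt(abs(fit$D - 2e-6) / 2e-6, 1e-9)
  expect_equal(fit$K, pi^2 * fit$D / 0.12^2)
  expect_equal(fit$r.squared, 1, tolerance = 1e-9)
})

test_that("flat curves are flagged, not fitted", {
  flat <- tibble::tibble(time_days = c(0, 100, 200, 300),
                         fraction = c(1, 1, 1, 1))
  fit <- fit_diffusivity(flat, e = 0.12)
  expect_true(is.na(fit$D))
  expect_match(fit$flags, "no desorption", all = FALSE)
})

test_that("the early-time window raises the first-term validity flag", {
  curve <- simulate_desorption(D = 2e-6, e = 0.12,
                               times = seq(10, 3000, length.out = 30),
                               noise = "none", seed = 1)
  fit <- fit_diffusivity(curve, e = 0.12)
  expect_true("first-term-window" %in% fit$flags)
  late <- curve[curve$fraction < 0.4, ]
  fit_late <- fit_diffusivity(late, e = 0.12)
  expect_false("first-term-window" %in% fit_late$flags)
})

test_that("noiseless fits reproduce the printed K for the best film", {
  d5 <- fx$desorption$D[fx$desorption$biofilm == "CB3C-5"]
  curve <- simulate_desorption(D = d5, e = E_FILM,
                               times = seq(20, 1500, length.out = 25),
                               noise = "none", seed = 1)
  fit <- fit_diffusivity(curve, e = E_FILM)
  expect_equal(signif(fit$K, 3), 2.62e-3)
})

test_that("parameter recovery stays within 5% median error at 2% noise", {
  seeds <- withr::with_seed(55, sample.int(1e6, 200))
  D_true <- 1.5e-6
  rel_err <- vapply(seeds, function(s) {
    curve <- simulate_desorption(D_true, 0.12, times = seq(50, 4000, by = 150),
                                 noise = "multiplicative", sigma = 0.02,
                                 seed = s)
    fit <- fit_diffusivity(curve, e = 0.12)
    abs(fit$D - D_true) / D_true
  }, numeric(1))
  expect_lt(stats::median(rel_err), 0.05)
})
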