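#' Fit the full third-order model to a 2^3 factorial design
#'
#' Estimates the eight coefficients of the coded-factor model
#' \deqn{y = \mu_0 + \mu_A A + \mu_B B + \mu_C C + \mu_{AB} AB + \mu_{AC} AC
#'       + \mu_{BC} BC + \mu_{ABC} ABC}
#' by ordinary least squares, which on the orthogonal +/-1 design is
#' identical to the classical contrast estimates (each coefficient is half
#' the difference of mean response between the +1 and -1 level of its
#' contrast column).  Coefficients are kept at full precision; a half-up
#' 2-decimal rounding is also reported for comparison with published
#' effect models.
#'
#' With eight runs and a single replicate the model is saturated: fitted
#' values equal the observations, residual degrees of freedom are zero,
#' and residual-based diagnostics are flagged undefined rather than
#' reported as numbers.
#'
#' @param design Tibble with coded columns `A`, `B`, `C` (values -1/+1,
#'   every combination present, optionally replicated) and the response.
#' @param response Column name (unquoted or string) of the response to fit.
#' @return An object of class `"factorial_fit"`.
#' @examples
#' fx <- cb3c_fixtures()
#' fit <- factorial_fit(fx$design, pLD50_SL)
#' tidy(fit)
#' glance(fit)
#' @export
factorial_fit <- function(design, response) {
  resp_name <- rlang::as_name(rlang::enquo(response))
  if (!resp_name %in% names(design)) {
    abort(paste0("response column not found: ", resp_name),
          class = "seedshield_validation_error")
  }
  n_rep <- validate_full_factorial(design)
  dat <- tibble(
    A = design$A, B = design$B, C = design$C,
    y = design[[resp_name]]
  )
  fit <- lm(y ~ A * B * C, data = dat)
  beta <- coef(fit)
  terms <- c("mu0", "A", "B", "C", "AB", "AC", "BC", "ABC")
  names(beta) <- terms[match(names(beta),
                             c("(Intercept)", "A", "B", "C",
                               "A:B", "A:C", "B:C", "A:B:C"))]
  beta <- beta[terms]
  structure(
    list(
      coefficients = beta,
      coefficients_2dp = round_half_up(beta, 2),
      response = resp_name,
      n = nrow(dat),
      replicates = n_rep,
      df.residual = fit$df.residual,
      lm = fit,
      data = dat
    ),
    class = "factorial_fit"
  )
}

# Half-up decimal rounding (0.005 -> 0.01), used only for display-style
# comparison of effect models; estimation is untouched.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.factorial_fit <- function(x, ...) {
  cat("2^3 factorial fit of", x$response, "\n")
  b <- x$coefficients_2dp
  cat(sprintf(
    "  %s = %.2f %+.2f A %+.2f B %+.2f C %+.2f AB %+.2f AC %+.2f BC %+.2f ABC\n",
    x$response, b[1], b[2], b[3], b[4], b[5], b[6], b[7], b[8]))
  cat(sprintf("  n = %d runs x %d replicate(s), residual df = %d%s\n",
              x$n / x$replicates, x$replicates, x$df.residual,
              if (x$df.residual == 0) " (saturated)" else ""))
  invisible(x)
}

#' @rdname factorial_fit
#' @param x,object A `factorial_fit` object.
#' @param ... Unused.
#' @method tidy factorial_fit
#' @export
tidy.factorial_fit <- function(x, ...) {
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    estimate_2dp = unname(x$coefficients_2dp)
  )
}

#' Summary statistics of a factorial fit
#'
#' One-row tibble of model diagnostics: response mean, model standard
#' deviation (root mean squared error), coefficient of variation,
#' R-squared, adjusted R-squared, PRESS-based predicted R-squared
#' (brute-force leave-one-out refits), adequate precision
#' (signal-to-noise: predicted range over its average standard error), and
#' the overall model F test.  On a saturated fit (zero residual degrees of
#' freedom) every residual-based quantity is `NA` and `saturated` is
#' `TRUE`; leave-one-out refits are then rank-deficient, so predicted
#' R-squared is also `NA`.
#'
#' @rdname factorial_fit
#' @method glance factorial_fit
#' @export
glance.factorial_fit <- function(x, ...) {
  y <- x$data$y
  n <- length(y)
  p <- 8L
  sst <- sum((y - mean(y))^2)
  sse <- sum(stats::residuals(x$lm)^2)
  dfe <- x$df.residual
  r2 <- 1 - sse / sst
  saturated <- dfe == 0L
  if (saturated) {
    mse <- NA_real_
    sd_model <- NA_real_
    cv <- NA_real_
    adj_r2 <- NA_real_
    adeq <- NA_real_
    fstat <- NA_real_
    pval <- NA_real_
  } else {
    mse <- sse / dfe
    sd_model <- sqrt(mse)
    cv <- 100 * sd_model / mean(y)
    adj_r2 <- 1 - (sse / dfe) / (sst / (n - 1))
    yhat <- stats::fitted(x$lm)
    adeq <- (max(yhat) - min(yhat)) / sqrt(p * mse / n)
    fstat <- ((sst - sse) / (p - 1)) / mse
    pval <- stats::pf(fstat, p - 1, dfe, lower.tail = FALSE)
  }
  press <- press_loo(x)
  tibble(
    mean = mean(y), sd = sd_model, cv_pct = cv,
    r.squared = r2, adj.r.squared = adj_r2,
    pred.r.squared = if (is.na(press)) NA_real_ else 1 - press / sst,
    adeq.precision = adeq,
    statistic = fstat, p.value = pval,
    df.residual = dfe, nobs = n, saturated = saturated
  )
}

# Brute-force leave-one-out PRESS: refit the same 8-term model without each
# observation and predict it back.  Returns NA when any refit cannot
# estimate all terms (single-replicate saturated design).
press_loo <- function(x) {
  dat <- x$data
  press <- 0
  for (i in seq_len(nrow(dat))) {
    refit <- lm(y ~ A * B * C, data = dat[-i, ])
    if (anyNA(coef(refit))) return(NA_real_)
    pred <- predict(refit, newdata = dat[i, ])
    press <- press + (dat$y[i] - pred)^2
  }
  unname(press)
}

#' Predict from a factorial fit at coded points
#'
#' Evaluates the full eight-term polynomial at coded factor settings.
#' Points outside the coded cube `[-1, 1]^3` trigger an extrapolation
#' warning but are still evaluated.
#'
#' @param object A `factorial_fit`.
#' @param newdata Tibble (or data frame) with columns `A`, `B`, `C`.
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.factorial_fit <- function(object, newdata, ...) {
  stopifnot(all(c("A", "B", "C") %in% names(newdata)))
  if (any(abs(newdata$A) > 1 | abs(newdata$B) > 1 | abs(newdata$C) > 1)) {
    warn("prediction point(s) outside the coded cube [-1, 1]^3: extrapolating")
  }
  X <- with(newdata, cbind(1, A, B, C, A * B, A * C, B * C, A * B * C))
  as.numeric(X %*% object$coefficients)
}

#' Contour grid of predicted response over a factor pair
#'
#' Evaluates the fitted model on a regular grid over the coded square of
#' two factors, the third held fixed (default -1, the level of the
#' best-performing formulation region).  Long format, ready for contour
#' plotting.
#'
#' @param fit A `factorial_fit`.
#' @param pair Character vector of two factor names among `"A"`, `"B"`,
#'   `"C"`.
#' @param fixed Coded level at which the remaining factor is held.
#' @param resolution Grid points per axis (`>= 2`).
#' @return Tibble with columns `A`, `B`, `C` and `.fitted`.
#' @examples
#' fit <- factorial_fit(cb3c_fixtures()$design, pLD50_SL)
#' contour_grid(fit, c("A", "C"), fixed = -1, resolution = 5)
#' @export
contour_grid <- function(fit, pair = c("A", "C"), fixed = -1, resolution = 50) {
  factors <- c("A", "B", "C")
  if (length(pair) != 2 || !all(pair %in% factors) || pair[1] == pair[2]) {
    abort("pair must name two distinct factors among A, B, C",
          class = "seedshield_validation_error")
  }
  if (resolution < 2) {
    abort("resolution must be >= 2", class = "seedshield_validation_error")
  }
  held <- setdiff(factors, pair)
  axis <- seq(-1, 1, length.out = resolution)
  grid <- tidyr::expand_grid(!!pair[1] := axis, !!pair[2] := axis)
  grid[[held]] <- fixed
  grid <- grid[, factors]
  grid$.fitted <- predict(fit, grid)
  grid
}

#' @rdname factorial_fit
#' @param pair,fixed,resolution Passed to [contour_grid()].
#' @method autoplot factorial_fit
#' @export
autoplot.factorial_fit <- function(object, pair = c("A", "C"), fixed = -1,
                                   resolution = 50, ...) {
  grid <- contour_grid(object, pair, fixed, resolution)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data[[pair[1]]],
                                     y = .data[[pair[2]]],
                                     z = .data$.fitted)) +
    ggplot2::geom_contour_filled() +
    ggplot2::labs(title = paste0("Predicted ", object$response),
                  subtitle = paste0(setdiff(c("A", "B", "C"), pair),
                                    " held at ", fixed))
}
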