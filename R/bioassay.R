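#' Abbott-corrected mortality
#'
#' Adjusts observed treated mortality for background control mortality:
#' \deqn{CM\% = \frac{MOI - MOC}{100 - MOC} \times 100.}
#' Values that come out negative (treated mortality below control) are
#' clamped to zero with a warning; the `"negative_corrected"` attribute
#' flags the affected entries.
#'
#' @param moi Observed treated mortality, percent, in `[0, 100]`
#'   (vectorised).
#' @param moc Observed control mortality, percent, in `[0, 100)`.
#' @return Corrected mortality in percent, clamped to `[0, 100]`, with a
#'   logical attribute `negative_corrected`.
#' @examples
#' corrected_mortality(55, 10)   # 50
#' @export
corrected_mortality <- function(moi, moc) {
  if (any(moi < 0 | moi > 100)) {
    abort("MOI must lie in [0, 100]", class = "seedshield_domain_error")
  }
  if (any(moc < 0 | moc > 100)) {
    abort("MOC must lie in [0, 100]", class = "seedshield_domain_error")
  }
  if (any(moc == 100)) {
    abort("control mortality of 100% invalidates the assay",
          class = "seedshield_domain_error")
  }
  cm <- (moi - moc) / (100 - moc) * 100
  neg <- cm < 0
  if (any(neg)) {
    warn(paste0(sum(neg), " corrected mortalit",
                if (sum(neg) == 1) "y" else "ies",
                " below zero (treated < control); clamped to 0"))
    cm[neg] <- 0
  }
  cm <- pmin(cm, 100)
  attr(cm, "negative_corrected") <- neg
  cm
}

# First upward crossing of 50% corrected mortality on the ln-dose axis.
# Ties (exact 50% hits) resolve to the lowest such dose.
interpolate_ld50 <- function(log_dose, cm) {
  ord <- order(log_dose)
  log_dose <- log_dose[ord]
  cm <- cm[ord]
  for (i in seq_along(cm)) {
    if (cm[i] == 50) {
      return(list(pld50 = log_dose[i], bracket = c(i, i)))
    }
    if (i < length(cm) && cm[i] < 50 && cm[i + 1] > 50) {
      p <- log_dose[i] + (50 - cm[i]) / (cm[i + 1] - cm[i]) *
        (log_dose[i + 1] - log_dose[i])
      return(list(pld50 = p, bracket = c(i, i + 1)))
    }
  }
  abort("corrected mortality never crosses 50% within the dose range; refusing to extrapolate",
        class = "seedshield_range_error")
}

#' Median lethal dose by log-linear interpolation
#'
#' Computes per-dose Abbott-corrected mortality from a dose-response assay
#' and locates the LD50 by piecewise-linear interpolation of CM% against
#' the natural logarithm of dose: pLD50 = ln(dose) at the first upward
#' crossing of 50%, and LD50 = exp(pLD50).  Corrected mortality is averaged
#' across replicates within each dose before interpolation; control
#' mortality is taken per replicate from the control rows (doses of 0 or
#' rows with `is_control = TRUE`).  No parametric dose-response model is
#' fitted.
#'
#' @param assay Tibble with columns `dose`, `replicate`, `exposed`, `dead`
#'   and optionally `is_control` (control rows may instead carry
#'   `dose = 0`).
#' @return An object of class `"ld50_fit"`: `ld50`, `pld50`,
#'   `bracket` (the bracketing dose pair), and `cm_table` (per-dose CM%).
#' @examples
#' assay <- simulate_bioassay(doses = c(0.25, 0.5, 1, 2, 4), n_per_dose = 30,
#'                            ld50 = 1, slope = 3, seed = 11)
#' pld50(assay)
#' @export
pld50 <- function(assay) {
  if (!"is_control" %in% names(assay)) {
    assay$is_control <- assay$dose == 0
  }
  if (!"replicate" %in% names(assay)) assay$replicate <- 1L
  validate_assay(assay)
  treated <- dplyr::filter(assay, !.data$is_control)
  if (dplyr::n_distinct(treated$dose) < 2) {
    abort("at least 2 distinct doses required", class = "seedshield_validation_error")
  }
  controls <- dplyr::filter(assay, .data$is_control)
  moc_by_rep <- if (nrow(controls) > 0) {
    dplyr::summarise(dplyr::group_by(controls, .data$replicate),
                     moc = 100 * sum(.data$dead) / sum(.data$exposed))
  } else {
    tibble(replicate = unique(treated$replicate), moc = 0)
  }
  per_rep <- dplyr::left_join(treated, moc_by_rep, by = "replicate")
  per_rep$moc[is.na(per_rep$moc)] <- 0
  per_rep$moi <- 100 * per_rep$dead / per_rep$exposed
  suppressWarnings(per_rep$cm <- as.numeric(corrected_mortality(per_rep$moi, per_rep$moc)))
  per_rep$negative_corrected <- per_rep$moi < per_rep$moc
  cm_table <- dplyr::summarise(
    dplyr::group_by(per_rep, .data$dose),
    moi = mean(.data$moi), moc = mean(.data$moc), cm = mean(.data$cm),
    negative_corrected = any(.data$negative_corrected),
    .groups = "drop"
  )
  cm_table <- dplyr::arrange(cm_table, .data$dose)
  cm_table$log_dose <- log(cm_table$dose)
  cross <- interpolate_ld50(cm_table$log_dose, cm_table$cm)
  structure(
    list(
      ld50 = exp(cross$pld50),
      pld50 = cross$pld50,
      bracket = cm_table$dose[cross$bracket],
      cm_table = cm_table
    ),
    class = "ld50_fit"
  )
}

#' @export
print.ld50_fit <- function(x, ...) {
  cat(sprintf("LD50 = %.4g (pLD50 = ln LD50 = %.4f)\n", x$ld50, x$pld50))
  cat(sprintf("  bracketing doses: [%g, %g]\n", x$bracket[1], x$bracket[2]))
  invisible(x)
}

#' @rdname pld50
#' @param x,object An `ld50_fit` object.
#' @param ... Unused.
#' @method tidy ld50_fit
#' @export
tidy.ld50_fit <- function(x, ...) x$cm_table

#' @rdname pld50
#' @method glance ld50_fit
#' @export
glance.ld50_fit <- function(x, ...) {
  tibble(ld50 = x$ld50, pld50 = x$pld50,
         bracket_low = x$bracket[1], bracket_high = x$bracket[2],
         n_doses = nrow(x$cm_table))
}

#' @rdname pld50
#' @method autoplot ld50_fit
#' @export
autoplot.ld50_fit <- function(object, ...) {
  ggplot2::ggplot(object$cm_table,
                  ggplot2::aes(x = .data$log_dose, y = .data$cm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 50, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$pld50, colour = "steelblue") +
    ggplot2::labs(x = "ln(dose)", y = "corrected mortality (%)",
                  title = sprintf("pLD50 = %.3f", object$pld50))
}

#' Sampling distribution of the pLD50 estimator
#'
#' Repeatedly simulates a dose-mortality assay under a known tolerance
#' curve, estimates pLD50 from each replicate by [pld50()], and summarises
#' the estimates.  Replicate assays whose corrected mortality never crosses
#' 50% are counted as failures, not silently dropped into the mean.
#'
#' @param reps Number of simulated assays.
#' @param seed Master seed; each replicate draws an independent derived
#'   substream.
#' @inheritParams simulate_bioassay
#' @return One-row tibble: `mean`, `se`, `sd`, `n_ok`, `n_failed`.
#' @export
pld50_from_simulation <- function(doses, n_per_dose = 10, replicates = 3,
                                  control_mortality = 0.05, ld50 = 1,
                                  slope = 2, reps = 100, seed = 1) {
  if (ld50 < min(doses) || ld50 > max(doses)) {
    abort("true LD50 must lie within the dose range",
          class = "seedshield_validation_error")
  }
  sub_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, reps))
  est <- purrr::map_dbl(sub_seeds, function(s) {
    assay <- simulate_bioassay(doses, n_per_dose, replicates,
                               control_mortality, ld50, slope, seed = s)
    tryCatch(pld50(assay)$pld50,
             seedshield_range_error = function(e) NA_real_)
  })
  ok <- est[!is.na(est)]
  tibble(
    mean = mean(ok),
    se = sd(ok) / sqrt(length(ok)),
    sd = sd(ok),
    n_ok = length(ok),
    n_failed = sum(is.na(est))
  )
}
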