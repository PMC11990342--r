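#' Pearson correlation matrix of a variable table
#'
#' Product-moment correlations between the numeric columns of a tibble
#' (identifier columns are dropped).  Requires at least three observations
#' and a nonzero variance in every variable; a degenerate column is named
#' in the error.
#'
#' @param data Tibble of observations by variables; non-numeric columns
#'   are treated as identifiers and ignored.
#' @param digits Optional rounding for display (e.g. 3); full precision by
#'   default.
#' @return Symmetric correlation matrix with unit diagonal.
#' @examples
#' correlation_matrix(cb3c_variable_matrix(), digits = 3)
#' @export
correlation_matrix <- function(data, digits = NULL) {
  m <- as_numeric_matrix(data)
  if (nrow(m) < 3) {
    abort("at least 3 observations required", class = "seedshield_validation_error")
  }
  v <- apply(m, 2, var)
  if (any(v == 0)) {
    abort(paste0("zero-variance variable: ",
                 paste(colnames(m)[v == 0], collapse = ", ")),
          class = "seedshield_validation_error")
  }
  r <- cor(m)
  if (!is.null(digits)) r <- round(r, digits)
  r
}

as_numeric_matrix <- function(data) {
  num <- dplyr::select(as_tibble(data), dplyr::where(is.numeric))
  if (anyNA(num)) {
    abort("variable matrix has missing cells", class = "seedshield_validation_error")
  }
  ids <- dplyr::select(as_tibble(data), !dplyr::where(is.numeric))
  m <- as.matrix(num)
  if (ncol(ids) > 0) rownames(m) <- as.character(ids[[1]])
  m
}

#' Principal component analysis on the correlation scale
#'
#' Eigendecomposition of the correlation matrix (variables standardised
#' with the sample n-1 convention), returned with eigenvalues in
#' descending order.  Sign convention: each loading vector is oriented so
#' that its largest-magnitude entry is positive, with scores flipped to
#' match.
#'
#' @inheritParams correlation_matrix
#' @return An object of class `"assoc_pca"`: `eigenvalues`, `loadings`
#'   (variables x components), `scores` (observations x components, as a
#'   tibble with the identifier column kept), `prop_variance`.
#' @examples
#' pca_correlation(cb3c_variable_matrix())
#' @export
pca_correlation <- function(data) {
  m <- as_numeric_matrix(data)
  if (nrow(m) < 3) {
    abort("at least 3 observations required", class = "seedshield_validation_error")
  }
  v <- apply(m, 2, var)
  if (any(v == 0)) {
    abort(paste0("zero-variance variable: ",
                 paste(colnames(m)[v == 0], collapse = ", ")),
          class = "seedshield_validation_error")
  }
  pc <- prcomp(m, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2, function(col) {
    sign(col[which.max(abs(col))])
  })
  flip[flip == 0] <- 1
  rotation <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  structure(
    list(
      eigenvalues = unname(pc$sdev^2),
      loadings = rotation,
      scores = dplyr::bind_cols(
        tibble(observation = rownames(m) %||% as.character(seq_len(nrow(m)))),
        as_tibble(scores)
      ),
      prop_variance = unname(pc$sdev^2 / sum(pc$sdev^2))
    ),
    class = "assoc_pca"
  )
}

#' @export
print.assoc_pca <- function(x, ...) {
  cat("PCA (correlation mode):", length(x$eigenvalues), "components\n")
  cat("  eigenvalues:", paste(sprintf("%.3f", x$eigenvalues), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname pca_correlation
#' @param x,object An `assoc_pca` object.
#' @param ... Unused.
#' @method tidy assoc_pca
#' @export
tidy.assoc_pca <- function(x, ...) {
  tibble(
    component = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    prop_variance = x$prop_variance,
    cum_variance = cumsum(x$prop_variance)
  )
}

#' @rdname pca_correlation
#' @method autoplot assoc_pca
#' @export
autoplot.assoc_pca <- function(object, ...) {
  load <- as_tibble(object$loadings, rownames = "variable")
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$observation),
                       vjust = -0.6, size = 3) +
    ggplot2::geom_segment(
      data = load,
      ggplot2::aes(x = 0, y = 0,
                   xend = .data$PC1 * max(abs(object$scores$PC1)),
                   yend = .data$PC2 * max(abs(object$scores$PC2))),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "steelblue"
    ) +
    ggplot2::labs(title = "PCA of diffusion and activity variables",
                  x = sprintf("PC1 (%.1f%%)", 100 * object$prop_variance[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * object$prop_variance[2]))
}

# Accepts a 2x2 (or r x c) counts matrix, or a tibble whose first column
# holds row labels (e.g. species) and remaining columns counts.
as_contingency_matrix <- function(x) {
  if (is.matrix(x)) {
    m <- x
  } else {
    x <- as_tibble(x)
    labcol <- !vapply(x, is.numeric, logical(1))
    m <- as.matrix(x[, !labcol])
    if (any(labcol)) rownames(m) <- as.character(x[[which(labcol)[1]]])
  }
  if (any(m < 0) || any(m != round(m))) {
    abort("counts must be non-negative integers",
          class = "seedshield_validation_error")
  }
  if (sum(m) == 0) {
    abort("contingency table has zero total", class = "seedshield_validation_error")
  }
  m
}

#' Pearson chi-square test of independence
#'
#' Plain or Yates-corrected chi-square statistic for a contingency table:
#' expected counts are `row total x column total / N`; the plain statistic
#' is `sum((O - E)^2 / E)` and the Yates variant shrinks each `|O - E|` by
#' 0.5 (floored at zero) before squaring.  The p-value is the upper tail
#' of the chi-square distribution with `(r-1)(c-1)` degrees of freedom.
#'
#' @param table Counts as a matrix, or a tibble with a label column
#'   followed by count columns (e.g. `species`, `male`, `female`).
#' @param yates Apply the continuity correction (2x2 tables only).
#' @return One-row tibble: `statistic`, `df`, `p.value`, `method`.
#' @examples
#' chi2_independence(cb3c_fixtures()$contingency)
#' chi2_independence(cb3c_fixtures()$contingency, yates = TRUE)
#' @export
chi2_independence <- function(table, yates = FALSE) {
  m <- as_contingency_matrix(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("zero marginal total", class = "seedshield_validation_error")
  }
  N <- sum(m)
  E <- outer(rowSums(m), colSums(m)) / N
  dev <- abs(m - E)
  if (yates) {
    if (!all(dim(m) == c(2, 2))) {
      abort("Yates correction applies to 2x2 tables only",
            class = "seedshield_validation_error")
    }
    dev <- pmax(dev - 0.5, 0)
  }
  stat <- sum(dev^2 / E)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  tibble(
    statistic = stat, df = df,
    p.value = pchisq(stat, df, lower.tail = FALSE),
    method = if (yates) "Pearson chi-square (Yates)" else "Pearson chi-square"
  )
}

#' Association coefficients of a 2x2 contingency table
#'
#' Computes the full descriptive battery for a 2x2 species-by-sex mortality
#' table: both chi-square variants with p-values, the chi-square-based
#' measures (phi, contingency coefficient C, Cramer's V, Tschuprow's T —
#' all equal for 2x2 tables), Goodman-Kruskal lambda in its symmetric and
#' both asymmetric directions, Cohen's kappa (treating the square table as
#' an agreement table; descriptive only), and the odds-ratio-based Yule's
#' Q and Y.
#'
#' Closed forms on counts `[[a, b], [c, d]]`, `N = a+b+c+d`:
#' `phi = sqrt(chi2/N)`, `C = sqrt(chi2/(chi2+N))`,
#' `V = sqrt(chi2/(N (min(r,c)-1)))`, `T = sqrt(chi2/(N sqrt((r-1)(c-1))))`,
#' `Q = (ad-bc)/(ad+bc)`, `Y = (sqrt(ad)-sqrt(bc))/(sqrt(ad)+sqrt(bc))`.
#' When `ad + bc = 0`, Q and Y are undefined and flagged `NA`.
#'
#' @inheritParams chi2_independence
#' @return An object of class `"association_bundle"`; use [tidy()] for a
#'   coefficient table with both full-precision and 3-decimal values.
#' @examples
#' bundle <- association_coefficients(cb3c_fixtures()$contingency)
#' tidy(bundle)
#' @export
association_coefficients <- function(table) {
  m <- as_contingency_matrix(table)
  if (!all(dim(m) == c(2, 2))) {
    abort("a 2x2 table is required", class = "seedshield_validation_error")
  }
  N <- sum(m)
  plain <- chi2_independence(m, yates = FALSE)
  yates <- chi2_independence(m, yates = TRUE)
  chi2 <- plain$statistic
  r <- nrow(m); k <- ncol(m)
  phi <- sqrt(chi2 / N)
  C <- sqrt(chi2 / (chi2 + N))
  V <- sqrt(chi2 / (N * (min(r, k) - 1)))
  Tt <- sqrt(chi2 / (N * sqrt((r - 1) * (k - 1))))
  # Goodman-Kruskal lambda: proportional reduction in prediction error
  lambda_col_given_row <- gk_lambda(m, predict = "col")
  lambda_row_given_col <- gk_lambda(m, predict = "row")
  lambda_sym <- gk_lambda(m, predict = "sym")
  po <- sum(diag(m)) / N
  pe <- sum(rowSums(m) * colSums(m)) / N^2
  kappa <- (po - pe) / (1 - pe)
  a <- m[1, 1]; b <- m[1, 2]; cc <- m[2, 1]; d <- m[2, 2]
  if (a * d + b * cc == 0) {
    Q <- NA_real_; Y <- NA_real_
    flags <- "Yule's Q/Y undefined (ad + bc = 0)"
  } else {
    Q <- (a * d - b * cc) / (a * d + b * cc)
    Y <- (sqrt(a * d) - sqrt(b * cc)) / (sqrt(a * d) + sqrt(b * cc))
    flags <- character(0)
  }
  structure(
    list(
      n = N,
      chi_squared = chi2, p_value = plain$p.value,
      chi_squared_yates = yates$statistic, p_value_yates = yates$p.value,
      phi = phi, contingency_coefficient = C, cramers_v = V,
      tschuprows_t = Tt,
      lambda = lambda_col_given_row,
      lambda_row_given_col = lambda_row_given_col,
      lambda_symmetric = lambda_sym,
      kappa = kappa, yule_q = Q, yule_y = Y,
      flags = flags
    ),
    class = "association_bundle"
  )
}

gk_lambda <- function(m, predict = c("col", "row", "sym")) {
  predict <- match.arg(predict)
  N <- sum(m)
  # error predicting columns within each row vs from the column margin
  col_term <- sum(apply(m, 1, max)) - max(colSums(m))
  col_denom <- N - max(colSums(m))
  row_term <- sum(apply(m, 2, max)) - max(rowSums(m))
  row_denom <- N - max(rowSums(m))
  switch(predict,
    col = if (col_denom == 0) 0 else col_term / col_denom,
    row = if (row_denom == 0) 0 else row_term / row_denom,
    sym = if (col_denom + row_denom == 0) 0
          else (col_term + row_term) / (col_denom + row_denom)
  )
}

#' @export
print.association_bundle <- function(x, ...) {
  cat(sprintf("2x2 association battery (N = %d)\n", x$n))
  cat(sprintf("  chi2 = %.4f (p = %.3f); Yates chi2 = %.4f (p = %.3f)\n",
              x$chi_squared, x$p_value, x$chi_squared_yates, x$p_value_yates))
  cat(sprintf("  phi = V = T = %.3f, C = %.3f, lambda = %.3f, kappa = %.3f\n",
              x$phi, x$contingency_coefficient, x$lambda, x$kappa))
  cat(sprintf("  Yule's Q = %.3f, Y = %.3f\n", x$yule_q, x$yule_y))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @rdname association_coefficients
#' @param x An `association_bundle` object.
#' @param ... Unused.
#' @method tidy association_bundle
#' @export
tidy.association_bundle <- function(x, ...) {
  vals <- c(
    chi_squared = x$chi_squared,
    chi_squared_yates = x$chi_squared_yates,
    p_value = x$p_value,
    p_value_yates = x$p_value_yates,
    phi = x$phi,
    contingency_coefficient = x$contingency_coefficient,
    cramers_v = x$cramers_v,
    tschuprows_t = x$tschuprows_t,
    lambda = x$lambda,
    lambda_row_given_col = x$lambda_row_given_col,
    lambda_symmetric = x$lambda_symmetric,
    kappa = x$kappa,
    yule_q = x$yule_q,
    yule_y = x$yule_y
  )
  tibble(
    coefficient = names(vals),
    value = unname(vals),
    value_3dp = round(unname(vals), 3)
  )
}
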