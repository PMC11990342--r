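#' Bundled study tables for the CB3C biofilm series
#'
#' Loads the printed data tables of the CB3C composite-biofilm study into a
#' validated list of tibbles: the 2^3 factorial design with its pLD50
#' responses for *Sitona lineatus* and *Bruchus pisorum*, the per-biofilm
#' desorption parameters (diffusivity D, evaporation constant K, initial
#' flux F), the physical film constants (thickness and mechanical
#' properties), the species-by-sex mortality contingency counts, and the
#' docking binding affinities.
#'
#' The desorption table is printed on display scales (x10^6, x10^3, x10^5);
#' those scales are undone on load so that `desorption` carries base units:
#' D in mm^2/day, K in 1/day, F in g/(day cm^2).
#'
#' @param dir Directory holding the fixture CSV files.  Defaults to the
#'   copies bundled with the package.
#' @return A list with elements `design`, `desorption`, `film`,
#'   `contingency`, `docking`, each a tibble, plus `film_thickness_mm`
#'   (numeric scalar, the slab thickness e).
#' @examples
#' fx <- cb3c_fixtures()
#' fx$desorption
#' @export
cb3c_fixtures <- function(dir = NULL) {
  dir <- dir %||% system.file("extdata", package = "seedshield")
  if (!dir.exists(dir)) {
    abort(paste0("fixture directory not found: ", dir), class = "seedshield_io_error")
  }
  design <- read_factorial_design(file.path(dir, "table1_design.csv"))

  desorption <- read_fixture_csv(
    file.path(dir, "table4_desorption.csv"),
    readr::cols(
      biofilm = readr::col_character(),
      D_x1e6_mm2_per_day = readr::col_double(),
      K_x1e3_per_day = readr::col_double(),
      F_x1e5_g_per_day_per_cm2 = readr::col_double()
    )
  )
  desorption <- tibble(
    biofilm = desorption$biofilm,
    D = desorption$D_x1e6_mm2_per_day * 1e-6,
    K = desorption$K_x1e3_per_day * 1e-3,
    F = desorption$F_x1e5_g_per_day_per_cm2 * 1e-5
  )
  if (any(!is.finite(unlist(desorption[, c("D", "K", "F")]))) ||
      any(desorption$D <= 0 | desorption$K <= 0 | desorption$F <= 0)) {
    abort("desorption parameters must all be strictly positive",
          class = "seedshield_validation_error")
  }

  film <- read_fixture_csv(
    file.path(dir, "table6_film.csv"),
    readr::cols(
      property = readr::col_character(), symbol = readr::col_character(),
      value = readr::col_double(), uncertainty = readr::col_double(),
      unit = readr::col_character()
    )
  )
  e <- film$value[film$symbol == "e"]
  if (length(e) != 1L || !is.finite(e) || e <= 0) {
    abort("film table must contain one positive thickness row (symbol 'e')",
          class = "seedshield_validation_error")
  }

  contingency <- read_contingency(file.path(dir, "table7_contingency.csv"))

  docking <- read_fixture_csv(
    file.path(dir, "table9_docking.csv"),
    readr::cols(target = readr::col_character(),
                affinity_kcal_mol = readr::col_double())
  )

  list(
    design = design,
    desorption = desorption,
    film = film,
    film_thickness_mm = e,
    contingency = contingency,
    docking = docking
  )
}

#' Assemble the diffusion-activity variable matrix
#'
#' Joins the desorption parameters (D, K, F) with the factorial pLD50
#' responses into the 8-observation, 5-variable matrix used for the
#' correlation and principal component analyses.
#'
#' @param fixtures A fixture list as returned by [cb3c_fixtures()].
#' @return A tibble with columns `biofilm`, `D`, `K`, `F`, `pLD50_SL`,
#'   `pLD50_BP`.
#' @examples
#' cb3c_variable_matrix()
#' @export
cb3c_variable_matrix <- function(fixtures = cb3c_fixtures()) {
  dplyr::inner_join(
    fixtures$desorption,
    dplyr::select(fixtures$design, "biofilm", "pLD50_SL", "pLD50_BP"),
    by = "biofilm"
  )
}

# Shared CSV reader: readr with an explicit column contract; a mismatch is
# reported as a parse error naming the offending column.
read_fixture_csv <- function(path, col_types) {
  if (!file.exists(path)) {
    abort(paste0("fixture file not found: ", path), class = "seedshield_io_error")
  }
  out <- readr::read_csv(path, col_types = col_types, progress = FALSE)
  problems <- readr::problems(out)
  if (nrow(problems) > 0) {
    abort(paste0("malformed CSV ", basename(path), ": row ", problems$row[1],
                 ", column ", problems$col[1], " (", problems$expected[1], ")"),
          class = "seedshield_parse_error")
  }
  missing <- setdiff(names(col_types$cols), names(out))
  if (length(missing) > 0) {
    abort(paste0("malformed CSV ", basename(path), ": missing column(s) ",
                 paste(missing, collapse = ", ")),
          class = "seedshield_parse_error")
  }
  out
}

# A full 2^3 design must contain every +/-1 combination of A, B, C exactly
# once per replicate block.
validate_full_factorial <- function(design, call = rlang::caller_env()) {
  needed <- c("A", "B", "C")
  missing <- setdiff(needed, names(design))
  if (length(missing) > 0) {
    abort(paste0("design is missing factor column(s): ",
                 paste(missing, collapse = ", ")),
          class = "seedshield_validation_error", call = call)
  }
  lev <- unlist(design[needed])
  if (!all(lev %in% c(-1, 1))) {
    abort("factor levels must be coded -1/+1",
          class = "seedshield_validation_error", call = call)
  }
  full <- tidyr::expand_grid(A = c(-1, 1), B = c(-1, 1), C = c(-1, 1))
  counts <- dplyr::count(design, .data$A, .data$B, .data$C)
  merged <- dplyr::left_join(full, counts, by = needed)
  n_rep <- merged$n[1]
  if (any(is.na(merged$n)) || length(unique(merged$n)) != 1L) {
    miss <- merged[is.na(merged$n) | merged$n != max(merged$n, na.rm = TRUE), ]
    abort(paste0("not a full 2^3 factorial design; run (",
                 paste(miss[1, c("A", "B", "C")], collapse = ","),
                 ") missing or unbalanced"),
          class = "seedshield_validation_error", call = call)
  }
  invisible(n_rep)
}
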