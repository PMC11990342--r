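#' Read and write stage tables
#'
#' Plain-CSV serialisation for every tabular type in the pipeline
#' (desorption curves, dose-response assays, factorial designs,
#' contingency counts, diffusion-activity variable matrices).  Values
#' round-trip at full double precision; readers validate the column
#' contract and the type's invariants on load.
#'
#' @param x Tibble to write.
#' @param path File path.
#' @return Readers return a validated tibble; writers return `path`
#'   invisibly.
#' @name stage_io
NULL

#' @rdname stage_io
#' @export
write_desorption_curve <- function(x, path) {
  stopifnot(all(c("time_days", "fraction") %in% names(x)))
  readr::write_csv(x[, c("time_days", "fraction")], path)
  invisible(path)
}

#' @rdname stage_io
#' @export
read_desorption_curve <- function(path) {
  out <- read_fixture_csv(path, readr::cols(
    time_days = readr::col_double(), fraction = readr::col_double()
  ))
  validate_desorption_curve(out)
  out
}

validate_desorption_curve <- function(curve, call = rlang::caller_env()) {
  if (nrow(curve) < 2 || any(diff(curve$time_days) <= 0) || curve$time_days[1] < 0) {
    abort("times must be a strictly increasing grid of >= 2 non-negative values",
          class = "seedshield_validation_error", call = call)
  }
  if (any(!is.finite(curve$fraction)) ||
      any(curve$fraction <= 0 | curve$fraction > 1)) {
    abort("fractions Mt/M0 must lie in (0, 1]",
          class = "seedshield_validation_error", call = call)
  }
  invisible(curve)
}

#' @rdname stage_io
#' @export
write_assay <- function(x, path) {
  cols <- c("dose", "replicate", "exposed", "dead", "is_control")
  stopifnot(all(cols %in% names(x)))
  readr::write_csv(x[, cols], path)
  invisible(path)
}

#' @rdname stage_io
#' @export
read_assay <- function(path) {
  out <- read_fixture_csv(path, readr::cols(
    dose = readr::col_double(), replicate = readr::col_integer(),
    exposed = readr::col_integer(), dead = readr::col_integer(),
    is_control = readr::col_logical()
  ))
  validate_assay(out)
  out
}

validate_assay <- function(assay, call = rlang::caller_env()) {
  if (any(assay$dead > assay$exposed)) {
    abort("dead counts exceed exposed counts",
          class = "seedshield_validation_error", call = call)
  }
  if (any(assay$dose[!assay$is_control] <= 0)) {
    abort("treatment doses must be strictly positive",
          class = "seedshield_validation_error", call = call)
  }
  invisible(assay)
}

#' @rdname stage_io
#' @export
write_factorial_design <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname stage_io
#' @export
read_factorial_design <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    biofilm = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  problems <- readr::problems(out)
  if (nrow(problems) > 0) {
    abort(paste0("malformed CSV ", basename(path), ": row ", problems$row[1],
                 ", column ", problems$col[1]),
          class = "seedshield_parse_error")
  }
  validate_full_factorial(out)
  out
}

#' @rdname stage_io
#' @export
write_contingency <- function(x, path) {
  stopifnot(all(c("species", "male", "female") %in% names(x)))
  readr::write_csv(x[, c("species", "male", "female")], path)
  invisible(path)
}

#' @rdname stage_io
#' @export
read_contingency <- function(path) {
  out <- read_fixture_csv(path, readr::cols(
    species = readr::col_character(),
    male = readr::col_double(), female = readr::col_double()
  ))
  counts <- unlist(out[, c("male", "female")])
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("contingency counts must be non-negative integers",
          class = "seedshield_validation_error")
  }
  out
}

#' @rdname stage_io
#' @export
write_variable_matrix <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname stage_io
#' @export
read_variable_matrix <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    biofilm = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  if (anyNA(out)) {
    abort("variable matrix has missing cells",
          class = "seedshield_validation_error")
  }
  out
}

#' Write a deterministic run report
#'
#' Serialises the outputs of one or more pipeline stages to an output
#' directory: one `report.json` carrying the seed, a configuration echo and
#' every result, plus one CSV per tabular result.  The report contains no
#' timestamps, so two runs with the same seed and inputs are byte-identical.
#'
#' @param results Named list of stage outputs (tibbles, named lists or
#'   scalars).  Must be non-empty.
#' @param dir Output directory, created if needed.
#' @param seed Integer seed recorded in the report.
#' @param config Optional named list echoed verbatim into the report.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(results, dir, seed, config = list()) {
  if (length(results) == 0) {
    abort("no stage results to report", class = "seedshield_validation_error")
  }
  if (is.null(names(results)) || any(names(results) == "")) {
    abort("results must be a fully named list", class = "seedshield_validation_error")
  }
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create output directory: ", dir),
                   class = "seedshield_io_error")
  }
  paths <- character(0)
  for (nm in names(results)) {
    if (is.data.frame(results[[nm]])) {
      p <- file.path(dir, paste0(nm, ".csv"))
      readr::write_csv(results[[nm]], p)
      paths <- c(paths, p)
    }
  }
  report <- list(
    package = "seedshield",
    seed = seed,
    config = config,
    stages = names(results),
    results = results
  )
  jpath <- file.path(dir, "report.json")
  jsonlite::write_json(report, jpath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", pretty = TRUE)
  invisible(c(paths, jpath))
}
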