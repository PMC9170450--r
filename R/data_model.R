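#' wetval: value transfer for wetland ecosystem services
#'
#' Calibrates a log-linear coupling model on a database of published wetland
#' valuation cases and transfers per-hectare service values to a target
#' wetland inventory. Unit values are expressed in yuan/(hm^2 * yr) at a
#' common price level; aggregated totals in yuan/yr. See
#' `vignette("wetval-methods")` for the model and its assumptions.
#'
#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Case schema
# ---------------------------------------------------------------------------

#' Declare the column schema of a valuation-case table
#'
#' A valuation case is one observed unit value for one ecosystem service at
#' one wetland, together with the covariates the coupling model uses. The
#' covariate set is open: `natural` names the wetland-intrinsic columns
#' (scale, shape and similar descriptors) and `environment` names the
#' socio-economic/environmental columns that interact with the supply score.
#'
#' @param natural character vector of column names holding wetland-intrinsic
#'   covariates.
#' @param environment character vector of column names holding environmental
#'   and socio-economic covariates.
#' @return An object of class `case_schema`.
#' @export
case_schema <- function(natural = character(), environment = character()) {
  natural <- as.character(natural)
  environment <- as.character(environment)
  if (anyDuplicated(c(natural, environment)))
    stop_validation("covariate names duplicated across natural/environment blocks")
  structure(list(natural = natural, environment = environment),
            class = "case_schema")
}

.case_required_cols <- c("case_id", "wetland_id", "wetland_type", "service",
                         "method", "base_year", "value_raw", "area")

#' Validate a table of valuation cases
#'
#' Checks the invariants the coupling model relies on: positive observed
#' unit values (their logarithm is taken), positive areas, and presence of
#' every covariate column named by the schema. Missing covariate values are
#' a hard error: the model defines no missing-data mechanism.
#'
#' @param cases data.frame of valuation cases.
#' @param schema a [case_schema()].
#' @param cpi optional [cpi_series()]; when given, every `base_year` must be
#'   covered by the series.
#' @return `cases`, invisibly, with `base_year` as integer.
#' @export
validate_cases <- function(cases, schema = case_schema(), cpi = NULL) {
  if (!is.data.frame(cases)) stop_validation("cases must be a data.frame")
  missing_cols <- setdiff(.case_required_cols, names(cases))
  if (length(missing_cols))
    stop_validation("missing required column(s): ", paste(missing_cols, collapse = ", "))
  covs <- c(schema$natural, schema$environment)
  missing_covs <- setdiff(covs, names(cases))
  if (length(missing_covs))
    stop_validation("missing covariate column(s): ", paste(missing_covs, collapse = ", "))

  bad <- which(!is.finite(cases$value_raw) | cases$value_raw <= 0)
  if (length(bad))
    stop_validation("value_raw must be > 0 (log is taken); offending row(s): ",
                    paste(bad, collapse = ", "))
  bad <- which(!is.finite(cases$area) | cases$area <= 0)
  if (length(bad))
    stop_validation("area must be > 0; offending row(s): ",
                    paste(bad, collapse = ", "))
  for (cc in covs) {
    bad <- which(!is.finite(as.numeric(cases[[cc]])))
    if (length(bad))
      stop_validation("covariate '", cc, "' missing/non-finite at row(s): ",
                      paste(bad, collapse = ", "))
  }
  cases$base_year <- as.integer(cases$base_year)
  if (!is.null(cpi)) {
    missing_years <- setdiff(unique(cases$base_year), as.integer(names(cpi$index_by_year)))
    if (length(missing_years))
      stop_validation("base_year(s) absent from CPI series: ",
                      paste(sort(missing_years), collapse = ", "))
  }
  invisible(cases)
}

#' Read a valuation-case database from CSV
#'
#' One row per (case, service, method) observation. Required columns:
#' `case_id`, `wetland_id`, `wetland_type`, `service`, `method`,
#' `base_year`, `value_raw` (yuan/(hm^2 * yr) at `base_year` prices) and
#' `area` (hm^2). Covariate columns are routed by the schema; unknown extra
#' columns are kept but unused.
#'
#' @inheritParams validate_cases
#' @param path CSV file path.
#' @return data.frame of validated cases with attribute `"schema"`.
#' @export
read_cases <- function(path, schema = case_schema(), cpi = NULL) {
  cases <- utils::read.csv(path, stringsAsFactors = FALSE)
  cases <- validate_cases(cases, schema = schema, cpi = cpi)
  attr(cases, "schema") <- schema
  cases
}

#' Write a pipeline result table to CSV
#'
#' Numbers are written at full precision (15 significant digits) so that a
#' read-back reproduces them exactly for text-representable values.
#'
#' @param table data.frame to write.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  if (!is.data.frame(table)) stop_validation("table must be a data.frame")
  ok <- tryCatch({
    utils::write.csv(format(table, digits = 15, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write '", path, "': ", conditionMessage(ok))
  invisible(path)
}

# ---------------------------------------------------------------------------
# CPI series
# ---------------------------------------------------------------------------

#' Consumer price index series
#'
#' Used to re-express unit values observed in different evaluation base
#' years at a common price level (default base year 2013, the price level
#' of the wetland resource survey the case database is anchored to).
#'
#' @param index_by_year named numeric vector, names are calendar years,
#'   values are positive index levels (any consistent base).
#' @param base_year the year whose price level all values are adjusted to.
#' @return An object of class `cpi_series`.
#' @export
cpi_series <- function(index_by_year, base_year = 2013L) {
  base_year <- as.integer(base_year)
  if (is.null(names(index_by_year)) || any(!nzchar(names(index_by_year))))
    stop_validation("index_by_year must be named by calendar year")
  idx <- as.numeric(index_by_year)
  if (any(!is.finite(idx) | idx <= 0))
    stop_validation("all CPI indices must be positive and finite")
  names(idx) <- as.character(as.integer(names(index_by_year)))
  if (!as.character(base_year) %in% names(idx))
    stop_validation("base_year ", base_year, " has no index in the series")
  structure(list(base_year = base_year, index_by_year = idx),
            class = "cpi_series")
}

#' Read a CPI series from CSV
#'
#' Expects columns `year` and `index`.
#'
#' @param path CSV file path.
#' @param base_year base year for price adjustment.
#' @return A [cpi_series()].
#' @export
read_cpi <- function(path, base_year = 2013L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("year", "index") %in% names(df)))
    stop_validation("CPI file must have columns 'year' and 'index'")
  cpi_series(stats::setNames(df$index, df$year), base_year = base_year)
}

#' Write a CPI series to CSV
#' @param cpi a [cpi_series()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cpi <- function(cpi, path) {
  write_results(data.frame(year = as.integer(names(cpi$index_by_year)),
                           index = unname(cpi$index_by_year)), path)
}

# ---------------------------------------------------------------------------
# Wetland inventory
# ---------------------------------------------------------------------------

#' Validate a target wetland inventory
#'
#' The inventory lists the wetland units a fitted model transfers values to:
#' `unit_id`, `wetland_type`, `area` (hm^2) and the covariate columns named
#' by the schema. Areas must be positive and every wetland type must be a
#' row of the supply matrix in use.
#'
#' @param inv data.frame of wetland units.
#' @param schema a [case_schema()] naming the covariate columns.
#' @param sm optional [supply_matrix()] to check wetland types against.
#' @return `inv`, invisibly.
#' @export
validate_inventory <- function(inv, schema = case_schema(), sm = NULL) {
  if (!is.data.frame(inv)) stop_validation("inventory must be a data.frame")
  need <- c("unit_id", "wetland_type", "area", schema$natural, schema$environment)
  missing_cols <- setdiff(need, names(inv))
  if (length(missing_cols))
    stop_validation("inventory missing column(s): ", paste(missing_cols, collapse = ", "))
  bad <- which(!is.finite(inv$area) | inv$area <= 0)
  if (length(bad))
    stop_validation("inventory area must be > 0; offending row(s): ",
                    paste(bad, collapse = ", "))
  if (anyDuplicated(inv$unit_id))
    stop_validation("inventory unit_id values must be unique")
  if (!is.null(sm)) {
    unknown <- setdiff(unique(inv$wetland_type), rownames(sm$n))
    if (length(unknown))
      stop_validation("wetland type(s) absent from supply matrix: ",
                      paste(unknown, collapse = ", "))
  }
  invisible(inv)
}

#' Read a wetland inventory from CSV or GeoJSON
#'
#' For GeoJSON input only feature attributes (`properties`) are used;
#' geometry is ignored. No GIS processing is performed.
#'
#' @inheritParams validate_inventory
#' @param path `.csv`, `.json` or `.geojson` file.
#' @return data.frame of wetland units.
#' @export
read_inventory <- function(path, schema = case_schema(), sm = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("json", "geojson")) {
    gj <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (is.null(gj$features))
      stop_validation("GeoJSON inventory must be a FeatureCollection")
    rows <- lapply(gj$features, function(f) as.data.frame(f$properties,
                                                          stringsAsFactors = FALSE))
    inv <- do.call(rbind, rows)
  } else {
    inv <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  validate_inventory(inv, schema = schema, sm = sm)
  inv
}
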