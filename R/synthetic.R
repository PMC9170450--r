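# Synthetic study generator: emulates a coastal-wetland valuation-case
# database (62 cases / 349 observations by default) with known ground truth,
# plus the supply matrix, CPI series, AHP hierarchy and target inventory the
# pipeline consumes.

.default_wetland_types <- c("river", "pond_pit", "salt_pan", "culture_zone",
                            "sandy_beach", "muddy_tidal_flat")
.default_services <- c("material_production", "flood_regulation",
                       "carbon_sequestration", "atmospheric_regulation",
                       "climate_regulation", "wave_shore_protection",
                       "land_promotion", "leisure_tourism")
.default_methods <- c("direct_market", "shadow_project",
                      "equivalence_factor", "travel_cost")
.provinces <- c("Liaoning", "Hebei", "Shandong", "Jiangsu", "Shanghai",
                "Zhejiang", "Fujian", "Guangdong", "Guangxi", "Hainan")

.take_codes <- function(pool, n, prefix) {
  if (n <= length(pool)) pool[seq_len(n)]
  else c(pool, paste0(prefix, seq(length(pool) + 1, n)))
}

#' Configuration of the synthetic study generator
#'
#' Defaults emulate the calibration database the coupling model is designed
#' for: 62 wetland cases carrying 349 service-value observations across 6
#' wetland types, 8 final services and 4 evaluation methods, with evaluation
#' base years 1995-2013 adjusted to 2013 prices. Areas and socio-economic
#' indices are log-normal, shape indices normal; ln-scale observation noise
#' has sd `sigma_log` (default 0.3). The method-effect truth spans a
#' ln-contrast of 1.35 (about a 3.9-fold value ratio between the extreme
#' evaluation methods).
#'
#' @param n_cases number of wetland cases (default 62).
#' @param n_observations total value observations (default 349; must be >=
#'   `n_cases`, every case receives at least one).
#' @param n_wetland_types,n_services,n_methods taxonomy sizes (6/8/4).
#' @param beta_truth named original-scale coefficient vector; `NULL` uses the
#'   documented default matching the design columns.
#' @param sigma_log ln-scale noise sd (default 0.3).
#' @param outlier_fraction fraction of observations planted as outliers
#'   (default 0); `outlier_shift` is their ln-scale shift in units of
#'   `sigma_log` (default 10).
#' @param seed RNG seed (default 20130101).
#' @param year_range evaluation base-year span (default 1995-2013; the last
#'   year is the CPI base).
#' @param cpi_drift_rate,cpi_drift_jitter mean annual CPI growth and its
#'   year-to-year sd (default 2.5% and 1%).
#' @param area_meanlog,area_sdlog ln-normal wetland area parameters (hm^2;
#'   default meanlog log(500), sdlog 1).
#' @param shape_mean,shape_sd normal shape-index parameters (default 2, 0.5).
#' @param env_meanlog,env_sdlog ln-normal environment-index parameters
#'   (default 0, 0.5) for the GDP and population-density indices.
#' @param ahp_tau ln-scale jitter of the AHP judgment matrices (default 0.05).
#' @param n_units size of the target wetland inventory (default 20).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_cases = 62L, n_observations = 349L,
                             n_wetland_types = 6L, n_services = 8L,
                             n_methods = 4L, beta_truth = NULL,
                             sigma_log = 0.3, outlier_fraction = 0,
                             outlier_shift = 10, seed = 20130101L,
                             year_range = c(1995L, 2013L),
                             cpi_drift_rate = 0.025, cpi_drift_jitter = 0.01,
                             area_meanlog = log(500), area_sdlog = 1,
                             shape_mean = 2, shape_sd = 0.5,
                             env_meanlog = 0, env_sdlog = 0.5,
                             ahp_tau = 0.05, n_units = 20L) {
  if (n_observations < n_cases)
    stop_validation("n_observations (", n_observations,
                    ") must be >= n_cases (", n_cases, ")")
  if (min(n_cases, n_wetland_types, n_services, n_methods, n_units) < 1)
    stop_validation("all counts must be >= 1")
  if (sigma_log < 0) stop_validation("sigma_log must be >= 0")
  if (outlier_fraction < 0 || outlier_fraction > 0.5)
    stop_validation("outlier_fraction must be in [0, 0.5]")
  cfg <- as.list(environment())
  cfg$wetland_types <- .take_codes(.default_wetland_types, n_wetland_types, "wt")
  cfg$services <- .take_codes(.default_services, n_services, "svc")
  cfg$methods <- .take_codes(.default_methods, n_methods, "method")
  cfg$schema <- case_schema(
    natural = c("nat_logarea", "nat_shape"),
    environment = c("env_gdp_index", "env_pop_density"))
  if (is.null(cfg$beta_truth)) cfg$beta_truth <- .default_beta_truth(cfg)
  structure(cfg, class = "generator_config")
}

# Original-scale truth, named exactly as build_design's columns.
.default_beta_truth <- function(cfg) {
  svc <- sort(cfg$services)
  mth <- sort(cfg$methods)
  b <- c("(Intercept)" = 6.0,
         nat_logarea = 0.30, nat_shape = -0.15,
         xd_x_env_gdp_index = 2e-5, xd_x_env_pop_density = -1e-5)
  if (length(svc) > 1) {
    bs <- rep_len(c(0.40, -0.30, 0.20, 0.60, -0.50, 0.10, 0.30), length(svc) - 1)
    names(bs) <- paste0("service_", svc[-1])
    b <- c(b, bs)
  }
  if (length(mth) > 1) {
    bm <- rep_len(c(0.45, -0.35, 1.00), length(mth) - 1)
    names(bm) <- paste0("method_", mth[-1])
    b <- c(b, bm)
  }
  b
}

# ln unit value at base-year prices under the coupling model truth
.forward_lnvalue <- function(cases, sm, schema, beta) {
  unit_tab <- data.frame(unit_id = cases$case_id,
                         wetland_type = cases$wetland_type, area = cases$area)
  xd <- unname(supply_score(unit_tab, sm))
  lp <- rep(beta[["(Intercept)"]], nrow(cases))
  for (nm in schema$natural) lp <- lp + beta[[nm]] * cases[[nm]]
  for (nm in schema$environment)
    lp <- lp + beta[[paste0("xd_x_", nm)]] * xd * cases[[nm]]
  svc_cols <- paste0("service_", cases$service)
  mth_cols <- paste0("method_", cases$method)
  lp + ifelse(svc_cols %in% names(beta), beta[svc_cols], 0) +
    ifelse(mth_cols %in% names(beta), beta[mth_cols], 0)
}

.generate_cpi <- function(cfg) {
  years <- seq(cfg$year_range[1], cfg$year_range[2])
  g <- cfg$cpi_drift_rate + stats::rnorm(length(years) - 1, 0, cfg$cpi_drift_jitter)
  idx <- cumprod(c(1, pmax(1 + g, 0.5)))
  idx <- idx / idx[length(idx)] * 100  # base year (last) = 100
  cpi_series(stats::setNames(idx, years), base_year = cfg$year_range[2])
}

.generate_supply <- function(cfg) {
  for (try in 1:20) {
    raw <- matrix(stats::rlnorm(cfg$n_wetland_types * cfg$n_services, 1, 0.5),
                  cfg$n_wetland_types, cfg$n_services,
                  dimnames = list(cfg$wetland_types, cfg$services))
    sm <- tryCatch(normalize_capacities(raw, axis = "per_service"),
                   error = function(e) NULL)
    if (!is.null(sm)) return(sm)
  }
  stop_numeric("could not draw a supply matrix without empty rows/columns")
}

# consistent-plus-jitter judgment matrix around known weights
.jitter_pairwise <- function(w, items, tau) {
  n <- length(w)
  a <- outer(w, w, "/")
  eps <- matrix(0, n, n)
  eps[upper.tri(eps)] <- stats::rnorm(n * (n - 1) / 2, 0, tau)
  a <- a * exp(eps - t(eps))
  diag(a) <- 1
  pairwise_matrix(a, items = items)
}

.generate_hierarchy <- function(cfg) {
  levels <- c("local", "provincial", "national", "global")
  lw <- c(0.35, 0.30, 0.20, 0.15)
  if (cfg$n_services < 2) {
    # a single service needs no pairwise comparison; its weight is 1
    return(list(hierarchy = NULL, level_weights = stats::setNames(lw, levels),
                composite_true = stats::setNames(1, cfg$services)))
  }
  sw <- lapply(levels, function(lv) {
    w <- stats::rgamma(cfg$n_services, shape = 5, rate = 1)
    w <- pmax(w, max(w) / 8)  # keep judgment ratios inside the Saaty scale
    stats::setNames(w / sum(w), sort(cfg$services))
  })
  names(sw) <- levels
  h <- ahp_hierarchy(
    level_matrix = .jitter_pairwise(lw, levels, cfg$ahp_tau),
    service_matrices = lapply(sw, function(w)
      .jitter_pairwise(unname(w), names(w), cfg$ahp_tau)))
  true_comp <- Reduce(`+`, Map(function(l, w) l * w, lw, sw))
  list(hierarchy = h, level_weights = stats::setNames(lw, levels),
       composite_true = true_comp / sum(true_comp))
}

.draw_units <- function(cfg, ids) {
  n <- length(ids)
  area <- stats::rlnorm(n, cfg$area_meanlog, cfg$area_sdlog)
  data.frame(unit_id = ids,
             wetland_type = sample(cfg$wetland_types, n, replace = TRUE),
             area = area,
             nat_logarea = log(area),
             nat_shape = stats::rnorm(n, cfg$shape_mean, cfg$shape_sd),
             env_gdp_index = stats::rlnorm(n, cfg$env_meanlog, cfg$env_sdlog),
             env_pop_density = stats::rlnorm(n, cfg$env_meanlog, cfg$env_sdlog),
             province = sample(.provinces, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# sample of length n guaranteed to contain every element of pool
.sample_covering <- function(pool, n) {
  if (n < length(pool)) return(sample(pool, n))
  sample(c(pool, sample(pool, n - length(pool), replace = TRUE)))
}

#' Generate a complete synthetic study bundle
#'
#' Draws wetlands with types, areas and covariates; builds and normalizes a
#' supply matrix; simulates a CPI series with multiplicative drift; builds a
#' consistent-plus-jitter AHP hierarchy around known composite weights;
#' allocates observations to cases (at least one each); computes each
#' observed unit value from the coupling-model forward equation with
#' `beta_truth` and ln-normal noise; de-adjusts values to their nominal
#' evaluation year through the inverse CPI ratio; and plants outliers if
#' requested. The returned truth record carries everything needed for
#' recovery checks.
#'
#' @param cfg a [generator_config()].
#' @return List of class `wetval_bundle`: `cases`, `schema`, `sm`, `cpi`,
#'   `hierarchy`, `inventory`, `truth`, `config`.
#' @export
generate_bundle <- function(cfg = generator_config()) {
  if (!inherits(cfg, "generator_config"))
    stop_validation("cfg must be a generator_config")
  set.seed(cfg$seed)

  sm <- .generate_supply(cfg)
  cpi <- .generate_cpi(cfg)
  ahp <- .generate_hierarchy(cfg)

  wetlands <- .draw_units(cfg, sprintf("case%03d", seq_len(cfg$n_cases)))
  extra <- as.integer(stats::rmultinom(1, cfg$n_observations - cfg$n_cases,
                                       rep(1, cfg$n_cases)))
  n_per_case <- 1L + extra
  row_case <- rep(seq_len(cfg$n_cases), n_per_case)

  n <- cfg$n_observations
  cases <- wetlands[row_case, , drop = FALSE]
  rownames(cases) <- NULL
  names(cases)[names(cases) == "unit_id"] <- "case_id"
  cases$obs_id <- sprintf("obs%04d", seq_len(n))
  cases$wetland_id <- sub("^case", "w", cases$case_id)
  cases$service <- .sample_covering(cfg$services, n)
  cases$method <- .sample_covering(cfg$methods, n)
  cases$base_year <- sample(seq(cfg$year_range[1], cfg$year_range[2]), n,
                            replace = TRUE)

  ln_v <- .forward_lnvalue(cases, sm, cfg$schema, cfg$beta_truth)
  if (cfg$sigma_log > 0) ln_v <- ln_v + stats::rnorm(n, 0, cfg$sigma_log)
  n_out <- round(cfg$outlier_fraction * n)
  outlier_ids <- character(0)
  if (n_out > 0) {
    pick <- sample(n, n_out)
    ln_v[pick] <- ln_v[pick] + cfg$outlier_shift * cfg$sigma_log
    outlier_ids <- cases$obs_id[pick]
  }
  # de-adjust from base-year prices to each observation's nominal year
  idx <- cpi$index_by_year
  cases$value_raw <- exp(ln_v) * unname(idx[as.character(cases$base_year)]) /
    idx[[as.character(cpi$base_year)]]

  front <- c("obs_id", "case_id", "wetland_id", "wetland_type", "service",
             "method", "base_year", "value_raw", "area")
  cases <- cases[, c(front, setdiff(names(cases), front))]
  validate_cases(cases, schema = cfg$schema, cpi = cpi)

  inventory <- .draw_units(cfg, sprintf("unit%03d", seq_len(cfg$n_units)))
  validate_inventory(inventory, schema = cfg$schema, sm = sm)

  structure(list(
    cases = cases, schema = cfg$schema, sm = sm, cpi = cpi,
    hierarchy = ahp$hierarchy, inventory = inventory,
    truth = list(beta_truth = cfg$beta_truth,
                 sigma_log = cfg$sigma_log,
                 composite_weights = ahp$composite_true,
                 level_weights = ahp$level_weights,
                 outlier_ids = outlier_ids,
                 seed = cfg$seed),
    config = cfg
  ), class = "wetval_bundle")
}

#' Tiny deterministic worked example
#'
#' A hand-checkable bundle: 3 wetland types x 2 services, 4 cases, 12
#' noise-free observations, a 4-year CPI series and a 2-unit target
#' inventory. The supply scores are easy to verify by hand:
#' `river` row (3, 5), `salt_pan` (2, 8), `muddy_flat` (6, 1), so the four
#' case wetlands with areas 2, 5, 10 and 20 hm^2 have total scores
#' X_d = 16, 50, 70 and 160. Values follow the coupling forward model
#' exactly (sigma_log = 0), so a fit reproduces the truth to rounding.
#'
#' @return A `wetval_bundle` (no `hierarchy`; weights come from
#'   [reference_service_weights()] or a user hierarchy).
#' @export
worked_example <- function() {
  sm <- supply_matrix(matrix(
    c(3L, 5L,
      2L, 8L,
      6L, 1L), nrow = 3, byrow = TRUE,
    dimnames = list(c("river", "salt_pan", "muddy_flat"),
                    c("material_production", "leisure_tourism"))))
  cpi <- cpi_series(c("2010" = 90, "2011" = 93, "2012" = 96, "2013" = 100),
                    base_year = 2013)
  schema <- case_schema(natural = "nat_shape", environment = "env_idx")
  beta <- c("(Intercept)" = 6, nat_shape = 0.25, xd_x_env_idx = 0.004,
            service_material_production = 0.5, method_shadow_project = 0.8)

  wet <- data.frame(
    case_id = paste0("case", 1:4),
    wetland_id = paste0("w", 1:4),
    wetland_type = c("river", "salt_pan", "muddy_flat", "river"),
    area = c(2, 5, 10, 20),
    nat_shape = c(1.2, 1.8, 2.4, 3.0),
    env_idx = c(1.0, 0.8, 1.2, 0.6),
    stringsAsFactors = FALSE)

  obs <- expand.grid(k = 1:3, i = 1:4)
  cases <- wet[obs$i, , drop = FALSE]
  rownames(cases) <- NULL
  cases$obs_id <- sprintf("obs%02d", seq_len(nrow(cases)))
  cases$service <- c("material_production", "leisure_tourism",
                     "leisure_tourism")[obs$k]
  cases$method <- c("direct_market", "direct_market", "shadow_project")[obs$k]
  cases$base_year <- c(2013L, 2011L, 2010L)[obs$k]

  # reference categories are the alphabetically first levels
  # (leisure_tourism, direct_market)
  ln_v <- .forward_lnvalue(cases, sm, schema, beta)
  idx <- cpi$index_by_year
  cases$value_raw <- exp(ln_v) * unname(idx[as.character(cases$base_year)]) / 100

  inventory <- data.frame(
    unit_id = c("unitA", "unitB"),
    wetland_type = c("river", "muddy_flat"),
    area = c(3, 6),
    nat_shape = c(2.0, 1.5),
    env_idx = c(1.0, 0.9),
    stringsAsFactors = FALSE)

  structure(list(cases = cases, schema = schema, sm = sm, cpi = cpi,
                 hierarchy = NULL, inventory = inventory,
                 truth = list(beta_truth = beta, sigma_log = 0,
                              composite_weights = NULL,
                              outlier_ids = character(0), seed = NA),
                 config = NULL),
            class = "wetval_bundle")
}

#' Write a study bundle to a directory of plain-text files
#'
#' Emits `cases.csv`, `supply_matrix.csv`, `cpi.csv`, `inventory.csv`,
#' `ahp.json` (the hierarchy's judgment matrices, if any), `schema.json`
#' and `truth.json`.
#'
#' @param bundle a `wetval_bundle`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$cases, file.path(dir, "cases.csv"), row.names = FALSE)
  write_supply_matrix(bundle$sm, file.path(dir, "supply_matrix.csv"))
  write_cpi(bundle$cpi, file.path(dir, "cpi.csv"))
  utils::write.csv(bundle$inventory, file.path(dir, "inventory.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(natural = bundle$schema$natural,
                            environment = bundle$schema$environment),
                       file.path(dir, "schema.json"), auto_unbox = FALSE)
  if (!is.null(bundle$hierarchy)) {
    h <- bundle$hierarchy
    jsonlite::write_json(list(
      levels = h$levels, services = h$services,
      level_matrix = h$level_matrix$a,
      service_matrices = lapply(h$service_matrices, function(m) m$a)),
      file.path(dir, "ahp.json"), digits = NA, auto_unbox = FALSE)
  }
  jsonlite::write_json(lapply(bundle$truth, function(x)
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an AHP hierarchy from the JSON layout written by [write_bundle()]
#' @param path JSON path.
#' @return An [ahp_hierarchy()].
#' @export
read_hierarchy <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  levels <- as.character(j$levels)
  services <- as.character(j$services)
  ahp_hierarchy(
    level_matrix = pairwise_matrix(j$level_matrix, items = levels),
    service_matrices = lapply(j$service_matrices, function(a)
      pairwise_matrix(a, items = services)))
}
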