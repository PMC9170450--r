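# The dimension-space-attribute coupling meta-regression:
#   ln V = b0 + bw.Xw + bc.(Xd * Xc) + bm.Xm + U
# with V the CPI-adjusted unit value (yuan/(hm^2*yr)), Xw the natural
# covariates, Xc the environmental covariates interacting with the supply
# score Xd, and Xm the one-hot service/method indicators.

#' Adjust a monetary value to base-year prices
#'
#' Rescales a value observed at `year` prices to the CPI series' base-year
#' price level: `value * index(base_year) / index(year)`.
#'
#' @param value numeric value(s) in yuan.
#' @param year calendar year(s) the value is expressed in.
#' @param cpi a [cpi_series()].
#' @return Value(s) at base-year prices.
#' @export
cpi_adjust <- function(value, year, cpi) {
  if (!inherits(cpi, "cpi_series")) stop_validation("cpi must be a cpi_series")
  yr <- as.character(as.integer(year))
  missing_years <- setdiff(unique(yr), names(cpi$index_by_year))
  if (length(missing_years))
    stop_validation("year(s) absent from CPI series: ",
                    paste(missing_years, collapse = ", "))
  value * cpi$index_by_year[[as.character(cpi$base_year)]] /
    unname(cpi$index_by_year[yr])
}

#' Build the coupling-model design from a case database
#'
#' Constructs the dependent variable `ln(V)` (V CPI-adjusted to the series'
#' base year) and the regressor blocks: the natural covariates `Xw`, the
#' interactions `Xd * Xc` between the case wetland's total supply score and
#' each environmental covariate, and one-hot indicators for service and
#' evaluation method (one reference category dropped per group, so the
#' intercept stays identifiable). Continuous columns are z-scored by default
#' for numerical conditioning; the centring constants are stored so that
#' predictions and original-scale coefficients are exact.
#'
#' @param cases validated case data.frame (see [read_cases()]).
#' @param sm a [supply_matrix()] covering every case wetland type.
#' @param cpi a [cpi_series()] covering every base year.
#' @param schema a [case_schema()] naming the covariate columns.
#' @param standardize z-score the continuous columns (default `TRUE`).
#' @return An object of class `coupling_design`: list with `y`, model matrix
#'   `X` (including intercept), `obs_id`, `column_spec`, `scaling`.
#' @export
build_design <- function(cases, sm, cpi, schema, standardize = TRUE) {
  cases <- validate_cases(cases, schema = schema, cpi = cpi)
  v_base <- cpi_adjust(cases$value_raw, cases$base_year, cpi)
  y <- log(v_base)

  # total supply score of each case's wetland over all services
  unit_tab <- data.frame(unit_id = cases$case_id,
                         wetland_type = cases$wetland_type,
                         area = cases$area)
  xd <- unname(supply_score(unit_tab, sm))

  xw <- as.matrix(cases[, schema$natural, drop = FALSE])
  xc_raw <- as.matrix(cases[, schema$environment, drop = FALSE])
  xint <- xc_raw * xd
  if (ncol(xint)) colnames(xint) <- paste0("xd_x_", schema$environment)

  svc_levels <- sort(unique(as.character(cases$service)))
  mth_levels <- sort(unique(as.character(cases$method)))
  xm <- cbind(.one_hot(cases$service, svc_levels, "service"),
              .one_hot(cases$method, mth_levels, "method"))

  cont <- cbind(xw, xint)
  center <- rep(0, ncol(cont))
  scale <- rep(1, ncol(cont))
  names(center) <- names(scale) <- colnames(cont)
  if (standardize && ncol(cont)) {
    center <- colMeans(cont)
    scale <- apply(cont, 2, stats::sd)
    degenerate <- colnames(cont)[!is.finite(scale) | scale == 0]
    if (length(degenerate))
      stop_numeric("zero-variance continuous column(s), cannot standardize: ",
                   paste(degenerate, collapse = ", "))
    cont <- sweep(sweep(cont, 2, center, "-"), 2, scale, "/")
  }

  X <- cbind("(Intercept)" = 1, cont, xm)
  column_spec <- list(
    natural = schema$natural,
    environment = schema$environment,
    interaction = colnames(xint),
    continuous = colnames(cont),
    service_levels = svc_levels, service_ref = svc_levels[1],
    method_levels = mth_levels, method_ref = mth_levels[1],
    columns = colnames(X)
  )
  structure(list(y = y, X = X, obs_id = as.character(cases$case_id),
                 row_id = if (!is.null(cases$obs_id)) as.character(cases$obs_id)
                          else sprintf("row%d", seq_len(nrow(cases))),
                 column_spec = column_spec,
                 scaling = list(center = center, scale = scale),
                 standardize = standardize,
                 n_removed = 0L),
            class = "coupling_design")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one-hot indicators with the first (alphabetical) level as reference
.one_hot <- function(x, levels, prefix) {
  x <- as.character(x)
  keep <- levels[-1]
  if (!length(keep)) {
    m <- matrix(numeric(0), nrow = length(x), ncol = 0)
    return(m)
  }
  m <- vapply(keep, function(l) as.numeric(x == l), numeric(length(x)))
  m <- matrix(m, nrow = length(x),
              dimnames = list(NULL, paste0(prefix, "_", keep)))
  m
}

.design_subset <- function(design, keep) {
  design$y <- design$y[keep]
  design$X <- design$X[keep, , drop = FALSE]
  design$obs_id <- design$obs_id[keep]
  design$row_id <- design$row_id[keep]
  design
}

#' Fit the coupling model by ordinary least squares
#'
#' Solves the log-linear model by QR decomposition and stores, alongside the
#' standardized-scale estimates, the coefficients and covariance mapped back
#' to the original covariate scale (an exact linear transform of the fit).
#' Duan's smearing factor `mean(exp(residuals))` is recorded for
#' retransforming log-scale predictions to the value scale; the naive
#' `exp` and the normal-theory `exp(sigma^2/2)` corrections are selectable.
#'
#' @param design a `coupling_design` from [build_design()].
#' @param retransform retransformation mode for predictions: `"smearing"`
#'   (default), `"naive"`, or `"normal"`.
#' @return An object of class `coupling_model`.
#' @export
fit_coupling <- function(design, retransform = c("smearing", "naive", "normal")) {
  retransform <- match.arg(retransform)
  X <- design$X
  y <- design$y
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p)
    stop_numeric("need more observations than columns (n = ", n, ", p = ", p,
                 "): no residual degrees of freedom")
  qx <- qr(X)
  if (qx$rank < p) {
    collinear <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stop_numeric("design is rank deficient; collinear column(s): ",
                 paste(collinear, collapse = ", "))
  }
  beta <- qr.coef(qx, y)
  fitted <- as.numeric(X %*% beta)
  resid <- y - fitted
  rss <- sum(resid^2)
  sigma2 <- rss / (n - p)
  # unscaled covariance (X'X)^-1, undoing the QR pivot
  R <- qr.R(qx)
  Vp <- chol2inv(R)
  V <- matrix(NA_real_, p, p, dimnames = list(colnames(X), colnames(X)))
  V[qx$pivot, qx$pivot] <- Vp
  vcov_std <- sigma2 * V
  hat <- rowSums(qr.Q(qx)^2)

  tr <- .orig_scale_transform(design$column_spec, design$scaling)
  beta_orig <- as.numeric(tr %*% beta)
  names(beta_orig) <- names(beta)
  vcov_orig <- tr %*% vcov_std %*% t(tr)

  smearing <- mean(exp(resid))
  structure(list(
    coefficients = beta,
    coefficients_original = beta_orig,
    vcov = vcov_std, vcov_original = vcov_orig,
    se = sqrt(diag(vcov_std)), se_original = sqrt(diag(vcov_orig)),
    sigma2 = sigma2, df_residual = n - p,
    smearing = smearing, retransform = retransform,
    n_used = n, n_removed = design$n_removed,
    column_spec = design$column_spec, scaling = design$scaling,
    standardize = design$standardize,
    residuals = resid, fitted = fitted, hat = hat,
    obs_id = design$obs_id, row_id = design$row_id
  ), class = "coupling_model")
}

# Linear map from standardized-scale to original-scale coefficients:
# slope_k -> slope_k / s_k, intercept -> b0 - sum_k b_k m_k / s_k.
.orig_scale_transform <- function(column_spec, scaling) {
  cols <- column_spec$columns
  p <- length(cols)
  tr <- diag(p)
  dimnames(tr) <- list(cols, cols)
  for (k in column_spec$continuous) {
    tr[k, k] <- 1 / scaling$scale[[k]]
    tr["(Intercept)", k] <- -scaling$center[[k]] / scaling$scale[[k]]
  }
  tr
}

#' @export
print.coupling_model <- function(x, ...) {
  cat("Coupling model (log-linear value-transfer regression)\n")
  cat(sprintf("  n used = %d (removed %d), residual df = %d\n",
              x$n_used, x$n_removed, x$df_residual))
  cat(sprintf("  residual sd (ln scale) = %.4f, smearing factor = %.4f\n",
              sqrt(x$sigma2), x$smearing))
  tab <- data.frame(estimate = x$coefficients_original,
                    se = x$se_original)
  print(round(tab, 6))
  invisible(x)
}

#' Retransformation factor of a fitted model
#' @param model a `coupling_model`.
#' @param mode override the model's stored retransformation mode.
#' @return Multiplicative factor applied to `exp(linear predictor)`.
#' @export
retransform_factor <- function(model, mode = model$retransform) {
  switch(mode,
         smearing = model$smearing,
         naive = 1,
         normal = exp(model$sigma2 / 2),
         stop_validation("unknown retransformation mode: ", mode))
}

#' Remove outlying observations by the standardized-residual rule
#'
#' Fits the model once, computes internally studentized residuals
#' `r_i = e_i / (s * sqrt(1 - h_ii))`, removes every row with
#' `|r_i| > threshold` (default 2.5), and refits on the remainder. By
#' default this is a single fit-filter-refit pass; `iterate = TRUE` repeats
#' until no row exceeds the threshold.
#'
#' @param design a `coupling_design`.
#' @param threshold standardized-residual cut-off (default 2.5).
#' @param iterate repeat the pass until stable (default `FALSE`).
#' @return List with the reduced `design`, the refitted `model`, `removed`
#'   (row ids of eliminated observations) and `r` (the studentized residuals
#'   of the first pass).
#' @export
remove_outliers <- function(design, threshold = 2.5, iterate = FALSE) {
  if (!is.finite(threshold) && threshold > 0) {
    model <- fit_coupling(design)
    r1 <- model$residuals / sqrt(model$sigma2 * (1 - model$hat))
    return(list(design = design, model = model,
                removed = character(0), r = r1))
  }
  if (threshold <= 0) stop_validation("threshold must be > 0")
  removed <- character(0)
  r1 <- NULL
  repeat {
    model <- fit_coupling(design)
    # a numerically perfect fit has no outliers; do not studentize rounding
    # noise (residual sd below 1e-10 of the response scale)
    if (sqrt(model$sigma2) < 1e-10 * max(1, max(abs(design$y)))) {
      if (is.null(r1)) r1 <- stats::setNames(rep(0, nrow(design$X)), design$row_id)
      break
    }
    r <- model$residuals / sqrt(model$sigma2 * (1 - model$hat))
    if (is.null(r1)) r1 <- stats::setNames(r, design$row_id)
    drop <- which(abs(r) > threshold)
    if (!length(drop)) break
    removed <- c(removed, design$row_id[drop])
    if (length(drop) == nrow(design$X))
      stop_numeric("outlier removal would eliminate every observation")
    design <- .design_subset(design, -drop)
    design$n_removed <- design$n_removed + length(drop)
    model <- fit_coupling(design)
    if (!iterate) break
  }
  list(design = design, model = model, removed = removed, r = r1)
}

#' Leave-one-out cross-validation of the coupling model
#'
#' Uses the exact hat-matrix identity for OLS leave-one-out residuals,
#' `e_(i) = e_i / (1 - h_ii)` — algebraically equal to refitting the model n
#' times without each observation. Reports the RMSE of the log-scale LOO
#' prediction errors and the mean absolute transfer error on the value
#' scale (percent, naive retransformation).
#'
#' @param design a `coupling_design` with `n > p + 1`.
#' @return An object of class `cv_report`: `loo_rmse_log`, `loo_mape`, and a
#'   per-observation data.frame `per_case`.
#' @export
loo_cv <- function(design) {
  if (nrow(design$X) <= ncol(design$X) + 1)
    stop_numeric("LOO CV needs n > p + 1")
  model <- fit_coupling(design)
  e_loo <- model$residuals / (1 - model$hat)
  yhat_loo <- design$y - e_loo
  v <- exp(design$y)
  vhat <- exp(yhat_loo)
  per_case <- data.frame(row_id = design$row_id,
                         obs_id = design$obs_id,
                         resid_loo_log = e_loo,
                         pred_value = vhat,
                         obs_value = v)
  structure(list(loo_rmse_log = sqrt(mean(e_loo^2)),
                 loo_mape = mean(abs(vhat - v) / v) * 100,
                 per_case = per_case),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Leave-one-out CV: RMSE (ln scale) = %.4f, MAPE (value scale) = %.1f%%\n",
              x$loo_rmse_log, x$loo_mape))
  invisible(x)
}

#' Transfer per-hectare service values to a wetland inventory
#'
#' For each inventory unit and requested service, evaluates
#' `value = f * exp(b0 + bw.xw + bc.(Xd * xc) + bm.xm)` with the same
#' covariate standardization as training and `f` the model's
#' retransformation factor. `Xd` is the unit's total supply score.
#'
#' @param model a `coupling_model`.
#' @param inv wetland inventory data.frame (see [validate_inventory()]).
#' @param sm the [supply_matrix()] used at training.
#' @param services service codes to predict (default: all seen in training).
#' @param method_code the evaluation-method indicator the predictions are
#'   expressed under (default: the training reference category).
#' @return data.frame (`unit_id`, `service`, `value` yuan/(hm^2 * yr)).
#' @export
predict_value <- function(model, inv, sm, services = NULL,
                          method_code = model$column_spec$method_ref) {
  cs <- model$column_spec
  if (is.null(services)) services <- cs$service_levels
  unseen <- setdiff(services, cs$service_levels)
  if (length(unseen))
    stop_validation("service(s) not seen at training: ", paste(unseen, collapse = ", "))
  if (!method_code %in% cs$method_levels)
    stop_validation("method '", method_code, "' not seen at training")
  schema <- case_schema(natural = cs$natural, environment = cs$environment)
  validate_inventory(inv, schema = schema, sm = sm)

  xd <- unname(supply_score(inv, sm))
  xw <- as.matrix(inv[, cs$natural, drop = FALSE])
  xint <- as.matrix(inv[, cs$environment, drop = FALSE]) * xd
  if (ncol(xint)) colnames(xint) <- paste0("xd_x_", cs$environment)
  cont <- cbind(xw, xint)
  if (length(cs$continuous))
    cont <- sweep(sweep(cont[, cs$continuous, drop = FALSE], 2,
                        model$scaling$center[cs$continuous], "-"),
                  2, model$scaling$scale[cs$continuous], "/")

  f <- retransform_factor(model)
  out <- vector("list", length(services))
  for (k in seq_along(services)) {
    svc <- services[k]
    xm_svc <- .one_hot(rep(svc, nrow(inv)), cs$service_levels, "service")
    xm_mth <- .one_hot(rep(method_code, nrow(inv)), cs$method_levels, "method")
    Xnew <- cbind("(Intercept)" = 1, cont, xm_svc, xm_mth)
    Xnew <- Xnew[, cs$columns, drop = FALSE]  # named-column contract
    lp <- as.numeric(Xnew %*% model$coefficients[cs$columns])
    out[[k]] <- data.frame(unit_id = inv$unit_id, service = svc,
                           value = f * exp(lp))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate transferred values into per-service and grand totals
#'
#' Per-service total = `sum_units value * area` (yuan/yr); the grand total
#' sums the services. When a service-weight vector is supplied, the weighted
#' composite index `sum_s w_s * total_s` is also reported.
#'
#' @param pred prediction table from [predict_value()].
#' @param inv the wetland inventory providing areas.
#' @param weights optional `weight_vector` over the predicted services.
#' @return List with `per_service` (data.frame service/total_yuan_yr),
#'   `total` (yuan/yr), and `composite` (NA unless weights given).
#' @export
aggregate_total <- function(pred, inv, weights = NULL) {
  missing_units <- setdiff(unique(pred$unit_id), inv$unit_id)
  if (length(missing_units))
    stop_validation("predicted unit(s) absent from inventory: ",
                    paste(missing_units, collapse = ", "))
  area <- stats::setNames(inv$area, inv$unit_id)[as.character(pred$unit_id)]
  contrib <- pred$value * unname(area)
  per_service <- stats::aggregate(contrib, by = list(service = pred$service), FUN = sum)
  names(per_service)[2] <- "total_yuan_yr"
  total <- sum(per_service$total_yuan_yr)
  composite <- NA_real_
  if (!is.null(weights)) {
    w <- weights$weights
    missing_w <- setdiff(per_service$service, names(w))
    if (length(missing_w))
      stop_validation("no weight for service(s): ", paste(missing_w, collapse = ", "))
    composite <- sum(w[per_service$service] * per_service$total_yuan_yr)
  }
  list(per_service = per_service, total = total, composite = composite)
}

#' Serialize a fitted coupling model to JSON
#' @param model a `coupling_model`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  keep <- list(
    coefficients = as.list(model$coefficients),
    coefficients_original = as.list(model$coefficients_original),
    se = as.list(model$se), se_original = as.list(model$se_original),
    sigma2 = model$sigma2, df_residual = model$df_residual,
    smearing = model$smearing, retransform = model$retransform,
    n_used = model$n_used, n_removed = model$n_removed,
    column_spec = model$column_spec,
    scaling = lapply(model$scaling, as.list),
    standardize = model$standardize
  )
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a fitted coupling model from JSON
#' @param path JSON path written by [write_model()].
#' @return A `coupling_model` (without training residuals).
#' @export
read_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$coefficients <- unlist(m$coefficients)
  m$coefficients_original <- unlist(m$coefficients_original)
  m$se <- unlist(m$se)
  m$se_original <- unlist(m$se_original)
  m$scaling <- lapply(m$scaling, unlist)
  for (nm in c("natural", "environment", "interaction", "continuous",
               "service_levels", "method_levels", "columns"))
    m$column_spec[[nm]] <- as.character(unlist(m$column_spec[[nm]]))
  structure(m, class = "coupling_model")
}
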