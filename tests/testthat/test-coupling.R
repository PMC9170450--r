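test_that("CPI adjustment follows the index ratio and inverts exactly", {
  cpi <- tiny_cpi()
  expect_equal(cpi_adjust(500, 2013, cpi), 500)              # identity at base
  expect_equal(cpi_adjust(100, 2011, cpi), 100 * 100 / 90)   # hand ratio
  # homogeneity: halving the year's index doubles the adjusted value
  cpi2 <- cpi_series(c("2011" = 45, "2012" = 95, "2013" = 100), 2013)
  expect_equal(cpi_adjust(100, 2011, cpi2), 2 * cpi_adjust(100, 2011, cpi))
  # de-adjusting with the inverse ratio restores the original value
  v <- cpi_adjust(321, 2012, cpi)
  expect_equal(v * cpi$index_by_year[["2012"]] / cpi$index_by_year[["2013"]],
               321, tolerance = 1e-12)
  expect_error(cpi_adjust(1, 1999, cpi), "1999",
               class = "wetval_validation_error")
})

test_that("the design holds ln value, Xd-environment interactions and dummies", {
  cases <- tiny_cases()
  d <- build_design(cases, tiny_supply(), tiny_cpi(), tiny_schema(),
                    standardize = FALSE)
  # hand check row 1: river, area 2 -> Xd = 16; env_z = 0.5 -> interaction 8
  expect_equal(unname(d$X[1, "xd_x_env_z"]), 16 * cases$env_z[1])
  expect_equal(d$y, log(cpi_adjust(cases$value_raw, cases$base_year, tiny_cpi())))
  # one reference level dropped per dummy group
  expect_true(all(c("service_svcB", "method_m2") %in% colnames(d$X)))
  expect_false(any(c("service_svcA", "method_m1") %in% colnames(d$X)))
  expect_true(all(d$X[, "service_svcB"] %in% c(0, 1)))

  # single case: interaction is the plain product Xd * xc
  one <- tiny_cases(1)
  one$area <- 1; one$env_z <- 2          # river row (3,5): Xd = 8
  d1 <- build_design(one, tiny_supply(), tiny_cpi(), tiny_schema(),
                     standardize = FALSE)
  expect_equal(unname(d1$X[1, "xd_x_env_z"]), 16)
})

test_that("standardization stores centring constants and rejects constants", {
  cases <- tiny_cases()
  d <- build_design(cases, tiny_supply(), tiny_cpi(), tiny_schema())
  expect_equal(unname(colMeans(d$X[, d$column_spec$continuous])), c(0, 0),
               tolerance = 1e-12)
  expect_equal(unname(apply(d$X[, d$column_spec$continuous], 2, sd)), c(1, 1),
               tolerance = 1e-12)
  cases$nat_x <- 1
  expect_error(build_design(cases, tiny_supply(), tiny_cpi(), tiny_schema()),
               "nat_x", class = "wetval_numeric_error")
})

test_that("OLS fit matches lm() and recovers a noise-free truth exactly", {
  b <- generate_bundle(generator_config(n_cases = 20, n_observations = 120,
                                        seed = 31))
  d <- build_design(b$cases, b$sm, b$cpi, b$schema)
  m <- fit_coupling(d)
  ref <- stats::lm(d$y ~ d$X - 1)
  expect_equal(unname(m$coefficients), unname(coef(ref)), tolerance = 1e-10)
  expect_equal(m$sigma2, summary(ref)$sigma^2, tolerance = 1e-10)
  expect_equal(unname(m$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-8)

  b0 <- generate_bundle(generator_config(n_cases = 20, n_observations = 120,
                                         seed = 32, sigma_log = 0))
  d0 <- build_design(b0$cases, b0$sm, b0$cpi, b0$schema)
  m0 <- fit_coupling(d0)
  truth <- b0$truth$beta_truth[names(m0$coefficients_original)]
  expect_lt(max(abs(m0$coefficients_original - truth)), 1e-8)
  expect_equal(m0$smearing, 1, tolerance = 1e-10)
})

test_that("rank-deficient and saturated designs fail with named columns", {
  b <- generate_bundle(generator_config(n_cases = 10, n_observations = 40,
                                        seed = 8))
  d <- build_design(b$cases, b$sm, b$cpi, b$schema)
  d$X <- cbind(d$X, dup_col = d$X[, "nat_shape"])
  d$column_spec$columns <- colnames(d$X)
  expect_error(fit_coupling(d), "dup_col|nat_shape",
               class = "wetval_numeric_error")

  d2 <- build_design(b$cases, b$sm, b$cpi, b$schema)
  keep <- seq_len(ncol(d2$X))
  d2 <- wetval:::.design_subset(d2, keep)   # n == p
  expect_error(fit_coupling(d2), "degrees of freedom",
               class = "wetval_numeric_error")
})

test_that("outlier removal follows the 2.5-sigma studentized-residual rule", {
  # clean noise-free data: nothing to remove
  b <- generate_bundle(generator_config(n_cases = 20, n_observations = 120,
                                        seed = 13, sigma_log = 0))
  d <- build_design(b$cases, b$sm, b$cpi, b$schema)
  expect_length(remove_outliers(d)$removed, 0)

  # a single planted 10-sigma observation in 200 rows is removed
  b2 <- generate_bundle(generator_config(n_cases = 30, n_observations = 200,
                                         seed = 14, sigma_log = 0.3))
  planted <- 57L
  b2$cases$value_raw[planted] <- b2$cases$value_raw[planted] * exp(10 * 0.3)
  d2 <- build_design(b2$cases, b2$sm, b2$cpi, b2$schema)
  res <- remove_outliers(d2)
  expect_true(b2$cases$obs_id[planted] %in% res$removed)

  # threshold = Inf is the identity
  res_inf <- remove_outliers(d2, threshold = Inf)
  expect_length(res_inf$removed, 0)
  expect_equal(nrow(res_inf$design$X), nrow(d2$X))

  # never removes more rows than exceed the threshold under the first fit
  expect_lte(length(res$removed), sum(abs(res$r) > 2.5))
})

test_that("hat-matrix LOO residuals equal literal refitting", {
  b <- generate_bundle(generator_config(n_cases = 10, n_observations = 30,
                                        n_services = 1, n_methods = 1,
                                        seed = 77))
  d <- build_design(b$cases, b$sm, b$cpi, b$schema)
  expect_equal(dim(d$X), c(30L, 5L))
  cv <- loo_cv(d)
  brute <- vapply(seq_len(nrow(d$X)), function(i) {
    f <- stats::lm.fit(d$X[-i, , drop = FALSE], d$y[-i])
    d$y[i] - sum(d$X[i, ] * f$coefficients)
  }, numeric(1))
  expect_equal(cv$per_case$resid_loo_log, brute, tolerance = 1e-8)

  # noise-free data cross-validates to zero error
  b0 <- generate_bundle(generator_config(n_cases = 10, n_observations = 60,
                                         seed = 78, sigma_log = 0))
  d0 <- build_design(b0$cases, b0$sm, b0$cpi, b0$schema)
  cv0 <- loo_cv(d0)
  expect_lt(cv0$loo_rmse_log, 1e-8)
  expect_lt(cv0$loo_mape, 1e-6)
})

test_that("value transfer matches hand linear algebra and the column contract", {
  b <- worked_example()
  d <- build_design(b$cases, b$sm, b$cpi, b$schema)
  m <- fit_coupling(d)
  pred <- predict_value(m, b$inventory, b$sm)

  # hand computation on unitA (river, 3 hm2 -> Xd = 24), truth scale
  beta <- b$truth$beta_truth
  lp <- beta[["(Intercept)"]] + beta[["nat_shape"]] * 2.0 +
    beta[["xd_x_env_idx"]] * 24 * 1.0
  v_leisure <- exp(lp)                                 # reference service
  v_material <- exp(lp + beta[["service_material_production"]])
  got <- pred[pred$unit_id == "unitA", ]
  expect_equal(got$value[got$service == "leisure_tourism"], unname(v_leisure),
               tolerance = 1e-8)
  expect_equal(got$value[got$service == "material_production"],
               unname(v_material), tolerance = 1e-8)

  # shuffling inventory column order must not change predictions
  inv_shuffled <- b$inventory[, rev(names(b$inventory))]
  expect_equal(predict_value(m, inv_shuffled, b$sm)$value, pred$value,
               tolerance = 1e-12)
  expect_error(predict_value(m, b$inventory, b$sm, services = "ghost"),
               "ghost", class = "wetval_validation_error")
  expect_error(predict_value(m, b$inventory, b$sm, method_code = "hedonic"),
               "hedonic", class = "wetval_validation_error")
})

test_that("a null model with unit smearing transfers a value of one", {
  b <- worked_example()
  d <- build_design(b$cases, b$sm, b$cpi, b$schema)
  m <- fit_coupling(d)
  m$coefficients[] <- 0
  m$smearing <- 1
  pred <- predict_value(m, b$inventory, b$sm)
  expect_equal(pred$value, rep(1, nrow(pred)), tolerance = 1e-12)
})

test_that("predictions are invariant under affine rescaling of a covariate", {
  b <- generate_bundle(generator_config(n_cases = 15, n_observations = 90,
                                        seed = 55))
  d <- build_design(b$cases, b$sm, b$cpi, b$schema)
  m <- fit_coupling(d)
  pred <- predict_value(m, b$inventory, b$sm)

  resc <- b
  resc$cases$nat_shape <- 3 * b$cases$nat_shape - 5
  resc$inventory$nat_shape <- 3 * b$inventory$nat_shape - 5
  m2 <- fit_coupling(build_design(resc$cases, resc$sm, resc$cpi, resc$schema))
  pred2 <- predict_value(m2, resc$inventory, resc$sm)
  expect_equal(pred2$value, pred$value, tolerance = 1e-8)
})

test_that("aggregation multiplies by area and applies service weights", {
  pred <- data.frame(unit_id = "u1", service = "sA", value = 5)
  inv <- data.frame(unit_id = "u1", wetland_type = "river", area = 2)
  tot <- aggregate_total(pred, inv)
  expect_equal(tot$total, 10)

  pred2 <- data.frame(unit_id = c("u1", "u1", "u2"),
                      service = c("sA", "sB", "sA"),
                      value = c(5, 1, 2))
  inv2 <- data.frame(unit_id = c("u1", "u2"), wetland_type = "river",
                     area = c(2, 3))
  tot2 <- aggregate_total(pred2, inv2)
  expect_equal(tot2$per_service$total_yuan_yr[tot2$per_service$service == "sA"],
               5 * 2 + 2 * 3)
  expect_equal(tot2$total, 10 + 2 + 6)
  inv2_double <- inv2; inv2_double$area <- inv2$area * 2
  expect_equal(aggregate_total(pred2, inv2_double)$total, 2 * tot2$total)

  # equal per-service totals T with the reference weights: composite = T * sum(w)
  ref <- reference_service_weights()
  svc <- names(ref$weights)
  predw <- data.frame(unit_id = "u1", service = svc, value = 7)
  invw <- data.frame(unit_id = "u1", wetland_type = "river", area = 1)
  totw <- aggregate_total(predw, invw, weights = ref)
  expect_equal(totw$composite, 7 * sum(ref$weights), tolerance = 1e-12)

  expect_error(aggregate_total(pred, data.frame(unit_id = "uX", area = 1)),
               "u1", class = "wetval_validation_error")
})

test_that("fitted models round-trip through JSON and keep predicting", {
  b <- generate_bundle(generator_config(n_cases = 12, n_observations = 70,
                                        seed = 61))
  d <- build_design(b$cases, b$sm, b$cpi, b$schema)
  m <- fit_coupling(d)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(m2$coefficients, m$coefficients, tolerance = 1e-12)
  expect_equal(m2$smearing, m$smearing, tolerance = 1e-12)
  expect_equal(predict_value(m2, b$inventory, b$sm)$value,
               predict_value(m, b$inventory, b$sm)$value, tolerance = 1e-12)
})

test_that("retransformation modes order as naive <= smearing for noisy fits", {
  b <- generate_bundle(generator_config(n_cases = 20, n_observations = 150,
                                        seed = 91))
  d <- build_design(b$cases, b$sm, b$cpi, b$schema)
  m <- fit_coupling(d)
  expect_equal(retransform_factor(m, "naive"), 1)
  expect_gt(retransform_factor(m, "smearing"), 1)  # Jensen: mean(exp(e)) > 1
  expect_gt(retransform_factor(m, "normal"), 1)
})
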