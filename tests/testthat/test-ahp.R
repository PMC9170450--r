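test_that("the all-ones matrix yields uniform weights with zero inconsistency", {
  w <- eigen_weights(matrix(1, 3, 3))
  expect_equal(unname(w$weights), rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(w$cr, 0, tolerance = 1e-9)
})

test_that("consistent matrices built from known weights are recovered exactly", {
  wt <- c(0.5, 0.3, 0.2)
  m <- pairwise_matrix(outer(wt, wt, "/"), items = c("a", "b", "c"))
  w <- eigen_weights(m)
  expect_equal(unname(w$weights), wt, tolerance = 1e-9)
  expect_equal(w$cr, 0, tolerance = 1e-9)
  expect_equal(w$lambda_max, 3, tolerance = 1e-9)
})

test_that("a perturbed judgment raises CR, matching a dense eigensolve", {
  wt <- c(0.5, 0.3, 0.2)
  a <- outer(wt, wt, "/")
  a[1, 2] <- a[1, 2] * 3
  a[2, 1] <- 1 / a[1, 2]
  w <- eigen_weights(pairwise_matrix(a, items = c("a", "b", "c")))
  expect_gt(w$cr, 0)
  oracle <- eigen_oracle(a)
  expect_equal(unname(w$weights), oracle$weights, tolerance = 1e-9)
  expect_equal(w$lambda_max, oracle$lambda_max, tolerance = 1e-9)
})

test_that("power iteration matches the eigensolve oracle on random reciprocal matrices", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(3:8, 1)
    a <- diag(n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      a[i, j] <- exp(stats::rnorm(1, 0, 0.6))
      a[j, i] <- 1 / a[i, j]
    }
    w <- eigen_weights(pairwise_matrix(a))
    oracle <- eigen_oracle(a)
    expect_equal(unname(w$weights), oracle$weights, tolerance = 1e-8)
    # permutation equivariance
    perm <- sample(n)
    wp <- eigen_weights(pairwise_matrix(a[perm, perm]))
    expect_equal(unname(wp$weights), unname(w$weights)[perm], tolerance = 1e-8)
  }
})

test_that("pairwise-matrix invariants are enforced", {
  a <- matrix(c(1, 2, 0.6, 1), 2, 2)  # 0.6 != 1/2
  expect_error(pairwise_matrix(a), "reciprocal",
               class = "wetval_validation_error")
  expect_error(pairwise_matrix(matrix(1, 1, 1)), "n >= 2",
               class = "wetval_validation_error")
  expect_error(pairwise_matrix(matrix(c(1, -2, -0.5, 1), 2, 2)), "positive",
               class = "wetval_validation_error")
})

test_that("composite weights are convex combinations of per-level weights", {
  # degenerate hierarchy: two equal levels with opposite single-service weights
  lvl <- pairwise_matrix(matrix(1, 2, 2), items = c("L1", "L2"))
  s1 <- pairwise_matrix(matrix(c(1, 1 / 9, 9, 1), 2, 2),
                        items = c("sA", "sB"))  # sA dominant
  s2 <- pairwise_matrix(matrix(c(1, 9, 1 / 9, 1), 2, 2))  # sB dominant
  s2$items <- c("sA", "sB")
  dimnames(s2$a) <- list(s2$items, s2$items)
  h <- ahp_hierarchy(lvl, list(L1 = s1, L2 = s2))
  comp <- composite_weights(h)
  expect_equal(unname(comp$weights), c(0.5, 0.5), tolerance = 1e-9)

  # construct-and-recover over a 4-level synthetic hierarchy
  set.seed(7)
  services <- paste0("s", 1:5)
  lw <- c(0.4, 0.3, 0.2, 0.1)
  sw <- lapply(1:4, function(i) {
    w <- stats::rgamma(5, 5, 1); w <- pmax(w, max(w) / 8); w / sum(w)
  })
  h <- ahp_hierarchy(
    pairwise_matrix(outer(lw, lw, "/"), items = paste0("L", 1:4)),
    stats::setNames(lapply(sw, function(w)
      pairwise_matrix(outer(w, w, "/"), items = services)), paste0("L", 1:4)))
  comp <- composite_weights(h)
  truth <- Reduce(`+`, Map(`*`, lw, sw))
  expect_equal(unname(comp$weights), truth / sum(truth), tolerance = 1e-9)
  expect_equal(sum(comp$weights), 1, tolerance = 1e-12)
  # each composite weight lies within the per-level range for that service
  rng <- apply(do.call(rbind, sw), 2, range)
  expect_true(all(comp$weights >= rng[1, ] - 1e-12 &
                  comp$weights <= rng[2, ] + 1e-12))
})

test_that("inconsistent matrices are rejected by name, overridably", {
  lvl <- pairwise_matrix(matrix(1, 2, 2), items = c("L1", "L2"))
  a <- matrix(c(1, 9, 4, 1 / 9, 1, 8, 1 / 4, 1 / 8, 1), 3, 3,
              byrow = TRUE)  # wildly intransitive
  bad <- pairwise_matrix(a, items = paste0("s", 1:3))
  ok <- pairwise_matrix(matrix(1, 3, 3), items = paste0("s", 1:3))
  h <- ahp_hierarchy(lvl, list(L1 = bad, L2 = ok))
  expect_error(composite_weights(h), "L1", class = "wetval_validation_error")
  comp <- composite_weights(h, enforce_cr = FALSE)
  expect_equal(sum(comp$weights), 1, tolerance = 1e-12)
})

test_that("the packaged reference weights match their published values", {
  w <- reference_service_weights()$weights
  expect_identical(unname(w[c("food_production", "carbon_sequestration")]),
                   c(0.1344, 0.0481))
  expect_identical(unname(w["wave_revetment"]), 0.1296)
  raw_sum <- sum(w)
  expect_gte(raw_sum, 0.995)
  expect_lte(raw_sum, 1.005)
  expect_equal(sum(reference_service_weights(renormalize = TRUE)$weights), 1,
               tolerance = 1e-12)
})

test_that("geometric-mean aggregation preserves reciprocality and consistency", {
  wt <- c(0.6, 0.25, 0.15)
  m1 <- pairwise_matrix(outer(wt, wt, "/"), items = letters[1:3])
  set.seed(1)
  e <- matrix(0, 3, 3); e[upper.tri(e)] <- stats::rnorm(3, 0, 0.2)
  m2 <- pairwise_matrix(outer(wt, wt, "/") * exp(e - t(e)), items = letters[1:3])
  g <- aggregate_judgments(list(m1, m2))
  expect_s3_class(g, "pairwise_matrix")
  expect_equal(max(abs(g$a * t(g$a) - 1)), 0, tolerance = 1e-12)
})

test_that("pairwise matrices round-trip through CSV", {
  wt <- c(0.5, 0.3, 0.2)
  m <- pairwise_matrix(outer(wt, wt, "/"), items = c("a", "b", "c"))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(item = m$items, m$a, check.names = FALSE),
                   path, row.names = FALSE)
  back <- read_pairwise_csv(path)
  expect_equal(back$a, m$a, tolerance = 1e-12)
  expect_identical(back$items, m$items)
})
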