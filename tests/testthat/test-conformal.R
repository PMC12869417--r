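# Conformal calibration: interval scaling, risk, Hoeffding bound, lambda search.

test_that("interval scaling is linear in lambda with identity at 1", {
  b <- quantile_bounds(matrix(10), matrix(0.2), matrix(0.3)) # l=8, u=13
  iv1 <- interval_at_lambda(matrix(10), b, 1)
  expect_equal(iv1$lower_b, matrix(8))
  expect_equal(iv1$upper_b, matrix(13))
  iv0 <- interval_at_lambda(matrix(10), b, 0)
  expect_equal(iv0$lower_b, matrix(10))
  expect_equal(iv0$upper_b, matrix(10))
  iv2 <- interval_at_lambda(matrix(10), b, 2)
  expect_equal(iv2$lower_b, matrix(6))
  expect_equal(iv2$upper_b, matrix(16))
  expect_error(interval_at_lambda(matrix(10), b, -0.5),
               class = "mriuq_argument_error")
})

test_that("miscoverage risk counts pixels strictly outside closed intervals", {
  x <- matrix(c(1, 2, 3, 4), 2)
  b <- quantile_bounds(x, x * 0 + 0.1, x * 0 + 0.1)
  iv <- interval_at_lambda(x, b, 1)
  expect_equal(miscoverage_risk(iv, x), 0)

  iv0 <- interval_at_lambda(x, b, 0)
  expect_equal(miscoverage_risk(iv0, x + 1), 1)

  y <- x
  y[1, 1] <- 100
  expect_equal(miscoverage_risk(iv, y), 0.25)
  # boundary value counts as covered (closed interval)
  yb <- interval_at_lambda(x, b, 1)$upper_b
  expect_equal(miscoverage_risk(interval_at_lambda(x, b, 1), yb), 0)
  expect_error(miscoverage_risk(iv, y[1, , drop = FALSE]),
               class = "mriuq_shape_error")
})

test_that("Hoeffding bound adds sqrt(log(1/delta)/(2I)) slack", {
  expect_equal(hoeffding_upper_bound(c(0.2, 0.4), 1), 0.3)
  expect_equal(hoeffding_upper_bound(rep(0.05, 100), exp(-2)),
               0.05 + sqrt(2 / 200))
  b10 <- hoeffding_upper_bound(rep(0.1, 10), 0.05)
  b100 <- hoeffding_upper_bound(rep(0.1, 100), 0.05)
  expect_gt(b10, b100)
  expect_error(hoeffding_upper_bound(numeric(0), 0.1),
               class = "mriuq_data_error")
  expect_error(hoeffding_upper_bound(c(0.5, 1.2), 0.1),
               class = "mriuq_argument_error")
})

test_that("calibrate_lambda equals the exhaustive-scan oracle on toy sets", {
  grid <- seq(0, 4, by = 0.05)
  for (s in 1:4) {
    items <- toy_cal_items(4, npix_side = if (s %% 2) 1L else 4L, seed = s)
    for (agg in c("per_image", "pooled")) {
      want <- oracle_calibrate(items, alpha = 0.25, delta = 1, grid, agg)
      got <- calibrate_lambda(items, 0.25, 1, grid, aggregate = agg)
      expect_equal(got$per_lambda_risk, want$risks, tolerance = 1e-12)
      expect_equal(got$per_lambda_bound, want$bounds, tolerance = 1e-12)
      expect_identical(got$chosen_lambda, want$chosen)
    }
  }
})

test_that("wide bounds with zero risk select the grid minimum", {
  x <- matrix(c(1, 2), 1)
  items <- list(list(pair = recon_pair(x, x),
                     bounds = quantile_bounds(x, x * 0 + 0.9, x * 0 + 0.9)))
  rec <- calibrate_lambda(items, 0.5, 1, lambda_grid = seq(0.5, 2, by = 0.5))
  expect_identical(rec$chosen_lambda, 0.5)
  expect_false(rec$infeasible)
})

test_that("shrinking delta never decreases the chosen lambda", {
  items <- toy_cal_items(8, npix_side = 4L, seed = 11)
  grid <- seq(0, 6, by = 0.02)
  lams <- vapply(c(1, 0.5, 0.2), function(d) {
    calibrate_lambda(items, 0.3, d, grid, aggregate = "pooled")$chosen_lambda
  }, numeric(1))
  expect_true(all(diff(lams) >= 0))
})

test_that("risk is nonincreasing in lambda for every image", {
  grid <- seq(0, 5, by = 0.1)
  for (s in 1:5) {
    it <- toy_cal_items(1, npix_side = 4L, seed = 100 + s)[[1]]
    risks <- vapply(grid, function(lam) {
      miscoverage_risk(interval_at_lambda(it$pair$x, it$bounds, lam), it$pair$y)
    }, numeric(1))
    expect_true(all(diff(risks) <= 0))
  }
})

test_that("binary search and linear scan agree on all grids", {
  for (s in 1:5) {
    items <- toy_cal_items(5, npix_side = 3L, seed = 200 + s)
    grid <- sort(unique(c(0, runif(37, 0, 5), 5)))
    a <- calibrate_lambda(items, 0.3, 0.9, grid, aggregate = "pooled",
                          method = "scan")
    b <- calibrate_lambda(items, 0.3, 0.9, grid, aggregate = "pooled",
                          method = "bisect")
    expect_identical(a$chosen_lambda, b$chosen_lambda)
    expect_identical(a$per_lambda_bound, b$per_lambda_bound)
  }
})

test_that("infeasible calibration is flagged, not silent", {
  # per-image Hoeffding slack with I = 2, delta = 0.01 exceeds alpha = 0.1:
  # sqrt(log(100)/4) ~ 1.07, so no lambda can satisfy the bound
  items <- toy_cal_items(2, npix_side = 2L, seed = 3)
  expect_warning(
    rec <- calibrate_lambda(items, 0.1, 0.01, seq(0, 4, 0.5),
                            aggregate = "per_image"),
    "infeasible"
  )
  expect_true(rec$infeasible)
  expect_true(is.na(rec$chosen_lambda))
  expect_error(calibrate_lambda(items, 0.1, 0.1, c(1, 0.5)),
               class = "mriuq_argument_error")
})

test_that("calibration records serialize to JSON", {
  items <- toy_cal_items(3, npix_side = 2L, seed = 5)
  rec <- calibrate_lambda(items, 0.3, 1, seq(0, 4, 0.5), aggregate = "pooled")
  f <- withr::local_tempfile(fileext = ".json")
  write_calibration_record(rec, f)
  j <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(j$chosen_lambda, rec$chosen_lambda)
  expect_equal(j$per_lambda_risk, rec$per_lambda_risk)
  expect_identical(j$n_calibration, 3L)
})
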