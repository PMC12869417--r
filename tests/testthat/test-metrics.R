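# Uncertainty/error maps, blurring, correlations, regions, coverage, thresholds.

test_that("uncertainty and error maps follow their definitions", {
  b <- quantile_bounds(matrix(10), matrix(0.2), matrix(0.3))
  iv <- interval_at_lambda(matrix(10), b, 2) # bounds (6, 16)
  q <- uncertainty_map(iv)
  expect_equal(q$q_tilde, matrix(10))

  q0 <- uncertainty_map(interval_at_lambda(matrix(10), b, 0))
  expect_equal(q0$q_tilde, matrix(0))

  # width scales linearly in lambda at fixed raw bounds
  w <- vapply(c(0.5, 1, 2, 3), function(l) {
    uncertainty_map(interval_at_lambda(matrix(10), b, l))$q_tilde[1, 1]
  }, numeric(1))
  expect_equal(w, c(0.5, 1, 2, 3) * 5)

  e <- error_map(matrix(3), matrix(5))
  expect_equal(e$e_tilde, matrix(2))
  expect_equal(error_map(matrix(5), matrix(3))$e_tilde, matrix(2))
  expect_equal(error_map(matrix(1:4, 2), matrix(1:4, 2))$e_tilde,
               matrix(0, 2, 2))
  expect_error(error_map(matrix(1), matrix(1:2, 1)),
               class = "mriuq_shape_error")
})

test_that("gaussian blur is identity at sigma 0, DC- and mass-preserving", {
  withr::with_seed(3, m <- matrix(runif(32 * 32), 32))
  expect_identical(gaussian_blur(m, 0), m)
  cm <- matrix(2.5, 16, 16)
  expect_equal(gaussian_blur(cm, 2), cm, tolerance = 1e-12)
  expect_lt(abs(mean(gaussian_blur(m, 2)) - mean(m)), 1e-6)
  expect_error(gaussian_blur(m, -1), class = "mriuq_argument_error")
})

test_that("pearson and spearman match brute-force oracles incl. ties", {
  a <- matrix(c(1, 2, 3, 4), 2)
  b <- matrix(c(1, 2, 3, 5), 2)
  expect_equal(pearson(a, a), 1)
  expect_equal(pearson(a, -a), -1)
  expect_equal(pearson(a, b), oracle_pearson(a, b), tolerance = 1e-12)

  expect_equal(spearman(a, exp(a)), 1)
  expect_equal(spearman(a, matrix(rev(sort(a)), 2)), -1)
  tie6 <- matrix(c(1, 2, 2, 3, 4, 4), 2)
  other <- matrix(c(2, 1, 5, 3, 3, 6), 2)
  expect_equal(spearman(tie6, other), oracle_spearman(tie6, other),
               tolerance = 1e-12)
  # Eq. identity: spearman(a, b) = pearson(rank(a), rank(b))
  expect_equal(spearman(tie6, other),
               pearson(matrix(rank(tie6), 2), matrix(rank(other), 2)),
               tolerance = 1e-12)

  # exhaustive small fixtures, with and without ties
  for (s in 1:10) {
    withr::with_seed(s, {
      n <- sample(4:16, 1)
      u <- matrix(sample(1:5, n, replace = TRUE) + runif(n) * (s %% 2), 1)
      v <- matrix(sample(1:5, n, replace = TRUE) + runif(n) * (s %% 2), 1)
    })
    if (sd(u) == 0 || sd(v) == 0) next
    expect_equal(pearson(u, v), oracle_pearson(u, v), tolerance = 1e-12)
    expect_equal(spearman(u, v), oracle_spearman(u, v), tolerance = 1e-12)
  }

  expect_error(pearson(matrix(1, 2, 2), a[, 1, drop = FALSE]),
               class = "mriuq_shape_error")
  expect_error(pearson(matrix(1, 2, 2), matrix(1:4, 2)),
               class = "mriuq_degenerate_error")
  expect_error(spearman(matrix(1, 2, 2), matrix(1:4, 2)),
               class = "mriuq_degenerate_error")
})

test_that("region partition tiles the image with near-equal blocks", {
  p <- region_partition(320, 320, 100)
  expect_length(p, 100)
  expect_true(all(vapply(p, function(b) length(b$rows) == 32 &&
                           length(b$cols) == 32, logical(1))))

  p2 <- region_partition(321, 321, 100)
  sides <- unlist(lapply(p2, function(b) c(length(b$rows), length(b$cols))))
  expect_true(all(sides %in% c(32, 33)))
  covered <- matrix(0L, 321, 321)
  for (b in p2) covered[b$rows, b$cols] <- covered[b$rows, b$cols] + 1L
  expect_true(all(covered == 1L))

  expect_length(region_partition(64, 64, 16), 16)
  expect_error(region_partition(5, 5, 100), class = "mriuq_argument_error")
})

test_that("region correlations average per-block values and skip constants", {
  withr::with_seed(4, q <- matrix(runif(64 * 64), 64))
  expect_equal(as.numeric(region_correlations(q, q, 16)), 1)
  expect_equal(as.numeric(region_correlations(q, -q + 3, 16, "pearson")), -1)

  # 4-region toy case against a per-block oracle
  withr::with_seed(5, {
    qm <- matrix(runif(36), 6)
    em <- qm + matrix(rnorm(36, 0, 0.5), 6)
  })
  blocks <- region_partition(6, 6, 4)
  want <- mean(vapply(blocks, function(b) {
    oracle_pearson(qm[b$rows, b$cols], em[b$rows, b$cols])
  }, numeric(1)))
  expect_equal(as.numeric(region_correlations(qm, em, 4)), want,
               tolerance = 1e-12)

  # constant blocks are skipped and counted
  qc <- qm; qc[1:3, 1:3] <- 1
  rc <- region_correlations(qc, em, 4)
  expect_identical(attr(rc, "n_skipped"), 1L)
  expect_error(region_correlations(matrix(1, 4, 4), matrix(1, 4, 4), 4),
               class = "mriuq_degenerate_error")
})

test_that("coverage is the complement of miscoverage", {
  x <- matrix(c(1, 2, 3, 4), 2)
  b <- quantile_bounds(x, x * 0 + 0.1, x * 0 + 0.1)
  iv <- interval_at_lambda(x, b, 1)
  expect_equal(coverage(iv, x), 1)
  y <- x; y[2, 2] <- 50
  expect_equal(coverage(iv, y), 0.75)
  expect_equal(coverage(iv, y) + miscoverage_risk(iv, y), 1)
})

test_that("normalized uncertainty summaries are percentages of the maximum", {
  x <- matrix(c(1, 2, 3, 4), 2)
  b <- quantile_bounds(x, x * 0, x * 0)
  q0 <- uncertainty_map(interval_at_lambda(x, b, 1))
  s0 <- normalized_uncertainty_summary(q0)
  expect_equal(s0$mean_pct, 0)

  qc <- structure(list(q_tilde = matrix(4, 2, 2), norm_scale = 4),
                  class = "uncertainty_map")
  sc <- normalized_uncertainty_summary(qc)
  expect_equal(sc$mean_pct, 100)
  expect_equal(sc$sd_pct, 0)

  q2 <- qc; q2$q_tilde <- qc$q_tilde / 2
  expect_equal(normalized_uncertainty_summary(q2)$mean_pct, 50)
  qb <- qc; qb$norm_scale <- 0
  expect_error(normalized_uncertainty_summary(qb),
               class = "mriuq_argument_error")
})

test_that("threshold maps zero values at or below the reference", {
  q <- matrix(c(0, 1, 2, 3), 2)
  expect_equal(threshold_map(q, 0), q)
  expect_equal(threshold_map(q, 3), matrix(0, 2, 2))
  counts <- vapply(c(0, 0.5, 1, 2, 3), function(r) sum(threshold_map(q, r) > 0),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(threshold_map(q, -1), class = "mriuq_argument_error")
})

test_that("correlation reports bundle blurred global and regional metrics", {
  fx <- fx_slice64()
  pairs <- list(fx$pair)
  pred <- analytic_predictor(function(x) 0.2 + 0.5 * x / max(x))
  b <- predict_bounds(pred, fx$pair)
  iv <- interval_at_lambda(fx$pair$x, b, 1.2)
  rep1 <- correlation_report(uncertainty_map(iv), error_map(fx$pair$x, fx$pair$y))
  expect_s3_class(rep1, "correlation_report")
  expect_true(abs(rep1$pearson_r) <= 1 && abs(rep1$spearman_rho) <= 1)
  expect_identical(rep1$blur_sigma, 2)
  expect_output(print(rep1), "Pearson")
})
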