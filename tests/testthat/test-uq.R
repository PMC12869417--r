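# Quantile-offset bounds, pinball / ResM losses, predictor training.

test_that("quantile bounds scale multiplicatively and bracket x", {
  b <- quantile_bounds(matrix(10), matrix(0.2), matrix(0.3))
  expect_equal(b$lower, matrix(8))
  expect_equal(b$upper, matrix(13))

  x <- matrix(c(0, 1, 2, 3), 2)
  b0 <- quantile_bounds(x, x * 0, x * 0)
  expect_equal(b0$lower, x)
  expect_equal(b0$upper, x)

  bz <- quantile_bounds(x, x * 0 + 1, x * 0 + 1)
  expect_equal(bz$lower[1, 1], 0)  # x = 0 pixels stay pinned at 0
  expect_equal(bz$upper[1, 1], 0)
  expect_true(all(bz$lower <= x & x <= bz$upper))

  expect_error(quantile_bounds(x, x * 0 - 0.1, x * 0),
               class = "mriuq_argument_error")
  expect_error(quantile_bounds(x, x[1, , drop = FALSE] * 0, x * 0),
               class = "mriuq_shape_error")
})

test_that("pinball loss evaluates the asymmetric residual penalty", {
  y <- matrix(c(1, 2, 3), 1)
  expect_equal(pinball_loss(y, y, 0.5), 0)
  expect_equal(pinball_loss(matrix(1), matrix(2), 0.95), 0.95)
  expect_equal(pinball_loss(matrix(1), matrix(0), 0.95), 0.05)
  expect_error(pinball_loss(y, y, 1), class = "mriuq_argument_error")
})

test_that("total QR loss sums the two pinball terms at a/2 and 1 - a/2", {
  x <- matrix(5); y <- matrix(5)
  b <- quantile_bounds(x, matrix(0.2), matrix(0.2))
  expect_equal(qr_total_loss(quantile_bounds(y, matrix(0), matrix(0)), y), 0)

  b1 <- quantile_bounds(matrix(5), matrix(1 / 5), matrix(1 / 5)) # l=4, u=6
  expect_equal(qr_total_loss(b1, matrix(5), alpha_coverage = 0.9),
               0.05 * 1 + 0.05 * 1)

  # level symmetry: swapping the roles of (y - l) and (u - y) preserves loss
  withr::with_seed(1, {
    x <- matrix(runif(16, 1, 2), 4)
    sl <- matrix(runif(16, 0, 0.5), 4)
    y <- matrix(runif(16, 0.5, 2.5), 4)
  })
  b2 <- quantile_bounds(x, sl, sl)
  mirrored <- qr_total_loss(quantile_bounds(x, sl, sl), 2 * x - y, 0.9)
  expect_equal(qr_total_loss(b2, y, 0.9), mirrored, tolerance = 1e-12)
})

test_that("ResM loss is squared error against |x - y|, sign-invariant", {
  expect_equal(resm_loss(matrix(1), matrix(1), matrix(0)), 0)
  expect_equal(resm_loss(matrix(2), matrix(1), matrix(0)), 1)
  x <- matrix(runif(9), 3); d <- matrix(runif(9), 3); off <- matrix(runif(9), 3)
  expect_equal(resm_loss(off, x, x + d), resm_loss(off, x, x - d))
  expect_error(resm_loss(matrix(-1), matrix(1), matrix(1)),
               class = "mriuq_argument_error")
})

test_that("constant-predictor pinball minimizer is the empirical quantile", {
  withr::with_seed(7, y <- rexp(501))
  for (tau in c(0.1, 0.5, 0.9)) {
    f <- function(q) pinball_loss(rep(q, length(y)), y, tau)
    qhat <- optimize(f, range(y))$minimum
    s <- sort(y)
    k <- ceiling(tau * length(y))
    gap <- s[min(k + 1, length(y))] - s[max(k - 1, 1)]
    expect_lte(abs(qhat - s[k]), gap + 1e-8)
  }
})

test_that("training recovers a known heteroscedastic noise field", {
  pairs <- fx_hetero_pairs(n = 6)
  sig <- fx_sigma_field()

  pred <- train_uq(pairs, feature_predictor("QR", seed = 1),
                   uq_config(mode = "QR", n_iter = 200, seed = 1))
  b <- predict_bounds(pred, pairs[[1]])
  half_width <- (b$upper - b$lower) / 2
  expect_gt(cor(as.vector(half_width), as.vector(sig)), 0.5)

  predr <- train_uq(pairs, feature_predictor("ResM", seed = 1),
                    uq_config(mode = "ResM", n_iter = 200, seed = 1))
  sr <- predict_offsets(predr, pairs[[1]]$x)
  expect_identical(sr$s_lower, sr$s_upper)
  offset <- sr$s_lower * pairs[[1]]$x
  expect_gt(cor(as.vector(offset), as.vector(sig)), 0.5)
})

test_that("training is seeded-deterministic and validates its inputs", {
  pairs <- fx_hetero_pairs(n = 2)
  run <- function() {
    attr(train_uq(pairs, feature_predictor("QR", seed = 3),
                  uq_config(n_iter = 40, seed = 3)), "history")$train_loss
  }
  expect_identical(run(), run())
  expect_error(train_uq(list(), feature_predictor("QR"), uq_config()),
               class = "mriuq_data_error")
  expect_error(
    train_uq(pairs, feature_predictor("ResM"), uq_config(mode = "QR")),
    class = "mriuq_argument_error")
})

test_that("optimal interval width grows with the target coverage", {
  # constant offsets on fixed data: exact scalar optimization per level
  withr::with_seed(9, {
    x <- matrix(runif(400, 0.5, 1.5), 20)
    y <- x + matrix(rnorm(400, 0, 0.2), 20)
  })
  width_at <- function(cov) {
    a <- 1 - cov
    sl <- optimize(function(s) pinball_loss(x * (1 - s), y, a / 2), c(0, 1))$minimum
    su <- optimize(function(s) pinball_loss(x * (1 + s), y, 1 - a / 2), c(0, 1))$minimum
    mean(x * (sl + su))
  }
  w <- vapply(c(0.8, 0.9, 0.95), width_at, numeric(1))
  expect_true(all(diff(w) > 0))
})

test_that("predictor checkpoints round-trip through JSON", {
  pairs <- fx_hetero_pairs(n = 2)
  p <- train_uq(pairs, feature_predictor("QR", seed = 2),
                uq_config(n_iter = 30, seed = 2))
  f <- withr::local_tempfile(fileext = ".json")
  write_predictor(p, f)
  p2 <- read_predictor(f)
  expect_equal(p2$w_lower, p$w_lower, tolerance = 1e-12)
  expect_equal(p2$w_upper, p$w_upper, tolerance = 1e-12)
  expect_identical(p2$mode, "QR")
  s1 <- predict_offsets(p, pairs[[1]]$x)
  s2 <- predict_offsets(p2, pairs[[1]]$x)
  expect_equal(s1, s2, tolerance = 1e-12)
})
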