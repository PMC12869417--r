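# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (and stats::cor) so each check is a
# genuine dual route.

# Pearson correlation from the covariance definition, double loop free
oracle_pearson <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

# average ranks computed element by element from their definition
oracle_ranks <- function(v) {
  v <- as.vector(v)
  vapply(v, function(x) sum(v < x) + (sum(v == x) + 1) / 2, numeric(1))
}

oracle_spearman <- function(a, b) {
  oracle_pearson(oracle_ranks(a), oracle_ranks(b))
}

# exhaustive lambda-grid scan built from the public primitives only
oracle_calibrate <- function(cal_items, alpha, delta, grid,
                             aggregate = "per_image") {
  risks <- sapply(grid, function(lam) {
    per_img <- vapply(cal_items, function(it) {
      iv <- interval_at_lambda(it$pair$x, it$bounds, lam)
      miscoverage_risk(iv, it$pair$y)
    }, numeric(1))
    if (aggregate == "per_image") {
      mean(per_img)
    } else {
      npix <- vapply(cal_items, function(it) length(it$pair$x), numeric(1))
      sum(per_img * npix) / sum(npix)
    }
  })
  i_eff <- if (aggregate == "per_image") length(cal_items) else
    sum(vapply(cal_items, function(it) length(it$pair$x), numeric(1)))
  bounds <- risks + sqrt(log(1 / delta) / (2 * i_eff))
  ok <- which(bounds <= alpha)
  list(risks = risks, bounds = bounds,
       chosen = if (length(ok)) grid[ok[1]] else NA_real_)
}

# tiny random calibration items: one-pixel to 4x4 "images"
toy_cal_items <- function(n_images, npix_side = 1L, seed = 1L) {
  withr::with_seed(seed, lapply(seq_len(n_images), function(i) {
    x <- matrix(runif(npix_side^2, 0.5, 1.5), npix_side)
    y <- x + matrix(rnorm(npix_side^2, 0, 0.3), npix_side)
    y[y < 0] <- 0
    s_l <- matrix(runif(npix_side^2, 0.05, 0.5), npix_side)
    s_u <- matrix(runif(npix_side^2, 0.05, 0.5), npix_side)
    list(pair = recon_pair(x, y), bounds = quantile_bounds(x, s_l, s_u))
  }))
}
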