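## Seeded end-to-end experiments: the coverage-guarantee study and the
## QR-vs-ResM correlation comparison. Both are thin drivers over the module
## functions, used by tests, the vignette and the acceptance script.

# simulate a split, reconstruct zero-filled at the requested acceleration,
# and return recon pairs per partition plus the mask
simulate_pairs <- function(n_train, n_cal, n_test, params, acceleration,
                           acs_fraction, seed) {
  data <- make_split_dataset(n_train, 0L, n_cal, n_test, params, seed = seed)
  mask <- make_cartesian_mask(params$width, acceleration, acs_fraction)
  to_pairs <- function(items) lapply(items, function(it) {
    recon_pair(zero_filled_rss(it$kspace, mask), it$image$pixels)
  })
  list(train = to_pairs(data$train), cal = to_pairs(data$cal),
       test = to_pairs(data$test), mask = mask)
}

#' Coverage-guarantee experiment
#'
#' Repeats, for `n_rep` independent seeds: simulate phantom slices, apply a
#' Cartesian mask at the given acceleration, reconstruct zero-filled, train a
#' quantile-offset predictor on the training split, conformally calibrate the
#' offset scale on the calibration split, and measure the mean pixelwise
#' coverage of the calibrated intervals on the held-out test split.
#'
#' @param n_rep Number of repetitions.
#' @param seed Master seed; repetition r uses `seed + r - 1` offsets.
#' @param n_train,n_cal,n_test Slices per partition per repetition.
#' @param params Simulation parameters ([sim_params()]).
#' @param acceleration,acs_fraction Undersampling settings.
#' @param alpha_coverage Target coverage (0.90 default).
#' @param delta Hoeffding confidence parameter.
#' @param aggregate Calibration risk aggregation (pooled by default; see
#'   [calibrate_lambda()]).
#' @param mode Predictor mode, `"QR"` or `"ResM"`.
#' @param train_iters,train_lr Offset-predictor training schedule.
#' @return Data frame with one row per repetition: `rep`, `seed`, `lambda`,
#'   `cal_risk` (risk at the chosen scale), `coverage` (held-out mean pixel
#'   coverage), `infeasible`.
#' @export
coverage_experiment <- function(n_rep = 20L, seed = 1L,
                                n_train = 20L, n_cal = 100L, n_test = 100L,
                                params = sim_params(),
                                acceleration = 4,
                                acs_fraction = protocol_acs_fraction("brain", 4),
                                alpha_coverage = 0.9, delta = 0.1,
                                aggregate = "pooled", mode = "QR",
                                train_iters = 600L, train_lr = 0.05) {
  rows <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    s <- seed + (r - 1L) * 1000L
    sim <- simulate_pairs(n_train, n_cal, n_test, params, acceleration,
                          acs_fraction, seed = s)
    pred <- train_uq(
      sim$train, feature_predictor(mode = mode, seed = s),
      uq_config(alpha_coverage = alpha_coverage, mode = mode,
                n_iter = train_iters, lr = train_lr, seed = s)
    )
    cal_items <- lapply(sim$cal, function(p) {
      list(pair = p, bounds = predict_bounds(pred, p))
    })
    record <- calibrate_lambda(cal_items,
                               alpha_miscoverage = 1 - alpha_coverage,
                               delta = delta, aggregate = aggregate)
    if (record$infeasible) {
      rows[[r]] <- data.frame(rep = r, seed = s, lambda = NA_real_,
                              cal_risk = NA_real_, coverage = NA_real_,
                              infeasible = TRUE)
      next
    }
    lam <- record$chosen_lambda
    cov_r <- vapply(sim$test, function(p) {
      iv <- interval_at_lambda(p$x, predict_bounds(pred, p), lam)
      coverage(iv, p$y)
    }, numeric(1))
    i <- match(lam, record$lambda_grid)
    rows[[r]] <- data.frame(rep = r, seed = s, lambda = lam,
                            cal_risk = record$per_lambda_risk[i],
                            coverage = mean(cov_r), infeasible = FALSE)
  }
  do.call(rbind, rows)
}

#' QR-versus-ResM correlation comparison
#'
#' For each repetition, trains both a QR (pinball-loss) and a ResM
#' (residual-magnitude) offset predictor on the same simulated data,
#' calibrates each, and computes the mean blurred Pearson correlation between
#' the calibrated uncertainty map and the true absolute-error map over the
#' test slices.
#'
#' @inheritParams coverage_experiment
#' @param lambda_grid Candidate calibration scales; wider than the
#'   calibration default because symmetric ResM offsets can need larger
#'   scales at small calibration sizes (the correlation itself is invariant
#'   to the scale).
#' @param blur_sigma Gaussian blur applied to both maps before correlating.
#' @return Data frame with one row per repetition: `rep`, `seed`,
#'   `pearson_qr`, `pearson_resm`, `lambda_qr`, `lambda_resm`.
#' @export
qr_vs_resm_experiment <- function(n_rep = 10L, seed = 1L,
                                  n_train = 16L, n_cal = 40L, n_test = 20L,
                                  params = sim_params(),
                                  acceleration = 4,
                                  acs_fraction = protocol_acs_fraction("brain", 4),
                                  alpha_coverage = 0.9, delta = 0.1,
                                  aggregate = "pooled",
                                  lambda_grid = seq(0, 8, by = 0.01),
                                  train_iters = 600L, train_lr = 0.05,
                                  blur_sigma = 2) {
  rows <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    s <- seed + (r - 1L) * 1000L
    sim <- simulate_pairs(n_train, n_cal, n_test, params, acceleration,
                          acs_fraction, seed = s)
    one_mode <- function(mode) {
      pred <- train_uq(
        sim$train, feature_predictor(mode = mode, seed = s),
        uq_config(alpha_coverage = alpha_coverage, mode = mode,
                  n_iter = train_iters, lr = train_lr, seed = s)
      )
      cal_items <- lapply(sim$cal, function(p) {
        list(pair = p, bounds = predict_bounds(pred, p))
      })
      record <- calibrate_lambda(cal_items,
                                 alpha_miscoverage = 1 - alpha_coverage,
                                 delta = delta, lambda_grid = lambda_grid,
                                 aggregate = aggregate)
      lam <- if (record$infeasible) max(record$lambda_grid) else
        record$chosen_lambda
      pr <- vapply(sim$test, function(p) {
        iv <- interval_at_lambda(p$x, predict_bounds(pred, p), lam)
        pearson(gaussian_blur(uncertainty_map(iv), blur_sigma),
                gaussian_blur(error_map(p$x, p$y), blur_sigma))
      }, numeric(1))
      list(pearson = mean(pr), lambda = lam)
    }
    qr <- one_mode("QR")
    resm <- one_mode("ResM")
    rows[[r]] <- data.frame(rep = r, seed = s,
                            pearson_qr = qr$pearson,
                            pearson_resm = resm$pearson,
                            lambda_qr = qr$lambda,
                            lambda_resm = resm$lambda)
  }
  do.call(rbind, rows)
}
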