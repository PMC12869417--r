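## Conformal calibration of the offset scale lambda: scaled intervals,
## empirical miscoverage risk, the Hoeffding-corrected upper bound, and the
## smallest-lambda search.

#' Scale raw quantile offsets by a calibration factor
#'
#' The calibrated interval at scale `lam` is
#' `lower_b = x - lam * (x - lower)` and `upper_b = x + lam * (upper - x)`:
#' `lam = 1` reproduces the raw bounds, `lam = 0` collapses onto `x`, and the
#' width grows linearly in `lam`.
#'
#' @param x Reconstruction magnitude image.
#' @param bounds A `quantile_bounds` bracketing `x`.
#' @param lam Nonnegative scale factor.
#' @param alpha_miscoverage,delta Optional calibration metadata recorded on
#'   the result.
#' @return Object of class `calibrated_intervals` with fields `lower_b`,
#'   `upper_b`, `x`, `lambda`, `alpha_miscoverage`, `delta`.
#' @export
#' @examples
#' b <- quantile_bounds(matrix(10), matrix(0.2), matrix(0.3))
#' interval_at_lambda(matrix(10), b, 2) # bounds 6 and 16
interval_at_lambda <- function(x, bounds, lam,
                               alpha_miscoverage = NA_real_,
                               delta = NA_real_) {
  stopifnot(inherits(bounds, "quantile_bounds"))
  check_same_dim(x, bounds$lower, "x and bounds")
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam < 0) {
    stop_mriuq("'lam' must be a single nonnegative number",
               class = "mriuq_argument_error")
  }
  structure(list(
    lower_b = x - lam * (x - bounds$lower),
    upper_b = x + lam * (bounds$upper - x),
    x = x, lambda = lam,
    alpha_miscoverage = alpha_miscoverage, delta = delta
  ), class = "calibrated_intervals")
}

#' Empirical pixelwise miscoverage risk
#'
#' Fraction of pixels whose ground-truth intensity falls strictly outside the
#' closed calibrated interval.
#'
#' @param intervals A `calibrated_intervals`.
#' @param y Ground-truth image of matching shape.
#' @return Scalar in `[0, 1]`.
#' @export
miscoverage_risk <- function(intervals, y) {
  stopifnot(inherits(intervals, "calibrated_intervals"))
  check_same_dim(intervals$lower_b, y, "intervals and ground truth")
  mean(y < intervals$lower_b | y > intervals$upper_b)
}

#' Hoeffding-corrected upper bound on the mean risk
#'
#' For `I` bounded-[0,1] per-image risks, the one-sided Hoeffding bound at
#' confidence `1 - delta` is `mean(risks) + sqrt(log(1/delta) / (2 * I))`.
#'
#' @param per_image_risks Numeric vector of per-image risks in `[0, 1]`.
#' @param delta Confidence parameter in (0, 1]; `delta = 1` gives zero slack.
#' @return Scalar upper bound (may exceed 1).
#' @export
hoeffding_upper_bound <- function(per_image_risks, delta) {
  if (length(per_image_risks) == 0) {
    stop_mriuq("at least one calibration risk is required",
               class = "mriuq_data_error")
  }
  if (any(per_image_risks < 0 | per_image_risks > 1)) {
    stop_mriuq("risks must lie in [0, 1]", class = "mriuq_argument_error")
  }
  check_scalar_in(delta, 0, 1, "delta", open = c(TRUE, FALSE))
  mean(per_image_risks) + sqrt(log(1 / delta) / (2 * length(per_image_risks)))
}

# Per-pixel critical lambda: smallest lambda at which the pixel is covered.
# Exactly reproduces miscoverage_risk(interval_at_lambda(x, b, g)) = mean(lc > g).
critical_lambda <- function(pair, bounds) {
  x <- pair$x; y <- pair$y
  lo_off <- x - bounds$lower   # >= 0
  up_off <- bounds$upper - x   # >= 0
  gap <- y - x
  lc <- numeric(length(x))
  below <- gap < 0
  above <- gap > 0
  lc[below] <- ifelse(lo_off[below] > 0, -gap[below] / lo_off[below], Inf)
  lc[above] <- ifelse(up_off[above] > 0, gap[above] / up_off[above], Inf)
  lc
}

#' Calibrate the offset scale on a held-out calibration set
#'
#' For each grid value the per-image (or pooled-pixel) miscoverage risk is
#' formed and bounded from above with the Hoeffding correction; the chosen
#' scale is the smallest grid value whose bound does not exceed
#' `alpha_miscoverage`. Risk is nonincreasing in lambda, so `method =
#' "bisect"` may binary-search the grid; both methods return identical
#' records.
#'
#' @param cal_pairs Nonempty list of items `list(pair = recon_pair, bounds =
#'   quantile_bounds)`.
#' @param alpha_miscoverage Target miscoverage level in (0, 1), e.g. 0.10 for
#'   90% coverage.
#' @param delta Hoeffding confidence parameter in (0, 1].
#' @param lambda_grid Increasing nonnegative grid of candidate scales.
#' @param aggregate `"per_image"`: each calibration image contributes one
#'   bounded risk to the Hoeffding bound (I = number of images).
#'   `"pooled"`: all calibration pixels are pooled into a single empirical
#'   risk (I = total pixel count). Small calibration sets may make the
#'   per-image slack alone exceed `alpha_miscoverage`, in which case
#'   calibration is infeasible at any scale and pooling is the operative
#'   choice.
#' @param method Grid search strategy; `"scan"` (linear) and `"bisect"`
#'   (binary search over the nonincreasing bound) are equivalent.
#' @return Object of class `calibration_record`: `lambda_grid`,
#'   `per_lambda_risk`, `per_lambda_bound`, `chosen_lambda` (`NA` when
#'   infeasible), `infeasible` flag, `n_calibration`, `n_pixels`,
#'   `alpha_miscoverage`, `delta`, `aggregate`.
#' @export
calibrate_lambda <- function(cal_pairs, alpha_miscoverage = 0.1, delta = 0.1,
                             lambda_grid = seq(0, 4, by = 0.01),
                             aggregate = c("per_image", "pooled"),
                             method = c("scan", "bisect")) {
  aggregate <- match.arg(aggregate)
  method <- match.arg(method)
  if (length(cal_pairs) == 0) {
    stop_mriuq("calibration set is empty: cannot calibrate lambda",
               class = "mriuq_data_error")
  }
  if (length(lambda_grid) == 0 || is.unsorted(lambda_grid, strictly = TRUE) ||
      any(lambda_grid < 0)) {
    stop_mriuq("'lambda_grid' must be nonempty, nonnegative and increasing",
               class = "mriuq_argument_error")
  }
  check_scalar_in(alpha_miscoverage, 0, 1, "alpha_miscoverage")

  # risk matrix: images x grid, risk_ij = fraction of pixels of image i not
  # covered at lambda_grid[j]; computed exactly via per-pixel critical lambdas
  lcs <- lapply(cal_pairs, function(it) critical_lambda(it$pair, it$bounds))
  risk_of <- function(lc) {
    s <- sort(lc)  # Inf sorts last; findInterval counts s <= g
    1 - findInterval(lambda_grid, s) / length(lc)
  }
  risk_mat <- do.call(rbind, lapply(lcs, risk_of))
  n_pixels <- sum(lengths(lcs))

  if (aggregate == "per_image") {
    per_lambda_risk <- colMeans(risk_mat)
    i_eff <- length(cal_pairs)
  } else {
    w <- lengths(lcs) / n_pixels
    per_lambda_risk <- drop(w %*% risk_mat)  # pooled pixel fraction
    i_eff <- n_pixels
  }
  slack <- sqrt(log(1 / delta) / (2 * i_eff))
  per_lambda_bound <- per_lambda_risk + slack

  ok <- per_lambda_bound <= alpha_miscoverage
  idx <- if (!any(ok)) NA_integer_ else if (method == "scan") {
    which(ok)[1L]
  } else {
    # binary search for the first TRUE of a nondecreasing ok-vector
    lo <- 1L; hi <- length(ok)
    while (lo < hi) {
      mid <- (lo + hi) %/% 2L
      if (ok[mid]) hi <- mid else lo <- mid + 1L
    }
    lo
  }
  infeasible <- is.na(idx)
  if (infeasible) {
    warning(sprintf(
      paste0("calibration infeasible: no lambda in [%g, %g] achieves bound <= %g ",
             "(minimum bound %.4f); widen the grid or enlarge the calibration set"),
      min(lambda_grid), max(lambda_grid), alpha_miscoverage,
      min(per_lambda_bound)
    ), call. = FALSE)
  }
  structure(list(
    lambda_grid = lambda_grid,
    per_lambda_risk = as.numeric(per_lambda_risk),
    per_lambda_bound = as.numeric(per_lambda_bound),
    chosen_lambda = if (infeasible) NA_real_ else lambda_grid[idx],
    infeasible = infeasible,
    n_calibration = length(cal_pairs),
    n_pixels = n_pixels,
    alpha_miscoverage = alpha_miscoverage,
    delta = delta,
    aggregate = aggregate
  ), class = "calibration_record")
}

#' @export
print.calibration_record <- function(x, ...) {
  cat(sprintf(
    "Conformal calibration (%s, I = %d images, %d pixels)\n",
    x$aggregate, x$n_calibration, x$n_pixels
  ))
  cat(sprintf("  alpha = %g, delta = %g, grid [%g, %g] (%d points)\n",
              x$alpha_miscoverage, x$delta, min(x$lambda_grid),
              max(x$lambda_grid), length(x$lambda_grid)))
  if (x$infeasible) {
    cat(sprintf("  INFEASIBLE: minimum risk bound %.4f > alpha\n",
                min(x$per_lambda_bound)))
  } else {
    i <- match(x$chosen_lambda, x$lambda_grid)
    cat(sprintf("  chosen lambda = %g (risk %.4f, bound %.4f)\n",
                x$chosen_lambda, x$per_lambda_risk[i], x$per_lambda_bound[i]))
  }
  invisible(x)
}

#' Serialize a calibration record to JSON
#'
#' @param record A `calibration_record`.
#' @param path Output path.
#' @export
write_calibration_record <- function(record, path) {
  stopifnot(inherits(record, "calibration_record"))
  jsonlite::write_json(unclass(record), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
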