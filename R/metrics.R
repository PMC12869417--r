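## Uncertainty/error maps and the correlation evaluation suite: Gaussian
## blurring, global and region-based Pearson/Spearman correlations, coverage,
## normalized-percentage summaries, and threshold maps.

#' Pixelwise uncertainty-width map
#'
#' `q = upper_b - lower_b`; computable without any ground truth.
#'
#' @param intervals A `calibrated_intervals`.
#' @param norm_scale Normalization scale (maximum reconstruction magnitude by
#'   default).
#' @return Object of class `uncertainty_map` with fields `q_tilde` (>= 0) and
#'   `norm_scale`.
#' @export
uncertainty_map <- function(intervals, norm_scale = max(intervals$x)) {
  stopifnot(inherits(intervals, "calibrated_intervals"))
  structure(list(q_tilde = intervals$upper_b - intervals$lower_b,
                 norm_scale = norm_scale),
            class = "uncertainty_map")
}

#' Pixelwise absolute-error map
#'
#' `e = |x - y|`; requires the ground truth.
#'
#' @param x Reconstruction.
#' @param y Ground truth of the same shape.
#' @return Object of class `error_map` with field `e_tilde`.
#' @export
error_map <- function(x, y) {
  check_same_dim(x, y, "x and y")
  structure(list(e_tilde = abs(x - y)), class = "error_map")
}

as_map_matrix <- function(m) {
  if (inherits(m, "uncertainty_map")) return(m$q_tilde)
  if (inherits(m, "error_map")) return(m$e_tilde)
  m
}

#' Gaussian blur with reflective boundary
#'
#' Separable Gaussian convolution, kernel truncated at 4 standard deviations,
#' reflective boundary handling (mass-preserving: the mean of the output
#' equals the mean of the input). `sigma = 0` is the identity.
#'
#' @param map Real matrix (or `uncertainty_map` / `error_map`).
#' @param sigma Nonnegative standard deviation in pixels.
#' @return Blurred matrix.
#' @export
gaussian_blur <- function(map, sigma = 2) {
  m <- as_map_matrix(map)
  if (sigma < 0) {
    stop_mriuq("'sigma' must be >= 0", class = "mriuq_argument_error")
  }
  if (sigma == 0) return(m)
  conv_separable(m, gaussian_kernel_1d(sigma, truncate = 4))
}

#' Pearson correlation between two maps
#'
#' `cov(a, b) / (sd(a) sd(b))` over all pixels.
#'
#' @param a,b Real matrices of identical shape, both non-constant.
#' @return Scalar in `[-1, 1]`.
#' @export
pearson <- function(a, b) {
  a <- as_map_matrix(a); b <- as_map_matrix(b)
  check_same_dim(a, b, "correlation inputs")
  if (sd(a) == 0 || sd(b) == 0) {
    stop_mriuq("correlation undefined: at least one input is constant",
               class = "mriuq_degenerate_error")
  }
  stats::cor(as.vector(a), as.vector(b))
}

#' Spearman rank correlation between two maps
#'
#' Pearson correlation of the rank-transformed maps; ties receive average
#' ranks.
#'
#' @param a,b Real matrices of identical shape, both non-constant after
#'   ranking.
#' @return Scalar in `[-1, 1]`.
#' @export
spearman <- function(a, b) {
  a <- as_map_matrix(a); b <- as_map_matrix(b)
  check_same_dim(a, b, "correlation inputs")
  if (sd(rank(a)) == 0 || sd(rank(b)) == 0) {
    stop_mriuq("correlation undefined: at least one input is constant",
               class = "mriuq_degenerate_error")
  }
  stats::cor(as.vector(a), as.vector(b), method = "spearman")
}

#' Partition an image into non-overlapping rectangular regions
#'
#' Tiles the image with an `r x c` grid of `n_regions` blocks (10 x 10 by
#' default) whose side lengths differ by at most one pixel; remainder rows and
#' columns are given to the top-left blocks.
#'
#' @param height,width Image dimensions.
#' @param n_regions Number of blocks; must factor into a near-square grid.
#' @return List of `n_regions` blocks, each `list(rows, cols)` of 1-based
#'   index vectors; the blocks tile the image exactly once.
#' @export
region_partition <- function(height, width, n_regions = 100L) {
  r <- floor(sqrt(n_regions))
  while (r > 1 && n_regions %% r != 0) r <- r - 1
  cc <- n_regions %/% r
  if (r * cc != n_regions) {
    stop_mriuq("'n_regions' must factor into a rectangular grid",
               class = "mriuq_argument_error")
  }
  if (height < r || width < cc) {
    stop_mriuq(sprintf("image %dx%d smaller than the %dx%d region grid",
                       height, width, r, cc),
               class = "mriuq_argument_error")
  }
  split_axis <- function(n, k) {
    sizes <- rep(n %/% k, k)
    extra <- n %% k
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    ends <- cumsum(sizes)
    mapply(function(e, s) seq.int(e - s + 1L, e), ends, sizes,
           SIMPLIFY = FALSE)
  }
  rows <- split_axis(height, r)
  cols <- split_axis(width, cc)
  out <- vector("list", n_regions)
  i <- 1L
  for (rr in seq_len(r)) for (ccc in seq_len(cc)) {
    out[[i]] <- list(rows = rows[[rr]], cols = cols[[ccc]])
    i <- i + 1L
  }
  out
}

#' Region-averaged correlation between uncertainty and error
#'
#' Computes the chosen correlation within each block of a [region_partition()]
#' and averages over blocks; blocks where either map is constant are skipped
#' and counted (attribute `"n_skipped"`).
#'
#' @param q Uncertainty map (matrix or `uncertainty_map`).
#' @param e Error map (matrix or `error_map`).
#' @param n_regions Number of regions (default 100).
#' @param method `"pearson"` or `"spearman"`.
#' @return Scalar mean correlation with attribute `n_skipped`.
#' @export
region_correlations <- function(q, e, n_regions = 100L,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  qm <- as_map_matrix(q); em <- as_map_matrix(e)
  check_same_dim(qm, em, "region correlation inputs")
  blocks <- region_partition(nrow(qm), ncol(qm), n_regions)
  f <- if (method == "pearson") pearson else spearman
  vals <- numeric(0)
  skipped <- 0L
  for (b in blocks) {
    qa <- qm[b$rows, b$cols]; ea <- em[b$rows, b$cols]
    const <- if (method == "pearson") {
      sd(qa) == 0 || sd(ea) == 0
    } else {
      sd(rank(qa)) == 0 || sd(rank(ea)) == 0
    }
    if (const) skipped <- skipped + 1L else vals <- c(vals, f(qa, ea))
  }
  if (length(vals) == 0) {
    stop_mriuq("all regions are degenerate: correlation undefined",
               class = "mriuq_degenerate_error")
  }
  structure(mean(vals), n_skipped = skipped)
}

#' Empirical pixelwise coverage
#'
#' `1 - miscoverage_risk`: the fraction of ground-truth pixels inside the
#' calibrated intervals.
#'
#' @param intervals A `calibrated_intervals`.
#' @param y Ground truth.
#' @return Scalar in `[0, 1]`.
#' @export
coverage <- function(intervals, y) 1 - miscoverage_risk(intervals, y)

#' Normalized uncertainty summary (percent of the reconstruction maximum)
#'
#' @param q An `uncertainty_map` with positive `norm_scale`.
#' @return List with `mean_pct` and `sd_pct`: `100 * mean(q)/norm_scale` and
#'   `100 * sd(q)/norm_scale`.
#' @export
normalized_uncertainty_summary <- function(q) {
  stopifnot(inherits(q, "uncertainty_map"))
  if (!is.finite(q$norm_scale) || q$norm_scale <= 0) {
    stop_mriuq("'norm_scale' must be > 0", class = "mriuq_argument_error")
  }
  list(mean_pct = 100 * mean(q$q_tilde) / q$norm_scale,
       sd_pct = 100 * stats::sd(q$q_tilde) / q$norm_scale)
}

#' Threshold an uncertainty map at a reference level
#'
#' Zeroes pixels at or below `reference_max` (e.g. the maximum uncertainty
#' observed at a clinically accepted acceleration) and keeps the rest at their
#' value, highlighting where uncertainty exceeds the reference.
#'
#' @param q Uncertainty map (matrix or `uncertainty_map`).
#' @param reference_max Nonnegative threshold.
#' @return Thresholded matrix.
#' @export
threshold_map <- function(q, reference_max) {
  m <- as_map_matrix(q)
  if (reference_max < 0) {
    stop_mriuq("'reference_max' must be >= 0", class = "mriuq_argument_error")
  }
  m[m <= reference_max] <- 0
  m
}

#' Full correlation report between uncertainty and error
#'
#' Blurs both maps (sigma = 2 by default, per the evaluation protocol), then
#' computes global Pearson/Spearman and 100-region averaged variants.
#'
#' @param q Uncertainty map.
#' @param e Error map.
#' @param blur_sigma Gaussian blur SD applied to both maps before
#'   correlating; set 0 for raw maps.
#' @param n_regions Regions for the block-averaged metrics.
#' @return Object of class `correlation_report` with fields `pearson_r`,
#'   `spearman_rho`, `region_pearson`, `region_spearman`, `blur_sigma`,
#'   `n_regions`, `n_skipped_pearson`, `n_skipped_spearman`.
#' @export
correlation_report <- function(q, e, blur_sigma = 2, n_regions = 100L) {
  qb <- gaussian_blur(q, blur_sigma)
  eb <- gaussian_blur(e, blur_sigma)
  rp <- region_correlations(qb, eb, n_regions, "pearson")
  rs <- region_correlations(qb, eb, n_regions, "spearman")
  structure(list(
    pearson_r = pearson(qb, eb),
    spearman_rho = spearman(qb, eb),
    region_pearson = as.numeric(rp),
    region_spearman = as.numeric(rs),
    blur_sigma = blur_sigma,
    n_regions = n_regions,
    n_skipped_pearson = attr(rp, "n_skipped"),
    n_skipped_spearman = attr(rs, "n_skipped")
  ), class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf(
    paste0("Uncertainty-error correlations (blur sigma = %g):\n",
           "  Pearson %.3f | Spearman %.3f | region-Pearson %.3f | ",
           "region-Spearman %.3f (%d regions)\n"),
    x$blur_sigma, x$pearson_r, x$spearman_rho, x$region_pearson,
    x$region_spearman, x$n_regions
  ))
  invisible(x)
}
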