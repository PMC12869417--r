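## Reconstruction operators at toy scale: coil reduce/expand, RSS combination,
## hard data consistency, a zero-filled baseline, an optional mini-unrolled
## reconstructor, and SSIM.

#' Combine coil images into a single image (reduce operator)
#'
#' Pixelwise sum over coils of `conj(sensitivity) * coil_image`. With
#' RSS-normalized maps this is the adjoint (and left inverse) of
#' [expand_operator()].
#'
#' @param coil_images Complex array (coil x height x width).
#' @param coils A `coil_maps` of matching dimensions.
#' @return Complex height x width matrix.
#' @export
reduce_operator <- function(coil_images, coils) {
  stopifnot(inherits(coils, "coil_maps"))
  check_same_dim(coil_images, coils$maps, "coil images and sensitivity maps")
  d <- dim(coil_images)
  prod <- Conj(coils$maps) * coil_images
  matrix(colSums(matrix(prod, nrow = d[1])), d[2], d[3])
}

#' Project a combined image onto individual coils (expand operator)
#'
#' Per-coil product `sensitivity * image`.
#'
#' @param image Complex (or real) height x width matrix.
#' @param coils A `coil_maps`.
#' @return Complex array (coil x height x width).
#' @export
expand_operator <- function(image, coils) {
  stopifnot(inherits(coils, "coil_maps"))
  d <- dim(coils$maps)
  if (!identical(dim(image), d[2:3])) {
    stop_mriuq("image and coil map dimensions disagree",
               class = "mriuq_shape_error")
  }
  coils$maps * array(rep(as.complex(image), each = d[1]), dim = d)
}

#' Root-sum-of-squares coil combination
#'
#' @param coil_images Complex array (coil x height x width) with at least one
#'   coil.
#' @return Real nonnegative height x width matrix.
#' @export
rss <- function(coil_images) {
  d <- dim(coil_images)
  if (is.null(d) || length(d) != 3L || d[1] < 1L) {
    stop_mriuq("'coil_images' must be a nonempty coil x height x width array",
               class = "mriuq_argument_error")
  }
  matrix(sqrt(colSums(matrix(Mod(coil_images)^2, nrow = d[1]))), d[2], d[3])
}

#' Enforce hard data consistency in k-space
#'
#' Replaces estimated k-space values on measured phase-encode lines with the
#' measured values; unmeasured lines pass through. Idempotent.
#'
#' @param kspace_est Complex array (coil x readout x phase-encode).
#' @param kspace_meas A `kspace_data` holding the measured (masked) k-space.
#' @param mask The `sampling_mask` that defines the measured lines.
#' @return Complex array with measured lines replaced.
#' @export
data_consistency <- function(kspace_est, kspace_meas, mask) {
  stopifnot(inherits(kspace_meas, "kspace_data"), inherits(mask, "sampling_mask"))
  check_same_dim(kspace_est, kspace_meas$kspace, "estimated and measured k-space")
  sel <- mask$line_selected
  kspace_est[, , sel] <- kspace_meas$kspace[, , sel]
  kspace_est
}

#' Zero-filled RSS reconstruction
#'
#' Inverse-transforms the (optionally masked) k-space coil by coil and
#' combines with RSS. At acceleration 1 with no noise this reproduces the
#' ground truth to float tolerance; at higher accelerations it exhibits the
#' aliasing that makes pixelwise uncertainty informative.
#'
#' @param kspace A `kspace_data`.
#' @param mask Optional `sampling_mask` applied before reconstruction.
#' @return Real nonnegative height x width magnitude image.
#' @export
zero_filled_rss <- function(kspace, mask = NULL) {
  stopifnot(inherits(kspace, "kspace_data"))
  if (!is.null(mask)) kspace <- apply_mask(kspace, mask)
  d <- dim(kspace$kspace)
  imgs <- array(0i, dim = d)
  for (c in seq_len(d[1])) imgs[c, , ] <- ifft2c(kspace$kspace[c, , ])
  rss(imgs)
}

#' Pair a reconstruction with its ground truth
#'
#' @param x Reconstruction magnitude image (nonnegative matrix).
#' @param y Ground-truth magnitude image of the same shape.
#' @param norm_scale Normalization scale; defaults to `max(x)`, the maximum
#'   reconstruction magnitude of the evaluated slice.
#' @return Object of class `recon_pair` with fields `x`, `y`, `norm_scale`.
#' @export
recon_pair <- function(x, y, norm_scale = max(x)) {
  check_same_dim(x, y, "reconstruction and ground truth")
  if (!is.finite(norm_scale) || norm_scale <= 0) {
    stop_mriuq("'norm_scale' must be > 0", class = "mriuq_argument_error")
  }
  structure(list(x = x, y = y, norm_scale = norm_scale), class = "recon_pair")
}

## ---- Reconstructor contract ---------------------------------------------

#' Reconstruct a magnitude image from undersampled k-space
#'
#' Generic entry point of the Reconstructor contract: any reconstructor is an
#' object with a `reconstruct` method mapping (k-space, mask, optional coil
#' maps) to a magnitude image, deterministic for fixed inputs.
#'
#' @param reconstructor A reconstructor object.
#' @param kspace A `kspace_data`.
#' @param mask A `sampling_mask`.
#' @param coils Optional `coil_maps` (required by unrolled reconstructors).
#' @return Real magnitude image.
#' @export
reconstruct <- function(reconstructor, kspace, mask, coils = NULL) {
  UseMethod("reconstruct")
}

#' Zero-filled baseline reconstructor
#'
#' @return Reconstructor object applying [zero_filled_rss()].
#' @export
zero_filled_reconstructor <- function() {
  structure(list(name = "zero_filled"),
            class = c("zf_reconstructor", "reconstructor"))
}

#' @export
reconstruct.zf_reconstructor <- function(reconstructor, kspace, mask,
                                         coils = NULL) {
  zero_filled_rss(kspace, mask)
}

#' Mini unrolled reconstructor
#'
#' A small unrolled cascade: each of `n_cascades` iterations reduces the coil
#' images to a combined image, applies a Gaussian-smoothing denoiser to the
#' real and imaginary parts, expands back to coils, transforms to k-space and
#' enforces hard data consistency. Deterministic; intended as a second,
#' less-aliased reconstructor behind the same contract.
#'
#' @param n_cascades Number of cascades (1-3 typical).
#' @param denoise_sigma Gaussian denoiser width in pixels.
#' @return Reconstructor object.
#' @export
unrolled_reconstructor <- function(n_cascades = 3L, denoise_sigma = 0.8) {
  stopifnot(n_cascades >= 1)
  structure(list(name = "unrolled", n_cascades = n_cascades,
                 denoise_sigma = denoise_sigma),
            class = c("unrolled_reconstructor", "reconstructor"))
}

#' @export
reconstruct.unrolled_reconstructor <- function(reconstructor, kspace, mask,
                                               coils = NULL) {
  if (is.null(coils)) {
    stop_mriuq("unrolled reconstruction requires coil maps",
               class = "mriuq_argument_error")
  }
  meas <- apply_mask(kspace, mask)
  d <- dim(meas$kspace)
  ks <- meas$kspace
  kern <- gaussian_kernel_1d(reconstructor$denoise_sigma)
  for (it in seq_len(reconstructor$n_cascades)) {
    imgs <- array(0i, dim = d)
    for (c in seq_len(d[1])) imgs[c, , ] <- ifft2c(ks[c, , ])
    comb <- reduce_operator(imgs, coils)
    den <- conv_separable(Re(comb), kern) + 1i * conv_separable(Im(comb), kern)
    est <- expand_operator(den, coils)
    for (c in seq_len(d[1])) est[c, , ] <- fft2c(est[c, , ])
    ks <- data_consistency(est, meas, mask)
  }
  imgs <- array(0i, dim = d)
  for (c in seq_len(d[1])) imgs[c, , ] <- ifft2c(ks[c, , ])
  rss(imgs)
}

## ---- SSIM ----------------------------------------------------------------

#' Structural similarity index (mean SSIM)
#'
#' Mean local SSIM with a uniform or Gaussian window over full-size local
#' statistics (reflective boundary).
#'
#' @param x,y Real images of identical shape.
#' @param window Odd window side length (default 7).
#' @param k1,k2 Stabilization constants (defaults 0.01 and 0.03).
#' @param data_range Dynamic range L of the data (> 0); defaults to
#'   `max(y) - min(y)`.
#' @param method `"uniform"` (default) or `"gaussian"` (sigma = window/6)
#'   window.
#' @return Scalar mean SSIM in `[-1, 1]`.
#' @export
ssim <- function(x, y, window = 7L, k1 = 0.01, k2 = 0.03,
                 data_range = max(y) - min(y),
                 method = c("uniform", "gaussian")) {
  check_same_dim(x, y, "SSIM inputs")
  method <- match.arg(method)
  if (data_range <= 0) {
    stop_mriuq("'data_range' must be > 0", class = "mriuq_argument_error")
  }
  if (window %% 2 == 0) {
    stop_mriuq("'window' must be odd", class = "mriuq_argument_error")
  }
  kern <- if (method == "uniform") uniform_kernel_1d(window) else {
    g <- gaussian_kernel_1d(window / 6, truncate = 3)
    # clip to the requested window size
    r <- (length(g) - 1) / 2; w <- (window - 1) / 2
    g <- g[(r - w + 1):(r + w + 1)]
    g / sum(g)
  }
  mu_x <- conv_separable(x, kern)
  mu_y <- conv_separable(y, kern)
  sxx <- conv_separable(x * x, kern) - mu_x^2
  syy <- conv_separable(y * y, kern) - mu_y^2
  sxy <- conv_separable(x * y, kern) - mu_x * mu_y
  c1 <- (k1 * data_range)^2
  c2 <- (k2 * data_range)^2
  num <- (2 * mu_x * mu_y + c1) * (2 * sxy + c2)
  den <- (mu_x^2 + mu_y^2 + c1) * (sxx + syy + c2)
  mean(num / den)
}
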