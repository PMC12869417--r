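## Synthetic multi-coil MRI data: ellipse phantoms, smooth coil sensitivities,
## and noisy Cartesian k-space. Every generator is a pure function of its seed.

#' Generate a nested-ellipse phantom with optional focal anomalies
#'
#' Builds a Shepp-Logan-like ground-truth magnitude image from a stack of
#' nested smooth ellipses, plus `n_anomalies` small high-contrast ellipses
#' standing in for focal lesions. Anomaly geometry is recorded so tests can
#' recover exact region masks.
#'
#' @param height,width Image dimensions in pixels (at least 16).
#' @param n_anomalies Number of lesion-surrogate ellipses (>= 0).
#' @param seed Integer seed; output is bit-reproducible for a fixed seed.
#' @return An object of class `ground_truth_image` with fields `pixels`
#'   (height x width nonnegative matrix), `anomaly_regions` (list of ellipse
#'   descriptors with `center`, `axes`, `angle`, `delta`) and `seed`.
#' @export
#' @examples
#' ph <- make_phantom(64, 64, n_anomalies = 2, seed = 1)
#' range(ph$pixels)
make_phantom <- function(height, width, n_anomalies = 0L, seed = 1L) {
  if (!is.numeric(height) || !is.numeric(width) || height < 16 || width < 16) {
    stop_mriuq("'height' and 'width' must be >= 16", class = "mriuq_argument_error")
  }
  if (n_anomalies < 0) {
    stop_mriuq("'n_anomalies' must be >= 0", class = "mriuq_argument_error")
  }
  withr::with_seed(seed, {
    xs <- (seq_len(width) - (width + 1) / 2) / (width / 2)
    ys <- (seq_len(height) - (height + 1) / 2) / (height / 2)
    X <- matrix(rep(xs, each = height), height, width)
    Y <- matrix(rep(ys, times = width), height, width)

    img <- matrix(0, height, width)
    # outer "skull" ellipse and nested interior structures; intensities add
    n_shells <- 4L
    a0 <- runif(1, 0.82, 0.92)
    b0 <- runif(1, 0.82, 0.92)
    shell_scale <- cumprod(c(1, runif(n_shells - 1L, 0.62, 0.85)))
    shell_int <- c(0.35, runif(n_shells - 1L, 0.1, 0.3))
    theta0 <- runif(1, -pi / 8, pi / 8)
    for (s in seq_len(n_shells)) {
      img <- img + shell_int[s] *
        ellipse_mask_xy(X, Y, c(0, 0), c(a0, b0) * shell_scale[s], theta0)
    }
    # a pair of off-centre "ventricle"-like hypointense ellipses
    for (sgn in c(-1, 1)) {
      img <- img - runif(1, 0.08, 0.16) *
        ellipse_mask_xy(X, Y, c(sgn * runif(1, 0.12, 0.22), runif(1, -0.1, 0.1)),
                        c(runif(1, 0.08, 0.14), runif(1, 0.16, 0.26)), theta0)
    }

    anomaly_regions <- vector("list", n_anomalies)
    inner <- c(a0, b0) * shell_scale[2L]
    for (k in seq_len(n_anomalies)) {
      repeat {
        ctr <- c(runif(1, -0.5, 0.5), runif(1, -0.5, 0.5))
        axes <- runif(2, 0.04, 0.10)
        # keep the whole anomaly inside the second shell (and the image)
        if (sum(((abs(ctr) + max(axes)) / inner)^2) <= 1) break
      }
      delta <- sample(c(-1, 1), 1) * runif(1, 0.25, 0.45)
      img <- img + delta * ellipse_mask_xy(X, Y, ctr, axes, 0)
      anomaly_regions[[k]] <- list(center = ctr, axes = axes, angle = 0,
                                   delta = delta)
    }
    img[img < 0] <- 0
    structure(list(pixels = img, anomaly_regions = anomaly_regions, seed = seed),
              class = "ground_truth_image")
  })
}

# membership of normalized coordinates (X, Y) in a rotated ellipse
ellipse_mask_xy <- function(X, Y, center, axes, angle) {
  dx <- X - center[1]
  dy <- Y - center[2]
  u <- dx * cos(angle) + dy * sin(angle)
  v <- -dx * sin(angle) + dy * cos(angle)
  (u / axes[1])^2 + (v / axes[2])^2 <= 1
}

#' Recover the binary anomaly mask of a phantom
#'
#' @param image A `ground_truth_image`.
#' @return Logical matrix, `TRUE` inside any recorded anomaly ellipse.
#' @export
anomaly_mask <- function(image) {
  stopifnot(inherits(image, "ground_truth_image"))
  d <- dim(image$pixels)
  xs <- (seq_len(d[2]) - (d[2] + 1) / 2) / (d[2] / 2)
  ys <- (seq_len(d[1]) - (d[1] + 1) / 2) / (d[1] / 2)
  X <- matrix(rep(xs, each = d[1]), d[1], d[2])
  Y <- matrix(rep(ys, times = d[2]), d[1], d[2])
  m <- matrix(FALSE, d[1], d[2])
  for (a in image$anomaly_regions) {
    m <- m | ellipse_mask_xy(X, Y, a$center, a$axes, a$angle)
  }
  m
}

#' Simulate smooth complex coil sensitivity maps
#'
#' Coil magnitudes are Gaussian bumps centred on a ring around the image with a
#' small uniform floor; phases are low-order polynomials in position. Maps are
#' normalized so the root sum of squares over coils is exactly 1 at every
#' pixel, which makes the RSS of noiseless coil images reproduce the phantom.
#'
#' @param height,width Image dimensions.
#' @param n_coils Number of receive coils (>= 1).
#' @param seed Integer seed.
#' @return Object of class `coil_maps`: `maps` is a complex array
#'   (coil x height x width), `n_coils` an integer.
#' @export
make_coil_maps <- function(height, width, n_coils = 4L, seed = 1L) {
  if (n_coils < 1) {
    stop_mriuq("'n_coils' must be >= 1", class = "mriuq_argument_error")
  }
  withr::with_seed(seed, {
    xs <- (seq_len(width) - (width + 1) / 2) / (width / 2)
    ys <- (seq_len(height) - (height + 1) / 2) / (height / 2)
    X <- matrix(rep(xs, each = height), height, width)
    Y <- matrix(rep(ys, times = width), height, width)
    ang <- 2 * pi * (seq_len(n_coils) - 1) / n_coils + runif(1, 0, 2 * pi)
    maps <- array(0i, dim = c(n_coils, height, width))
    for (c in seq_len(n_coils)) {
      cx <- 1.1 * cos(ang[c])
      cy <- 1.1 * sin(ang[c])
      mag <- exp(-((X - cx)^2 + (Y - cy)^2) / (2 * 0.7^2)) + 0.05
      ph <- runif(1, -pi, pi) + runif(1, -1, 1) * X + runif(1, -1, 1) * Y +
        runif(1, -0.5, 0.5) * X * Y
      maps[c, , ] <- mag * exp(1i * ph)
    }
    norm <- sqrt(apply(Mod(maps)^2, c(2, 3), sum))
    for (c in seq_len(n_coils)) maps[c, , ] <- maps[c, , ] / norm
    structure(list(maps = maps, n_coils = as.integer(n_coils)),
              class = "coil_maps")
  })
}

#' Simulate noisy multi-coil Cartesian k-space
#'
#' Per-coil k-space is the orthonormal centred 2-D Fourier transform of the
#' sensitivity-weighted phantom, plus i.i.d. complex Gaussian noise with
#' standard deviation `noise_sigma` per real/imaginary component.
#'
#' @param image A `ground_truth_image`.
#' @param coils A `coil_maps` with matching dimensions.
#' @param noise_sigma Nonnegative noise standard deviation (k-space units).
#' @param seed Integer seed for the noise realization.
#' @return Object of class `kspace_data`: `kspace` complex array
#'   (coil x readout x phase-encode), `noise_sigma`, `seed`.
#' @export
simulate_kspace <- function(image, coils, noise_sigma = 0.01, seed = 1L) {
  stopifnot(inherits(image, "ground_truth_image"), inherits(coils, "coil_maps"))
  d <- dim(image$pixels)
  if (!identical(dim(coils$maps)[2:3], d)) {
    stop_mriuq("coil maps and image dimensions disagree",
               class = "mriuq_shape_error")
  }
  if (noise_sigma < 0) {
    stop_mriuq("'noise_sigma' must be >= 0", class = "mriuq_argument_error")
  }
  nc <- coils$n_coils
  ks <- array(0i, dim = c(nc, d[1], d[2]))
  for (c in seq_len(nc)) {
    ks[c, , ] <- fft2c(coils$maps[c, , ] * image$pixels)
  }
  if (noise_sigma > 0) {
    withr::with_seed(seed, {
      n <- length(ks)
      ks <- ks + complex(real = rnorm(n, 0, noise_sigma),
                         imaginary = rnorm(n, 0, noise_sigma))
    })
  }
  structure(list(kspace = ks, noise_sigma = noise_sigma, seed = seed),
            class = "kspace_data")
}

#' Default simulation parameters
#'
#' @param height,width Image size.
#' @param n_coils Number of coils.
#' @param n_anomalies Anomalies per phantom.
#' @param noise_sigma k-space complex-Gaussian noise SD per component.
#' @return Named list of simulation parameters.
#' @export
sim_params <- function(height = 64L, width = 64L, n_coils = 4L,
                       n_anomalies = 2L, noise_sigma = 0.01) {
  list(height = height, width = width, n_coils = n_coils,
       n_anomalies = n_anomalies, noise_sigma = noise_sigma)
}

#' Generate disjoint train / validation / calibration / test partitions
#'
#' Each item is an independently seeded (k-space, ground truth, coil maps)
#' triple; item seeds are drawn without replacement so partitions never share a
#' seed.
#'
#' @param n_train,n_val,n_cal,n_test Partition sizes (>= 0).
#' @param params Simulation parameters from [sim_params()].
#' @param seed Master seed from which all item seeds are derived.
#' @return List with elements `train`, `val`, `cal`, `test`; each a list of
#'   items `list(kspace, image, coils, seed)`.
#' @export
make_split_dataset <- function(n_train, n_val, n_cal, n_test,
                               params = sim_params(), seed = 1L) {
  counts <- c(train = n_train, val = n_val, cal = n_cal, test = n_test)
  if (any(counts < 0)) {
    stop_mriuq("partition sizes must be >= 0", class = "mriuq_argument_error")
  }
  total <- sum(counts)
  item_seeds <- if (total > 0) {
    withr::with_seed(seed, sample.int(.Machine$integer.max - 3L, total))
  } else integer(0)
  make_item <- function(s) {
    img <- make_phantom(params$height, params$width, params$n_anomalies,
                        seed = s)
    cm <- make_coil_maps(params$height, params$width, params$n_coils,
                         seed = s + 1L)
    ks <- simulate_kspace(img, cm, params$noise_sigma, seed = s + 2L)
    list(kspace = ks, image = img, coils = cm, seed = s)
  }
  out <- list()
  off <- 0L
  for (nm in names(counts)) {
    out[[nm]] <- lapply(item_seeds[seq_len(counts[[nm]]) + off], make_item)
    off <- off + counts[[nm]]
  }
  out
}
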