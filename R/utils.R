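#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor fft rnorm runif plogis quantile sd optimize
#' @importFrom utils write.csv head tail
NULL

## ---- argument checking helpers ------------------------------------------

stop_mriuq <- function(..., class = "mriuq_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_same_dim <- function(a, b, what = "inputs") {
  if (!identical(dim2(a), dim2(b))) {
    stop_mriuq(sprintf(
      "%s must have identical dimensions (got %s vs %s)",
      what, paste(dim2(a), collapse = "x"), paste(dim2(b), collapse = "x")
    ), class = "mriuq_shape_error")
  }
  invisible(TRUE)
}

# dim() that treats a bare vector as length-n
dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

check_scalar_in <- function(x, lo, hi, name, open = c(TRUE, TRUE)) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open[1]) x > lo else x >= lo) && (if (open[2]) x < hi else x <= hi)
  if (!ok) {
    br <- c(if (open[1]) "(" else "[", if (open[2]) ")" else "]")
    stop_mriuq(sprintf("'%s' must be a single number in %s%s, %s%s",
                       name, br[1], lo, hi, br[2]),
               class = "mriuq_argument_error")
  }
  invisible(TRUE)
}

## ---- centered unitary 2-D Fourier transform ------------------------------

fftshift2 <- function(x) {
  d <- dim(x)
  x[c(seq_len(d[1]) + floor(d[1] / 2) - 1) %% d[1] + 1,
    c(seq_len(d[2]) + floor(d[2] / 2) - 1) %% d[2] + 1, drop = FALSE]
}

ifftshift2 <- function(x) {
  d <- dim(x)
  x[c(seq_len(d[1]) + ceiling(d[1] / 2) - 1) %% d[1] + 1,
    c(seq_len(d[2]) + ceiling(d[2] / 2) - 1) %% d[2] + 1, drop = FALSE]
}

# Orthonormal centered 2-D DFT: Parseval holds exactly (energy preserved).
fft2c <- function(x) fftshift2(stats::fft(ifftshift2(x))) / sqrt(length(x))

ifft2c <- function(k) {
  fftshift2(stats::fft(ifftshift2(k), inverse = TRUE)) / sqrt(length(k))
}

## ---- separable convolution with reflective boundary ----------------------

# pad-by-reflection 1-D convolution along matrix rows, kernel must be odd-length
conv_reflect_rows <- function(x, kernel) {
  r <- (length(kernel) - 1L) / 2L
  n <- nrow(x)
  if (r == 0L) return(x * kernel)
  if (r >= n) stop_mriuq("kernel radius exceeds image extent",
                         class = "mriuq_argument_error")
  # half-sample symmetric reflection (scipy ndimage 'reflect'): for a
  # normalized symmetric kernel this conserves the total mass exactly
  idx <- c(rev(seq_len(r)), seq_len(n), n + 1L - seq_len(r))
  xp <- x[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(x))
  for (j in seq_along(kernel)) {
    out <- out + kernel[j] * xp[seq_len(n) + (j - 1L), , drop = FALSE]
  }
  out
}

conv_separable <- function(x, kernel) {
  t(conv_reflect_rows(t(conv_reflect_rows(x, kernel)), kernel))
}

gaussian_kernel_1d <- function(sigma, truncate = 4) {
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  k <- exp(-0.5 * (seq(-r, r) / sigma)^2)
  k / sum(k)
}

uniform_kernel_1d <- function(size) rep(1 / size, size)
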