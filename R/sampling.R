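## Cartesian undersampling: a 1-D mask over phase-encode lines with a centred
## contiguous block of autocalibration (ACS) lines and equispaced sampling of
## the periphery.

# ACS fraction retained at each nominal acceleration, per acquisition protocol
.acs_protocol <- list(
  brain = c(`2` = 0.16, `4` = 0.08, `6` = 0.053, `8` = 0.04, `10` = 0.03),
  knee  = c(`4` = 0.08, `6` = 0.053)
)

#' ACS fraction for a protocol (anatomy, acceleration) combination
#'
#' Fraction of central phase-encode lines retained as autocalibration signal:
#' brain protocols retain 16%, 8%, 5.3%, 4% and 3% of central k-space at
#' accelerations 2, 4, 6, 8 and 10; knee protocols retain 8% and 5.3% at 4 and
#' 6.
#'
#' @param anatomy `"brain"` or `"knee"`.
#' @param acceleration Nominal acceleration factor.
#' @return The ACS fraction as a real number in (0, 1).
#' @export
#' @examples
#' protocol_acs_fraction("brain", 4) # 0.08
protocol_acs_fraction <- function(anatomy, acceleration) {
  anatomy <- match.arg(anatomy, c("brain", "knee"))
  key <- as.character(acceleration)
  tab <- .acs_protocol[[anatomy]]
  if (!key %in% names(tab)) {
    stop_mriuq(sprintf(
      "no protocol entry for anatomy '%s' at acceleration %s (available: %s)",
      anatomy, key, paste(names(tab), collapse = ", ")
    ), class = "mriuq_lookup_error")
  }
  unname(tab[[key]])
}

#' Construct a Cartesian undersampling mask
#'
#' Selects `round(acs_fraction * n_lines)` centred contiguous ACS lines out of
#' a total budget of `round(n_lines / acceleration)` lines; the remaining
#' budget is spread equispaced over the non-ACS lines. With `seed = NULL`
#' (the default, a fixed mask) the equispaced phase is 0; a seed randomizes
#' the phase.
#'
#' @param n_lines Number of phase-encode lines (>= 4).
#' @param acceleration Nominal acceleration in `[1, n_lines]`.
#' @param acs_fraction Fraction of lines kept as ACS, in (0, 1).
#' @param seed Optional integer seed for a random equispaced phase.
#' @return Object of class `sampling_mask`: logical `line_selected`, integer
#'   `acs_lines` (1-based), `acceleration`, `acs_fraction`.
#' @export
#' @examples
#' m <- make_cartesian_mask(100, 4, protocol_acs_fraction("brain", 4))
#' sum(m$line_selected) # 25
make_cartesian_mask <- function(n_lines, acceleration, acs_fraction,
                                seed = NULL) {
  if (n_lines < 4) {
    stop_mriuq("'n_lines' must be >= 4", class = "mriuq_argument_error")
  }
  if (acceleration < 1 || acceleration > n_lines) {
    stop_mriuq("'acceleration' must lie in [1, n_lines]",
               class = "mriuq_argument_error")
  }
  check_scalar_in(acs_fraction, 0, 1, "acs_fraction")
  budget <- round(n_lines / acceleration)
  n_acs <- round(acs_fraction * n_lines)
  if (budget < n_acs) {
    stop_mriuq(sprintf(
      "infeasible mask: %d ACS lines exceed the sampling budget of %d lines",
      n_acs, budget
    ), class = "mriuq_infeasible_error")
  }
  sel <- logical(n_lines)
  acs_start <- floor((n_lines - n_acs) / 2)  # 0-based, half-open block
  acs_lines <- acs_start + seq_len(n_acs)
  sel[acs_lines] <- TRUE
  n_rem <- budget - n_acs
  if (n_rem > 0) {
    non_acs <- which(!sel)
    step <- length(non_acs) / n_rem
    phase <- if (is.null(seed)) 0 else
      withr::with_seed(seed, runif(1, 0, step))
    picks <- non_acs[floor(phase + (seq_len(n_rem) - 1) * step) + 1L]
    sel[picks] <- TRUE
  }
  structure(list(line_selected = sel, acs_lines = as.integer(acs_lines),
                 acceleration = acceleration, acs_fraction = acs_fraction),
            class = "sampling_mask")
}

#' @export
print.sampling_mask <- function(x, ...) {
  cat(sprintf(
    "Cartesian sampling mask: %d/%d lines (nominal R=%g, realized R=%.2f), %d ACS lines\n",
    sum(x$line_selected), length(x$line_selected), x$acceleration,
    length(x$line_selected) / sum(x$line_selected), length(x$acs_lines)
  ))
  invisible(x)
}

#' Apply a line mask to multi-coil k-space
#'
#' Zeroes the unselected phase-encode lines (last array axis) across all
#' coils; selected lines pass through unchanged.
#'
#' @param kspace A `kspace_data`.
#' @param mask A `sampling_mask` whose length matches the phase-encode axis.
#' @return A `kspace_data` with unselected lines zeroed.
#' @export
apply_mask <- function(kspace, mask) {
  stopifnot(inherits(kspace, "kspace_data"), inherits(mask, "sampling_mask"))
  d <- dim(kspace$kspace)
  if (d[3] != length(mask$line_selected)) {
    stop_mriuq(sprintf(
      "mask length %d does not match phase-encode dimension %d",
      length(mask$line_selected), d[3]
    ), class = "mriuq_shape_error")
  }
  ks <- kspace$kspace
  ks[, , !mask$line_selected] <- 0i
  structure(list(kspace = ks, noise_sigma = kspace$noise_sigma,
                 seed = kspace$seed),
            class = "kspace_data")
}
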