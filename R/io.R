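## Array and dataset I/O: a minimal NPY v1.0 codec (double, complex, logical,
## integer), the multi-coil k-space bundle format, and mask serialization.

#' Write an R array to an NPY file
#'
#' Minimal NPY v1.0 writer for double, complex, logical and integer arrays.
#' Data are written C-ordered little-endian with dtypes `<f8`, `<c16`, `|b1`,
#' `<i4`.
#'
#' @param x Vector, matrix or array.
#' @param path Output file path.
#' @export
npy_write <- function(x, path) {
  d <- dim2(x)
  descr <- if (is.complex(x)) "<c16" else if (is.logical(x)) "|b1"
    else if (is.integer(x)) "<i4" else if (is.numeric(x)) "<f8"
    else stop_mriuq("unsupported array type for NPY",
                    class = "mriuq_format_error")
  shape <- paste0("(", paste0(d, ",", collapse = " "), ")")
  shape <- sub(", \\)$", ")", sub(",\\)$", ",)", shape))
  header <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': %s, }",
                    descr, shape)
  pad <- 64L - ((10L + nchar(header) + 1L) %% 64L)
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(0x93), charToRaw("NUMPY"), as.raw(c(1, 0))), con)
  writeBin(as.integer(nchar(header)), con, size = 2, endian = "little")
  writeBin(charToRaw(header), con)
  # C order: transpose the axis order before flattening column-major
  v <- if (length(d) > 1L) as.vector(aperm(array(x, d), rev(seq_along(d)))) else
    as.vector(x)
  if (is.logical(x)) {
    writeBin(as.raw(as.integer(v)), con)
  } else if (is.integer(x)) {
    writeBin(v, con, size = 4, endian = "little")
  } else {
    writeBin(v, con, endian = "little")
  }
  invisible(path)
}

#' Read an NPY file written by [npy_write()] (or NumPy)
#'
#' Supports dtypes `<f8`, `<c16`, `|b1`, `<i4`/`<i8` in C or Fortran order.
#'
#' @param path NPY file path.
#' @return Array with the stored shape.
#' @export
npy_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8)
  if (!identical(magic[1:6], c(as.raw(0x93), charToRaw("NUMPY")))) {
    stop_mriuq("not an NPY file: ", path, class = "mriuq_format_error")
  }
  hlen <- readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr': '([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order': True", header)
  shape_s <- sub(".*'shape': \\(([^)]*)\\).*", "\\1", header)
  d <- as.integer(strsplit(gsub(" ", "", shape_s), ",")[[1]])
  if (length(d) == 0 || anyNA(d)) d <- integer(0)
  n <- if (length(d)) prod(d) else 1L
  v <- switch(descr,
    "<f8" = readBin(con, "double", n, endian = "little"),
    "<c16" = readBin(con, "complex", n, size = 16, endian = "little"),
    "|b1" = as.logical(readBin(con, "raw", n)),
    "<i4" = readBin(con, "integer", n, size = 4, endian = "little"),
    "<i8" = as.integer(readBin(con, "double", 0)) # fallthrough below
  )
  if (descr == "<i8") {
    stop_mriuq("64-bit integer NPY arrays are not supported",
               class = "mriuq_format_error")
  }
  if (is.null(v)) {
    stop_mriuq("unsupported NPY dtype: ", descr, class = "mriuq_format_error")
  }
  if (length(d) <= 1L) return(v)
  if (fortran) array(v, d) else aperm(array(v, rev(d)), rev(seq_along(d)))
}

#' Write a multi-coil k-space bundle
#'
#' Serializes a simulated acquisition as a directory holding `kspace.npy`
#' (coil x readout x phase-encode complex array), optionally
#' `reconstruction_rss.npy` (the ground-truth magnitude image), and a
#' `meta.json` sidecar with seed and noise level.
#'
#' @param kspace A `kspace_data`.
#' @param path Directory to create/overwrite.
#' @param ground_truth Optional `ground_truth_image` (or matrix).
#' @return `path`, invisibly.
#' @export
write_kspace_bundle <- function(kspace, path, ground_truth = NULL) {
  stopifnot(inherits(kspace, "kspace_data"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  npy_write(kspace$kspace, file.path(path, "kspace.npy"))
  if (!is.null(ground_truth)) {
    gt <- if (inherits(ground_truth, "ground_truth_image"))
      ground_truth$pixels else ground_truth
    npy_write(gt, file.path(path, "reconstruction_rss.npy"))
  }
  jsonlite::write_json(list(seed = kspace$seed,
                            noise_sigma = kspace$noise_sigma,
                            shape = dim(kspace$kspace)),
                       file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-coil k-space bundle
#'
#' @param path Bundle directory written by [write_kspace_bundle()].
#' @return List with `kspace` (a `kspace_data`) and `ground_truth` (matrix or
#'   `NULL` when `reconstruction_rss` is absent, restricting downstream use to
#'   inference-only mode).
#' @export
read_kspace_bundle <- function(path) {
  kfile <- file.path(path, "kspace.npy")
  if (!file.exists(kfile)) {
    stop_mriuq("bundle is missing the 'kspace' dataset (kspace.npy): ", path,
               class = "mriuq_format_error")
  }
  ks <- npy_read(kfile)
  if (length(dim(ks)) != 3L) {
    stop_mriuq(sprintf(
      "'kspace' must be a rank-3 coil x readout x phase-encode array (got rank %d)",
      length(dim2(ks))
    ), class = "mriuq_format_error")
  }
  meta <- if (file.exists(file.path(path, "meta.json"))) {
    jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  } else list(seed = NA_integer_, noise_sigma = NA_real_)
  gfile <- file.path(path, "reconstruction_rss.npy")
  gt <- if (file.exists(gfile)) npy_read(gfile) else NULL
  list(
    kspace = structure(list(kspace = ks, noise_sigma = meta$noise_sigma,
                            seed = meta$seed), class = "kspace_data"),
    ground_truth = gt
  )
}

#' Serialize a sampling mask (NPY boolean vector + JSON sidecar)
#'
#' @param mask A `sampling_mask`.
#' @param path Path stem; writes `<path>.npy` and `<path>.json`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "sampling_mask"))
  npy_write(mask$line_selected, paste0(path, ".npy"))
  jsonlite::write_json(list(acceleration = mask$acceleration,
                            acs_fraction = mask$acs_fraction,
                            n_acs = length(mask$acs_lines),
                            acs_lines = mask$acs_lines),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a sampling mask written by [write_mask()]
#'
#' @param path Path stem used at write time.
#' @return A `sampling_mask`.
#' @export
read_mask <- function(path) {
  sel <- as.logical(npy_read(paste0(path, ".npy")))
  j <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(line_selected = sel, acs_lines = as.integer(j$acs_lines),
                 acceleration = j$acceleration, acs_fraction = j$acs_fraction),
            class = "sampling_mask")
}
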