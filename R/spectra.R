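#' Single infrared spectrum
#'
#' @param intensities Numeric vector of absorbance (or 2nd-derivative)
#'   values, one per axis channel.
#' @param axis Wavenumber axis (see [wn_axis()]).
#' @param derivative_order 0 for absorbance, 2 for a second derivative.
#' @return An object of class `ir_spectrum`.
#' @export
ir_spectrum <- function(intensities, axis, derivative_order = 0L) {
  validate_axis(axis)
  if (length(intensities) != length(axis))
    stop("invalid-parameter: intensities and axis lengths differ", call. = FALSE)
  if (!all(is.finite(intensities)))
    stop("invalid-parameter: non-finite intensities", call. = FALSE)
  if (!derivative_order %in% c(0L, 2L))
    stop("invalid-parameter: derivative_order must be 0 or 2", call. = FALSE)
  structure(list(intensities = as.numeric(intensities),
                 axis = as.numeric(axis),
                 derivative_order = as.integer(derivative_order)),
            class = "ir_spectrum")
}

#' @export
print.ir_spectrum <- function(x, ...) {
  cat(sprintf("<ir_spectrum> %d channels, %.0f-%.0f cm^-1, derivative order %d\n",
              length(x$axis), min(x$axis), max(x$axis), x$derivative_order))
  invisible(x)
}

#' Hyperspectral FTIR image cube
#'
#' The central container: an `n_rows x n_cols x n_channels` array with a
#' wavenumber axis. Pixels are addressed `(row, col)` with `(1, 1)` top-left;
#' the anterior-posterior width of a disc section runs along columns.
#' Flattened to a matrix (see [cube_matrix()]) pixels are ordered row-major,
#' giving the `D` matrix consumed by MCR.
#'
#' @param cube Numeric 3-d array `(rows, cols, channels)`.
#' @param axis Wavenumber axis, length = `dim(cube)[3]`.
#' @param derivative_order 0 or 2.
#' @param pixel_size_um Optional pixel edge length in micrometres.
#' @return An object of class `hyper_image`.
#' @export
hyper_image <- function(cube, axis, derivative_order = 0L, pixel_size_um = NULL) {
  validate_axis(axis)
  if (!is.array(cube) || length(dim(cube)) != 3L)
    stop("invalid-parameter: cube must be a 3-d array", call. = FALSE)
  if (dim(cube)[3] != length(axis))
    stop("invalid-parameter: third cube dimension must match axis", call. = FALSE)
  if (!derivative_order %in% c(0L, 2L))
    stop("invalid-parameter: derivative_order must be 0 or 2", call. = FALSE)
  structure(list(cube = cube, axis = as.numeric(axis),
                 derivative_order = as.integer(derivative_order),
                 pixel_size_um = pixel_size_um),
            class = "hyper_image")
}

#' @export
print.hyper_image <- function(x, ...) {
  d <- dim(x$cube)
  cat(sprintf("<hyper_image> %d x %d pixels, %d channels (%.0f-%.0f cm^-1), derivative order %d\n",
              d[1], d[2], d[3], min(x$axis), max(x$axis), x$derivative_order))
  invisible(x)
}

#' @rdname hyper_image
#' @param x A `hyper_image`.
#' @export
n_rows <- function(x) dim(x$cube)[1]

#' @rdname hyper_image
#' @export
n_cols <- function(x) dim(x$cube)[2]

#' Flatten a cube to the pixels x channels matrix D
#'
#' Pixels are ordered row-major (all columns of row 1, then row 2, ...).
#' @param image A `hyper_image`.
#' @return Matrix of dimension `(n_rows*n_cols) x n_channels`.
#' @export
cube_matrix <- function(image) {
  d <- dim(image$cube)
  m <- matrix(aperm(image$cube, c(2L, 1L, 3L)), nrow = d[1] * d[2], ncol = d[3])
  m
}

# Inverse of cube_matrix: matrix rows (row-major pixels) back to an array.
matrix_cube <- function(m, nr, nc) {
  aperm(array(m, dim = c(nc, nr, ncol(m))), c(2L, 1L, 3L))
}

# Row-major linear index of (row, col) pixels, matching cube_matrix ordering.
pixel_index <- function(row, col, nc) (row - 1L) * nc + col

#' Pixel inclusion mask
#'
#' @param included Logical matrix, `TRUE` = tissue pixel retained.
#' @return Object of class `pixel_mask` (a logical matrix).
#' @export
pixel_mask <- function(included) {
  if (!is.matrix(included) || !is.logical(included))
    stop("invalid-parameter: mask must be a logical matrix", call. = FALSE)
  if (!any(included))
    stop("empty-mask: no pixel included", call. = FALSE)
  structure(included, class = c("pixel_mask", "matrix", "array"))
}

mask_check <- function(mask, image) {
  if (!identical(dim(mask), dim(image$cube)[1:2]))
    stop("incompatible-image: mask dimensions do not match image", call. = FALSE)
  if (!any(mask)) stop("empty-mask: no pixel included", call. = FALSE)
  invisible(mask)
}

# -- Savitzky-Golay second derivative -----------------------------------------

# Full channels x channels linear operator applying the SG 2nd derivative,
# interior channels by the central filter row, edge channels by one-sided
# polynomial fits (the startup/finish rows of signal::sgolay).
sg_operator <- function(n_chan, window_length, poly_order) {
  if (window_length %% 2L != 1L)
    stop("invalid-parameter: window_length must be odd", call. = FALSE)
  if (window_length < poly_order + 2L)
    stop("invalid-parameter: window_length must be >= poly_order + 2", call. = FALSE)
  if (n_chan < window_length)
    stop("invalid-parameter: window longer than trace", call. = FALSE)
  FF <- signal::sgolay(p = poly_order, n = window_length, m = 2, ts = 1)
  FF <- unclass(FF)
  k <- (window_length - 1L) %/% 2L
  A <- matrix(0, n_chan, n_chan)
  for (i in seq_len(k)) {
    A[i, 1:window_length] <- FF[i, ]
    A[n_chan - k + i, (n_chan - window_length + 1L):n_chan] <- FF[k + 1L + i, ]
  }
  central <- FF[k + 1L, ]
  for (i in (k + 1L):(n_chan - k)) A[i, (i - k):(i + k)] <- central
  A
}

#' Savitzky-Golay second derivative
#'
#' Per-trace local least-squares polynomial second derivative (default:
#' polynomial order 3, 15-point window — the standard smoothing scale for
#' 2 cm^-1 spaced FTIR data). Output is the raw filter response in
#' per-(axis step)^2 units; no division by the physical channel spacing is
#' applied, so only relative magnitudes matter downstream. Edge channels are
#' computed from the polynomial fitted to the one-sided end window, which
#' keeps the axis length unchanged.
#'
#' @param x An [ir_spectrum()] or [hyper_image()] with `derivative_order` 0.
#' @param window_length Odd filter length in channels (default 15).
#' @param poly_order Polynomial order of the local fit (default 3).
#' @return Object of the same class with `derivative_order = 2`.
#' @export
second_derivative <- function(x, window_length = 15L, poly_order = 3L) {
  UseMethod("second_derivative")
}

#' @export
second_derivative.ir_spectrum <- function(x, window_length = 15L, poly_order = 3L) {
  if (x$derivative_order != 0L)
    stop("invalid-parameter: input must be underivatized (derivative_order 0)", call. = FALSE)
  A <- sg_operator(length(x$axis), window_length, poly_order)
  ir_spectrum(drop(A %*% x$intensities), x$axis, derivative_order = 2L)
}

#' @export
second_derivative.hyper_image <- function(x, window_length = 15L, poly_order = 3L) {
  if (x$derivative_order != 0L)
    stop("invalid-parameter: input must be underivatized (derivative_order 0)", call. = FALSE)
  A <- sg_operator(length(x$axis), window_length, poly_order)
  D <- cube_matrix(x) %*% t(A)
  hyper_image(matrix_cube(D, n_rows(x), n_cols(x)), x$axis,
              derivative_order = 2L, pixel_size_um = x$pixel_size_um)
}

# -- normalisation / offset / region ------------------------------------------

#' Vector-normalize a spectrum over a wavenumber window
#'
#' Divides the whole trace by the Euclidean norm computed over channels in
#' `[lo, hi]` (default 950-1800 cm^-1), so the in-window norm of the result
#' is 1.
#'
#' @param spectrum An [ir_spectrum()].
#' @param lo,hi Window bounds in cm^-1.
#' @return Normalized `ir_spectrum`.
#' @export
vector_normalize <- function(spectrum, lo = 950, hi = 1800) {
  idx <- wn_window(spectrum$axis, lo, hi)
  nrm <- sqrt(sum(spectrum$intensities[idx]^2))
  if (nrm <= 0)
    stop("degenerate-spectrum: zero norm over normalization window", call. = FALSE)
  ir_spectrum(spectrum$intensities / nrm, spectrum$axis, spectrum$derivative_order)
}

#' Offset-correct a spectrum
#'
#' Subtracts a single scalar so the minimum over `[lo, hi]` becomes zero;
#' the trace shape is preserved.
#'
#' @inheritParams vector_normalize
#' @return Offset-corrected `ir_spectrum`.
#' @export
offset_correct <- function(spectrum, lo = 950, hi = 1800) {
  idx <- wn_window(spectrum$axis, lo, hi)
  ir_spectrum(spectrum$intensities - min(spectrum$intensities[idx]),
              spectrum$axis, spectrum$derivative_order)
}

#' Restrict to a spectral region
#'
#' Keeps channels with `lo <= wavenumber <= hi` (both bounds inclusive).
#'
#' @param x A `hyper_image` or `ir_spectrum`.
#' @param lo,hi Region bounds in cm^-1.
#' @return Object of the same class on the restricted axis.
#' @export
select_region <- function(x, lo, hi) UseMethod("select_region")

#' @export
select_region.hyper_image <- function(x, lo, hi) {
  idx <- wn_window(x$axis, lo, hi, min_channels = 2L)
  hyper_image(x$cube[, , idx, drop = FALSE], x$axis[idx],
              derivative_order = x$derivative_order,
              pixel_size_um = x$pixel_size_um)
}

#' @export
select_region.ir_spectrum <- function(x, lo, hi) {
  idx <- wn_window(x$axis, lo, hi, min_channels = 2L)
  ir_spectrum(x$intensities[idx], x$axis[idx], x$derivative_order)
}

# -- masking / averaging / collation ------------------------------------------

#' Mask paraffin/substrate-only pixels by spectral statistics
#'
#' A pixel is retained iff its 2nd-derivative value at the channel nearest
#' `marker_wavenumber` is strictly below `threshold`. Tissue shows a strong
#' negative amide II 2nd-derivative lobe near 1554 cm^-1; paraffin- or
#' substrate-only pixels do not, and are excluded at the default threshold 0.
#'
#' @param image A `hyper_image` with `derivative_order = 2`.
#' @param marker_wavenumber Marker band in cm^-1 (default 1554).
#' @param threshold Inclusion threshold on the 2nd-derivative value (default 0).
#' @return A [pixel_mask()].
#' @export
compute_mask <- function(image, marker_wavenumber = 1554, threshold = 0) {
  if (image$derivative_order != 2L)
    stop("invalid-parameter: compute_mask needs a 2nd-derivative image", call. = FALSE)
  if (marker_wavenumber < min(image$axis) || marker_wavenumber > max(image$axis))
    stop("invalid-parameter: marker outside axis range", call. = FALSE)
  ch <- wn_nearest(image$axis, marker_wavenumber)
  inc <- image$cube[, , ch] < threshold
  if (!any(inc)) stop("empty-mask: all pixels excluded", call. = FALSE)
  pixel_mask(inc)
}

#' Average spectrum over a pixel region
#'
#' @param image A `hyper_image`.
#' @param region Logical matrix / [pixel_mask()] of pixels to average.
#' @return An [ir_spectrum()] (channel-wise arithmetic mean).
#' @export
region_average <- function(image, region) {
  mask_check(region, image)
  D <- cube_matrix(image)
  sel <- as.vector(t(region))     # row-major, matching cube_matrix
  ir_spectrum(colMeans(D[sel, , drop = FALSE]), image$axis, image$derivative_order)
}

#' Collate images by stacking along the row axis
#'
#' Samples measured separately are merged into one data matrix; e.g. the
#' 92 x 228 control and injected cubes of one animal collate to 184 x 228.
#'
#' @param images List of `hyper_image`s sharing axis and column count.
#' @return One `hyper_image` with `n_rows` the sum of the inputs'.
#' @export
collate <- function(images) {
  if (!is.list(images) || length(images) < 1L)
    stop("invalid-parameter: need a non-empty list of images", call. = FALSE)
  ref <- images[[1]]
  for (im in images) {
    if (!isTRUE(all.equal(im$axis, ref$axis)) || n_cols(im) != n_cols(ref) ||
        im$derivative_order != ref$derivative_order)
      stop("incompatible-image: axis, column count or derivative order differ",
           call. = FALSE)
  }
  cubes <- lapply(images, `[[`, "cube")
  total <- sum(vapply(cubes, function(x) dim(x)[1], integer(1)))
  out <- array(0, dim = c(total, n_cols(ref), length(ref$axis)))
  at <- 0L
  for (cb in cubes) {
    out[at + seq_len(dim(cb)[1]), , ] <- cb
    at <- at + dim(cb)[1]
  }
  hyper_image(out, ref$axis, ref$derivative_order, ref$pixel_size_um)
}

#' Mosaic image dimensions from tiling and detector geometry
#'
#' A mosaic of `tiles_rows x tiles_cols` focal-plane-array frames, each
#' `fpa_rows x fpa_cols` detector pixels, binned by `aggregation` detector
#' pixels per output pixel, yields an image of
#' `tiles_rows * fpa_rows / sqrt(aggregation)` by
#' `tiles_cols * fpa_cols / sqrt(aggregation)` pixels.
#'
#' @param tiles_rows,tiles_cols Mosaic tile counts.
#' @param fpa_rows,fpa_cols Detector frame size (default 64 x 64).
#' @param aggregation Detector pixels per output pixel; must be a perfect
#'   square whose root divides both frame dimensions.
#' @return Integer vector `c(n_rows, n_cols)`.
#' @examples
#' mosaic_dimensions(23, 57, 64, 64, 256)  # 92 x 228
#' @export
mosaic_dimensions <- function(tiles_rows, tiles_cols, fpa_rows = 64L,
                              fpa_cols = 64L, aggregation = 256L) {
  s <- sqrt(aggregation)
  if (s != round(s))
    stop("invalid-parameter: aggregation must be a perfect square", call. = FALSE)
  s <- as.integer(round(s))
  if (fpa_rows %% s != 0L || fpa_cols %% s != 0L)
    stop("invalid-parameter: sqrt(aggregation) must divide the FPA dimensions",
         call. = FALSE)
  c(n_rows = as.integer(tiles_rows * fpa_rows %/% s),
    n_cols = as.integer(tiles_cols * fpa_cols %/% s))
}
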