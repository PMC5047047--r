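#' Construct a wavenumber axis
#'
#' A wavenumber axis is a strictly monotone numeric vector of band positions
#' in cm^-1. FTIR imaging data are collected from high to low wavenumber, so
#' the default axis is descending; every range-based operation in the package
#' is order-agnostic.
#'
#' @param lo,hi Extremes of the axis in cm^-1.
#' @param by Channel spacing in cm^-1 (default 2, the usual point density of
#'   4 cm^-1 resolution interferograms).
#' @param descending Store the axis from `hi` down to `lo` (default `TRUE`).
#' @return Numeric vector of wavenumbers.
#' @examples
#' ax <- wn_axis(900, 1800)
#' length(ax)
#' @export
wn_axis <- function(lo = 900, hi = 1800, by = 2, descending = TRUE) {
  if (!is.numeric(lo) || !is.numeric(hi) || hi <= lo)
    stop("invalid-parameter: need hi > lo", call. = FALSE)
  if (by <= 0) stop("invalid-parameter: spacing must be > 0", call. = FALSE)
  v <- seq(lo, hi, by = by)
  if (descending) rev(v) else v
}

validate_axis <- function(axis) {
  if (!is.numeric(axis) || length(axis) < 2L)
    stop("invalid-parameter: axis must be numeric, length >= 2", call. = FALSE)
  d <- diff(axis)
  if (!all(is.finite(axis)) || !(all(d > 0) || all(d < 0)))
    stop("invalid-parameter: axis must be strictly monotone", call. = FALSE)
  invisible(axis)
}

#' Nominal channel spacing of an axis
#'
#' Median absolute difference of consecutive wavenumbers.
#' @param axis Numeric wavenumber vector.
#' @return Spacing in cm^-1.
#' @export
wn_spacing <- function(axis) {
  validate_axis(axis)
  stats::median(abs(diff(axis)))
}

#' Index of the channel nearest a wavenumber
#' @param axis Numeric wavenumber vector.
#' @param wn Target wavenumber in cm^-1.
#' @return Integer channel index.
#' @export
wn_nearest <- function(axis, wn) {
  validate_axis(axis)
  which.min(abs(axis - wn))[1L]
}

# Channel indices with lo <= wavenumber <= hi, in storage order.
# Bounds inclusive; when a bound falls between samples the nearest channel
# inside the closed interval is what the inequality selects.
wn_window <- function(axis, lo, hi, min_channels = 1L) {
  validate_axis(axis)
  if (hi < lo) { tmp <- lo; lo <- hi; hi <- tmp }
  idx <- which(axis >= lo & axis <= hi)
  if (length(idx) < min_channels)
    stop("invalid-region: fewer than ", min_channels,
         " channels in [", lo, ", ", hi, "] cm^-1", call. = FALSE)
  idx
}
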