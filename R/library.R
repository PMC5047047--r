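#' Gaussian band model
#'
#' @param center Band position in cm^-1.
#' @param width Gaussian sigma in cm^-1.
#' @param amplitude Relative absorbance (>= 0).
#' @return A `band_model` (named list).
#' @export
band_model <- function(center, width, amplitude = 1) {
  if (width <= 0) stop("invalid-parameter: band width must be > 0", call. = FALSE)
  if (amplitude < 0) stop("invalid-parameter: band amplitude must be >= 0", call. = FALSE)
  structure(list(center = center, width = width, amplitude = amplitude),
            class = "band_model")
}

#' Reference component spectrum from a band table
#'
#' Sum of Gaussian bands evaluated on the axis, max-normalized to 1.
#'
#' @param name Component label.
#' @param bands List of [band_model()]s.
#' @param axis Wavenumber axis.
#' @return A `ref_spectrum`: `ir_spectrum` plus `name` and `bands` fields.
#' @export
reference_spectrum <- function(name, bands, axis) {
  validate_axis(axis)
  y <- rep(0, length(axis))
  for (b in bands)
    y <- y + b$amplitude * exp(-(axis - b$center)^2 / (2 * b$width^2))
  if (max(y) > 0) y <- y / max(y)
  out <- ir_spectrum(y, axis, 0L)
  out$name <- name
  out$bands <- bands
  class(out) <- c("ref_spectrum", class(out))
  out
}

#' Reference spectral library
#'
#' @param entries List of [reference_spectrum()]s with unique names sharing
#'   one axis.
#' @return A `ref_library`.
#' @export
reference_library <- function(entries) {
  nms <- vapply(entries, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("invalid-parameter: duplicate component names", call. = FALSE)
  ax <- entries[[1]]$axis
  for (e in entries)
    if (!isTRUE(all.equal(e$axis, ax)))
      stop("invalid-parameter: library entries must share one axis", call. = FALSE)
  names(entries) <- nms
  structure(list(entries = entries, axis = ax), class = "ref_library")
}

#' @export
print.ref_library <- function(x, ...) {
  cat("<ref_library>", paste(names(x$entries), collapse = ", "), "\n")
  invisible(x)
}

# Band tables for the IVD matrix components. Positions are literature band
# assignments for collagen I/II (amide II 1558 vs 1552, amide III, C-O),
# chondroitin-sulphate proteoglycan (C-O-S ~1126, SO3- ~1228, C-O-C 1064,
# C-OH 1030, 1160, 1376), elastin (1516, 1160) and crystalline paraffin
# (CH2/CH3 deformations 1473/1464/1378 plus weak CH2 wag/twist progression
# bands at 1303 and 1168). Amplitudes are synthetic choices (documented in
# the vignette); each spectrum is max-normalized.
ivd_band_tables <- function(pg_shift = 2) {
  list(
    collagen_I = list(
      band_model(1558, 12, 0.95), band_model(1282, 8, 0.35),
      band_model(1240, 10, 0.60), band_model(1202, 8, 0.30),
      band_model(1032, 12, 0.50)),
    collagen_II = list(
      band_model(1552, 12, 0.95), band_model(1238, 10, 0.60),
      band_model(1202, 8, 0.35), band_model(1082, 12, 0.45)),
    PG1 = list(
      band_model(1030, 10, 0.80), band_model(1064, 10, 0.90),
      band_model(1160, 9, 0.45), band_model(1126, 7, 0.65),
      band_model(1228, 10, 0.50), band_model(1376, 8, 0.30)),
    PG2 = list(
      band_model(1030, 10, 0.40), band_model(1064, 10, 1.00),
      band_model(1160, 9, 0.25), band_model(1126 - pg_shift, 7, 0.75),
      band_model(1228, 10, 0.30), band_model(1376, 8, 0.20)),
    elastin = list(
      band_model(1516, 12, 0.90), band_model(1160, 10, 0.50)),
    paraffin = list(
      band_model(1473, 5, 0.90), band_model(1464, 5, 1.00),
      band_model(1378, 6, 0.55), band_model(1303, 6, 0.12),
      band_model(1168, 7, 0.15))
  )
}

#' Default IVD reference library
#'
#' Six components: collagen I, collagen II, two proteoglycan populations
#' (PG2 is PG1 with the C-O-S band shifted from 1126 to `1126 - pg_shift`
#' cm^-1 and altered relative amplitudes), elastin, and paraffin.
#'
#' @param axis Wavenumber axis spanning at least 950-1600 cm^-1.
#' @param pg_shift Downward C-O-S shift of PG2 in cm^-1 (default 2).
#' @return A [reference_library()].
#' @export
default_library <- function(axis = wn_axis(), pg_shift = 2) {
  validate_axis(axis)
  if (min(axis) > 950 || max(axis) < 1600)
    stop("invalid-parameter: axis must span at least 950-1600 cm^-1", call. = FALSE)
  tabs <- ivd_band_tables(pg_shift)
  reference_library(lapply(names(tabs), function(nm)
    reference_spectrum(nm, tabs[[nm]], axis)))
}

#' Second-derivative versions of library entries
#'
#' @param library A [reference_library()].
#' @param window_length,poly_order Savitzky-Golay parameters (see
#'   [second_derivative()]).
#' @param negate Return the negated 2nd derivative — the working orientation
#'   used for MCR, in which absorbance bands are positive peaks.
#' @return Named list of `ir_spectrum`s with `derivative_order = 2`.
#' @export
library_second_derivative <- function(library, window_length = 15L,
                                      poly_order = 3L, negate = FALSE) {
  lapply(library$entries, function(e) {
    d2 <- second_derivative(ir_spectrum(e$intensities, e$axis, 0L),
                            window_length, poly_order)
    if (negate) d2$intensities <- -d2$intensities
    d2
  })
}
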