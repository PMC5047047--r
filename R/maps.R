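# Biological labelling of MCR factors: amide-III tissue maps, re-embedded
# concentration maps, component/tissue ratios, reference-based assignment and
# the C-O-S peak-position discrimination of the two proteoglycan populations.

# trapezoid weights on an (ascending-sorted) wavenumber window
trapz_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  w[1] <- (x[2] - x[1]) / 2
  w[n] <- (x[n] - x[n - 1]) / 2
  if (n > 2) w[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  w
}

#' Amide-III tissue map
#'
#' Per-pixel trapezoidal peak integration of the negated 2nd derivative over
#' the amide III window (default 1186-1297 cm^-1): the trace is rectified
#' pointwise (negative values set to zero) before integration, so the value
#' is the area of the negative 2nd-derivative lobes — a measure of overall
#' extracellular-matrix / tissue content used to normalize component maps.
#' (The raw integral of a 2nd derivative across a fully contained band is
#' zero by the fundamental theorem of calculus; rectification is what makes
#' "peak integration" of derivative spectra meaningful.) Masked pixels are
#' `NA`.
#'
#' @param image A `hyper_image` with `derivative_order = 2`.
#' @param mask A [pixel_mask()] / logical matrix.
#' @param lo,hi Integration window in cm^-1.
#' @return Numeric matrix with attribute `window`.
#' @export
tissue_map <- function(image, mask, lo = 1186, hi = 1297) {
  if (image$derivative_order != 2L)
    stop("invalid-parameter: tissue_map needs a 2nd-derivative image", call. = FALSE)
  mask_check(mask, image)
  idx <- wn_window(image$axis, lo, hi, min_channels = 2L)
  ax <- image$axis[idx]
  ord <- order(ax)
  w <- trapz_weights(ax[ord])
  D <- cube_matrix(image)[, idx[ord], drop = FALSE]
  vals <- drop(pmax(-D, 0) %*% w)          # pixels in row-major order
  sel <- as.vector(t(unclass(mask)))
  m <- rep(NA_real_, length(vals))
  m[sel] <- vals[sel]
  out <- matrix(m, nrow = n_rows(image), byrow = TRUE)
  attr(out, "window") <- c(lo, hi)
  out
}

#' Re-embed a factor's concentrations into the pixel grid
#'
#' @param model An `mcr_model` returned by [resolve()] (carries mask/grid).
#' @param factor_index Column of `C` to embed (1-based).
#' @return Numeric matrix (`NA` at masked pixels).
#' @export
component_map <- function(model, factor_index) {
  if (factor_index < 1L || factor_index > model$k)
    stop("invalid-parameter: factor_index out of range", call. = FALSE)
  if (is.null(model$mask) || is.null(model$grid))
    stop("invalid-parameter: model does not carry mask/grid information", call. = FALSE)
  nr <- model$grid[1]; nc <- model$grid[2]
  v <- rep(NA_real_, nr * nc)
  sel <- as.vector(t(model$mask))              # row-major order
  v[sel] <- model$C[, factor_index]
  matrix(v, nrow = nr, byrow = TRUE)
}

#' Component/tissue ratio map
#'
#' Elementwise division of a component map by the tissue map where the
#' tissue signal is at least `epsilon`; `NA` elsewhere. The default epsilon
#' is `1e-3` times the median tissue value over unmasked pixels, guarding
#' the division at tissue edges.
#'
#' @param component Component map matrix (from [component_map()]).
#' @param tissue Tissue map matrix (from [tissue_map()]).
#' @param epsilon Division guard; `NULL` for the default.
#' @return Numeric matrix with attribute `epsilon`.
#' @export
ratio_map <- function(component, tissue, epsilon = NULL) {
  if (!identical(dim(component), dim(tissue)))
    stop("incompatible-image: component and tissue grids differ", call. = FALSE)
  if (is.null(epsilon))
    epsilon <- 1e-3 * stats::median(tissue[!is.na(tissue)])
  out <- component / tissue
  out[is.na(tissue) | tissue < epsilon] <- NA_real_
  attr(out, "epsilon") <- epsilon
  out
}

# exact optimum of the injective assignment maximizing total score;
# enumeration over the smaller side (exact for k <= 8), greedy beyond
solve_assignment <- function(score, method = c("optimal", "greedy")) {
  method <- match.arg(method)
  k <- nrow(score); m <- ncol(score)
  if (method == "greedy" || min(k, m) > 8L) {
    assign_vec <- rep(NA_integer_, k)
    used <- logical(m)
    ord <- order(-apply(score, 1, max))
    for (i in ord) {
      cand <- order(-score[i, ])
      cand <- cand[!used[cand]]
      if (length(cand)) { assign_vec[i] <- cand[1]; used[cand[1]] <- TRUE }
    }
    return(assign_vec)
  }
  nsel <- min(k, m)
  best <- NULL; best_val <- -Inf
  idx_factors <- utils::combn(seq_len(k), nsel, simplify = FALSE)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  ref_perms <- perms(seq_len(m))
  for (fi in idx_factors) {
    for (p in ref_perms) {
      p <- p[seq_len(nsel)]
      val <- sum(score[cbind(fi, p)])
      if (val > best_val + 1e-12) { best_val <- val; best <- list(fi = fi, p = p) }
    }
  }
  assign_vec <- rep(NA_integer_, k)
  assign_vec[best$fi] <- best$p
  assign_vec
}

#' Assign MCR factors to reference components
#'
#' Scores every (factor, reference) pair by the Pearson correlation between
#' the factor profile (working orientation) and the negated 2nd derivative
#' of the reference spectrum on the model's axis, then picks the injective
#' assignment maximizing the total score (exact optimum; ties broken by
#' lower factor index). Factors left without a reference are labelled
#' `"extra"`.
#'
#' @param model An `mcr_model` from [resolve()].
#' @param library A [reference_library()].
#' @param region Optional `c(lo, hi)` to restrict scoring; default the
#'   model's own region.
#' @param method `"optimal"` (exact assignment) or `"greedy"`.
#' @param sg_window,sg_poly Savitzky-Golay parameters used to derive the
#'   library's 2nd derivatives.
#' @return Data frame (`factor`, `component`, `score`) with the full score
#'   matrix as attribute `scores`.
#' @export
assign_factors <- function(model, library, region = NULL,
                           method = c("optimal", "greedy"),
                           sg_window = 15L, sg_poly = 3L) {
  method <- match.arg(method)
  if (length(library$entries) == 0L)
    stop("invalid-parameter: empty reference library", call. = FALSE)
  if (is.null(region)) region <- model$region
  refs <- library_second_derivative(library, sg_window, sg_poly, negate = TRUE)
  idx_model <- wn_window(model$axis, region[1], region[2], min_channels = 3L)
  score <- matrix(NA_real_, model$k, length(refs),
                  dimnames = list(NULL, names(refs)))
  for (j in seq_along(refs)) {
    r <- refs[[j]]
    ridx <- wn_window(r$axis, region[1], region[2], min_channels = 3L)
    # align by wavenumber (library and model may differ in axis extent)
    common <- intersect(round(r$axis[ridx], 6), round(model$axis[idx_model], 6))
    mi <- idx_model[match(common, round(model$axis[idx_model], 6))]
    li <- ridx[match(common, round(r$axis[ridx], 6))]
    for (f in seq_len(model$k))
      score[f, j] <- stats::cor(model$S[mi, f], r$intensities[li])
  }
  assign_vec <- solve_assignment(score, method)
  comp <- ifelse(is.na(assign_vec), "extra", colnames(score)[assign_vec])
  sc <- ifelse(is.na(assign_vec), NA_real_, score[cbind(seq_len(model$k), assign_vec)])
  out <- data.frame(factor = seq_len(model$k), component = comp, score = sc,
                    stringsAsFactors = FALSE)
  attr(out, "scores") <- score
  attr(out, "method") <- method
  out
}

#' C-O-S peak position of a profile
#'
#' Position of the maximum of a working-orientation profile inside the
#' sulfated-polysaccharide window (default 1100-1140 cm^-1), refined by
#' 3-point parabolic interpolation and reported to 0.1 cm^-1. The printed
#' PG1/PG2 shift (1126 vs 1124 cm^-1) equals the usual channel spacing, so
#' integer-channel argmax alone could not resolve it.
#'
#' @param profile An [ir_spectrum()] (bands positive), e.g. a column of an
#'   `mcr_model`'s `S` wrapped via `ir_spectrum(model$S[, j], model$axis, 2)`.
#' @param window `c(lo, hi)` search window in cm^-1.
#' @return Peak position in cm^-1.
#' @export
cos_peak_position <- function(profile, window = c(1100, 1140)) {
  idx <- wn_window(profile$axis, window[1], window[2], min_channels = 3L)
  ax <- profile$axis[idx]; y <- profile$intensities[idx]
  ord <- order(ax)
  ax <- ax[ord]; y <- y[ord]
  i <- which.max(y)
  if (i == 1L || i == length(y))
    stop("no-peak: no interior local maximum in window", call. = FALSE)
  # parabola through the three channels around the argmax
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  delta <- if (abs(denom) < .Machine$double.eps) 0 else
    0.5 * (y[i - 1] - y[i + 1]) / denom
  delta <- max(min(delta, 0.5), -0.5)
  pos <- ax[i] + delta * (ax[i + 1] - ax[i - 1]) / 2
  round(pos, 1)
}
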