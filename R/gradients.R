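# Width-normalized regional gradients: an area of interest (AoI) across the
# middle of the disc is averaged column-wise, the tissue width is rescaled to
# 0-100 %, and areas under the curve over fixed regional windows (aAF 10-20 %,
# NP 51-61 %, pAF 85-95 %) become the semi-quantitative per-sample parameters.

#' Area of interest across a disc section
#'
#' @param row_start First row of the block (1-based).
#' @param row_count Number of rows (default 10).
#' @return An `area_of_interest` list.
#' @export
area_of_interest <- function(row_start, row_count = 10L) {
  if (row_count < 1L) stop("invalid-parameter: row_count must be >= 1", call. = FALSE)
  structure(list(row_start = as.integer(row_start),
                 row_count = as.integer(row_count)),
            class = "area_of_interest")
}

#' Centre an AoI on the tissue-row centroid
#'
#' @param tissue Tissue map matrix (`NA` at non-tissue pixels).
#' @param row_count AoI height in rows.
#' @return An [area_of_interest()].
#' @export
centered_aoi <- function(tissue, row_count = 10L) {
  w <- rowSums(!is.na(tissue) & tissue > 0)
  if (sum(w) == 0) stop("degenerate-section: no tissue rows", call. = FALSE)
  centroid <- sum(seq_len(nrow(tissue)) * w) / sum(w)
  start <- as.integer(round(centroid - row_count / 2)) + 1L
  start <- max(1L, min(start, nrow(tissue) - row_count + 1L))
  area_of_interest(start, row_count)
}

#' Extract an AoI sub-grid
#'
#' @param map Numeric matrix (ratio or tissue map).
#' @param aoi An [area_of_interest()]; `NULL` centres a `row_count`-row block
#'   on the map's own tissue centroid.
#' @param row_count Height used when `aoi` is `NULL`.
#' @return The designated rows, all columns.
#' @export
extract_aoi <- function(map, aoi = NULL, row_count = 10L) {
  if (is.null(aoi)) aoi <- centered_aoi(map, row_count)
  rows <- aoi$row_start + seq_len(aoi$row_count) - 1L
  if (min(rows) < 1L || max(rows) > nrow(map))
    stop("invalid-parameter: AoI rows outside grid", call. = FALSE)
  map[rows, , drop = FALSE]
}

#' Width-normalized gradient profile
#'
#' Column-wise mean of the AoI (missing pixels ignored), tissue extent
#' detection (first/last column with at least `min_tissue_pixels` positive
#' tissue pixels), and linear interpolation onto the fixed 0-100 % IVD-width
#' axis (101 points, 1 % spacing).
#'
#' @param aoi_grid AoI sub-grid of the ratio (or abundance) map.
#' @param tissue_aoi_grid Matching AoI sub-grid of the tissue map.
#' @param component Component label carried in the result.
#' @param sample_id Sample identifier carried in the result.
#' @param min_tissue_pixels Column tissue criterion (default 3).
#' @return A `gradient_profile`: `percent` (0:100), `values`, `component`,
#'   `sample_id`, `width_cols`.
#' @export
width_normalized_profile <- function(aoi_grid, tissue_aoi_grid,
                                     component = NA_character_,
                                     sample_id = NA_character_,
                                     min_tissue_pixels = 3L) {
  if (!identical(dim(aoi_grid), dim(tissue_aoi_grid)))
    stop("incompatible-image: AoI grids differ in shape", call. = FALSE)
  tis_count <- colSums(!is.na(tissue_aoi_grid) & tissue_aoi_grid > 0)
  cols <- which(tis_count >= min_tissue_pixels)
  if (length(cols) < 3L)
    stop("degenerate-section: tissue extent below 3 columns", call. = FALSE)
  c1 <- min(cols); c2 <- max(cols)
  means <- colMeans(aoi_grid[, c1:c2, drop = FALSE], na.rm = TRUE)
  pct_src <- 100 * (seq(c1, c2) - c1) / (c2 - c1)
  ok <- is.finite(means)
  vals <- stats::approx(pct_src[ok], means[ok], xout = 0:100, rule = 2)$y
  structure(list(percent = 0:100, values = vals, component = component,
                 sample_id = sample_id, width_cols = c(c1, c2)),
            class = "gradient_profile")
}

#' Area under a gradient profile over a width window
#'
#' Trapezoidal area over `[lo_pct, hi_pct]` on the percent axis, in
#' (ratio x % width) units. Non-integer bounds are handled by linear
#' interpolation at the window edges, so adjacent windows are exactly
#' additive.
#'
#' @param profile A [width_normalized_profile()].
#' @param lo_pct,hi_pct Window in percent of IVD width, `0 <= lo < hi <= 100`.
#' @param region Optional region label carried in the result.
#' @return One-row data frame (`sample_id`, `region`, `component`, `value`).
#' @export
integrate_region <- function(profile, lo_pct, hi_pct, region = NA_character_) {
  if (lo_pct < 0 || hi_pct > 100 || lo_pct >= hi_pct)
    stop("invalid-parameter: need 0 <= lo < hi <= 100", call. = FALSE)
  x <- profile$percent; y <- profile$values
  inside <- which(x > lo_pct & x < hi_pct)
  if (any(!is.finite(y[x >= lo_pct & x <= hi_pct])))
    stop("missing-data: profile undefined inside window", call. = FALSE)
  f <- stats::approxfun(x, y)
  xs <- c(lo_pct, x[inside], hi_pct)
  ys <- c(f(lo_pct), y[inside], f(hi_pct))
  value <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  data.frame(sample_id = profile$sample_id, region = region,
             component = profile$component, value = value,
             stringsAsFactors = FALSE)
}

#' Cohort table of regional parameters
#'
#' Integrates every profile of every sample over the regional windows and
#' assembles the long-format cohort table, deterministically ordered by
#' sample, region and component.
#'
#' @param samples List of per-sample profile lists; each element is a named
#'   list of [width_normalized_profile()]s (names = components) and must
#'   carry distinct `sample_id`s.
#' @param windows Named list of percent windows (default [regional_windows()]).
#' @return Data frame (`sample_id`, `region`, `component`, `value`).
#' @export
regional_table <- function(samples, windows = regional_windows()) {
  rows <- list()
  for (s in samples) {
    for (prof in s) {
      for (reg in names(windows)) {
        w <- windows[[reg]]
        rows[[length(rows) + 1L]] <- integrate_region(prof, w[1], w[2], reg)
      }
    }
  }
  out <- do.call(rbind, rows)
  ids <- vapply(samples, function(s) s[[1]]$sample_id, character(1))
  if (anyDuplicated(ids))
    stop("incompatible-run: duplicate sample ids", call. = FALSE)
  out <- out[order(out$sample_id, out$region, out$component), , drop = FALSE]
  rownames(out) <- NULL
  out
}
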