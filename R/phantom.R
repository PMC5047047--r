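# Synthetic transflectance FTIR phantom of a sagittal IVD section.
#
# The phantom realises the statistical structure the analysis assumes: a
# bilinear Beer-Lambert mixture D = C* S*^T of reference component spectra on
# smooth anterior->posterior abundance gradients (collagen I maximal in the
# annulus fibrosus, collagen II and the proteoglycans maximal in the nucleus
# pulposus, paraffin everywhere), plus additive polynomial baselines,
# multiplicative intensity variation and white Gaussian noise. Non-tissue
# border pixels carry either paraffin-only spectra or bare baseline
# (substrate), reproducing both masking failure modes.

# run code with a private, seeded RNG stream; the caller's RNG is untouched
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Phantom configuration
#'
#' @param n_rows,n_cols Pixel grid (default 60 x 208, a typical single-section
#'   mosaic).
#' @param axis_lo,axis_hi,spacing Wavenumber axis parameters in cm^-1.
#' @param degeneration_level Degeneration severity `d` in `[0, 1]`: scales
#'   the nucleus PG1 abundance by `1 - 0.8 d` and PG2 by `0.2 + 0.8 d`.
#'   Default 0.5, the mildly degenerate state the enzymatic goat model
#'   induces.
#' @param pg_shift Planted PG2 C-O-S downshift in cm^-1 (default 2:
#'   1126 -> 1124).
#' @param noise_sigma Additive white-noise sigma in absorbance units.
#' @param baseline_order Per-pixel polynomial baseline order (-1 = none).
#' @param baseline_amplitude Scale of the random baseline coefficients.
#' @param multiplicative_range Per-pixel multiplicative factor range
#'   (default `c(1, 1)`: the phantom mixing model is bilinear plus baseline
#'   plus noise; add gain variation via [add_distortions()] if wanted).
#' @param border_rows,border_cols Non-tissue frame thickness.
#' @param substrate_cols Outermost columns per side that are substrate-only
#'   (bare baseline); the rest of the frame is paraffin-only.
#' @param components Components mixed into the tissue (default the five the
#'   standard model resolves; add `"elastin"` for a six-component phantom).
#' @param seed Integer RNG seed; the generator is bit-reproducible given it.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(n_rows = 60L, n_cols = 208L,
                           axis_lo = 900, axis_hi = 1800, spacing = 2,
                           degeneration_level = 0.5, pg_shift = 2,
                           noise_sigma = 0.005, baseline_order = 2L,
                           baseline_amplitude = 0.05,
                           multiplicative_range = c(1, 1),
                           border_rows = 4L, border_cols = 8L,
                           substrate_cols = 2L,
                           components = c("collagen_I", "collagen_II",
                                          "PG1", "PG2", "paraffin"),
                           seed = 1L) {
  if (degeneration_level < 0 || degeneration_level > 1)
    stop("invalid-parameter: degeneration_level must be in [0, 1]", call. = FALSE)
  if (spacing <= 0) stop("invalid-parameter: spacing must be > 0", call. = FALSE)
  if (noise_sigma < 0) stop("invalid-parameter: noise_sigma must be >= 0", call. = FALSE)
  if (substrate_cols > border_cols)
    stop("invalid-parameter: substrate_cols cannot exceed border_cols", call. = FALSE)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 axis_lo = axis_lo, axis_hi = axis_hi, spacing = spacing,
                 degeneration_level = degeneration_level, pg_shift = pg_shift,
                 noise_sigma = noise_sigma,
                 baseline_order = as.integer(baseline_order),
                 baseline_amplitude = baseline_amplitude,
                 multiplicative_range = multiplicative_range,
                 border_rows = as.integer(border_rows),
                 border_cols = as.integer(border_cols),
                 substrate_cols = as.integer(substrate_cols),
                 components = components, seed = as.integer(seed)),
            class = "phantom_config")
}

# Smooth anterior->posterior abundance profiles on the normalized width
# t in [0,1] (0 = anterior edge). d = degeneration level.
ivd_profile <- function(component, t, d = 0) {
  switch(component,
    # annulus collagen I: maximal at both AF margins, absent in the NP centre
    collagen_I  = (2 * t - 1)^4,
    # collagen II occupies NP and inner AF as a broad plateau, absent at the margins
    collagen_II = sqrt(pmax(0, 1 - (2 * t - 1)^2)),
    # native PG population: narrow NP-core peak (the healthy NP is
    # PG-dominated, roughly 2:1 over collagen by dry weight), lost with
    # degeneration
    PG1         = 2.0 * (1 - 0.8 * d) * exp(-(t - 0.50)^2 / (2 * 0.12^2)),
    # altered PG population: posterior NP / inner pAF, distinct from the
    # native NP-core pool, gained with degeneration
    PG2         = 1.8 * (0.2 + 0.8 * d) * exp(-(t - 0.70)^2 / (2 * 0.12^2)),
    elastin     = 0.75 * abs(2 * t - 1)^3,
    # embedding paraffin: present throughout at unit mean; its spatial
    # texture in a generated phantom is an independent smooth random field
    # (infiltration/section-thickness variation), see generate_phantom()
    paraffin    = rep(1, length(t)),
    stop("invalid-parameter: unknown component ", component, call. = FALSE))
}

# Smooth seeded random field in [0, 1] on an nr x nc grid: a low-order
# 2-D cosine expansion, emulating embedding/section-thickness texture.
smooth_field <- function(nr, nc, order = 2L) {
  rf <- (seq_len(nr) - 1) / max(1, nr - 1)
  cf <- (seq_len(nc) - 1) / max(1, nc - 1)
  f <- matrix(0, nr, nc)
  for (i in 0:order) for (j in 0:order) {
    if (i == 0 && j == 0) next
    f <- f + stats::rnorm(1, 0, 1 / (1 + i + j)) *
      outer(cos(pi * i * rf + stats::runif(1, 0, 2 * pi) * (i > 0)),
            cos(pi * j * cf + stats::runif(1, 0, 2 * pi) * (j > 0)))
  }
  rng <- range(f)
  if (diff(rng) < .Machine$double.eps) return(matrix(0.5, nr, nc))
  (f - rng[1]) / diff(rng)
}

# Axial (row) thickness modulation of the section, peaked mid-section.
ivd_row_factor <- function(rfrac) 0.85 + 0.30 * exp(-(rfrac - 0.5)^2 / (2 * 0.25^2))

#' Generate a synthetic IVD phantom
#'
#' @param config A [phantom_config()].
#' @param library A [reference_library()]; defaults to [default_library()] on
#'   the configured axis.
#' @return List with elements
#'   `image` (absorbance [hyper_image()]),
#'   `ground_truth` (`phantom_truth`: `true_concentrations` array with
#'   component names, `tissue_mask`, `width_extent`, and
#'   `regional_true_abundance`), and
#'   `covariates` (per-region covariate table, see [simulate_cohort()]).
#' @export
generate_phantom <- function(config, library = NULL) {
  ax <- wn_axis(config$axis_lo, config$axis_hi, config$spacing)
  if (is.null(library)) library <- default_library(ax, pg_shift = config$pg_shift)
  if (!isTRUE(all.equal(library$axis, ax)))
    stop("invalid-parameter: library axis does not match config axis", call. = FALSE)
  comps <- config$components
  if (!all(comps %in% names(library$entries)))
    stop("invalid-parameter: components missing from library", call. = FALSE)

  nr <- config$n_rows; nc <- config$n_cols
  d  <- config$degeneration_level
  tis_rows <- (config$border_rows + 1L):(nr - config$border_rows)
  ct1 <- config$border_cols + 1L; ct2 <- nc - config$border_cols
  tvals <- (seq(ct1, ct2) - ct1) / (ct2 - ct1)
  rfrac <- (tis_rows - min(tis_rows)) / max(1L, diff(range(tis_rows)))
  rowfac <- ivd_row_factor(rfrac)

  Cstar <- array(0, dim = c(nr, nc, length(comps)),
                 dimnames = list(NULL, NULL, comps))
  tissue <- matrix(FALSE, nr, nc)
  tissue[tis_rows, ct1:ct2] <- TRUE
  # every component carries an independent smooth spatial texture on top of
  # its width profile (AF lamellae, cell clusters, PG granules, paraffin
  # infiltration) — the within-section heterogeneity real stains show
  texture <- with_seed(config$seed + 77L,
    lapply(seq_along(comps), function(j)
      smooth_field(length(tis_rows), length(tvals), order = 4L)))
  for (j in seq_along(comps)) {
    prof <- ivd_profile(comps[j], tvals, d)
    tex <- 0.70 + 0.60 * texture[[j]]
    if (comps[j] == "paraffin") {
      # infiltration spans near-zero (dense matrix excludes wax) to full
      tex_par <- 0.10 + 1.20 * texture[[j]]
      Cstar[tis_rows, ct1:ct2, j] <- tex_par * outer(rep(1, length(tis_rows)), prof)
    } else {
      Cstar[tis_rows, ct1:ct2, j] <- tex * outer(rowfac, prof)
    }
  }
  # non-tissue frame: paraffin-only except the outer substrate-only columns
  sub_cols <- c(seq_len(config$substrate_cols),
                nc - seq_len(config$substrate_cols) + 1L)
  if ("paraffin" %in% comps) {
    par_only <- !tissue
    par_only[, sub_cols] <- FALSE
    Cstar[, , "paraffin"][par_only] <- 1.3
  }

  S <- vapply(comps, function(nm) library$entries[[nm]]$intensities,
              numeric(length(ax)))
  D <- matrix(Cstar, nrow = nr * nc)          # column-major pixel order is
  D <- D %*% t(S)                             # irrelevant here: reshaped back
  cube <- array(D, dim = c(nr, nc, length(ax)))
  img <- hyper_image(cube, ax, 0L)
  img <- add_distortions(img, baseline_order = config$baseline_order,
                         baseline_amplitude = config$baseline_amplitude,
                         multiplicative_range = config$multiplicative_range,
                         noise_sigma = config$noise_sigma, seed = config$seed)

  regional <- grid_regional_truth(Cstar, comps, tis_rows, ct1, ct2)
  gt <- structure(list(true_concentrations = Cstar, components = comps,
                       tissue_mask = tissue, width_extent = c(ct1, ct2),
                       regional_true_abundance = regional, config = config),
                  class = "phantom_truth")
  cov <- with_seed(config$seed + 101L,
                   phantom_covariates(regional, d, sample_id = "phantom_1"))
  list(image = img, ground_truth = gt, covariates = cov)
}

# Region windows as percent of IVD width (pAF Methods alternative 85-100
# available via regional_windows(paf_to_100 = TRUE)).

#' Default regional windows (% of IVD width)
#' @param paf_to_100 Use the 85-100 % posterior-annulus window variant.
#' @return Named list of `c(lo, hi)` percent windows.
#' @export
regional_windows <- function(paf_to_100 = FALSE) {
  list(aAF = c(10, 20), NP = c(51, 61),
       pAF = if (paf_to_100) c(85, 100) else c(85, 95))
}

# Mean true abundance per component over each regional window, from the
# generated concentration grids (tissue rows, columns mapped to % width).
grid_regional_truth <- function(Cstar, comps, tis_rows, ct1, ct2,
                                windows = regional_windows()) {
  pct <- 100 * (seq(ct1, ct2) - ct1) / (ct2 - ct1)
  out <- expand.grid(region = names(windows), component = comps,
                     stringsAsFactors = FALSE)
  out$true_abundance <- mapply(function(reg, comp) {
    w <- windows[[reg]]
    cols <- seq(ct1, ct2)[pct >= w[1] & pct <= w[2]]
    mean(Cstar[tis_rows, cols, comp])
  }, out$region, out$component)
  out[order(out$region, out$component), , drop = FALSE]
}

# Mean true abundance of each component over each regional window, computed
# from the analytic width profiles (row modulation is a common factor and
# cancels in region contrasts).
phantom_regional_truth <- function(comps, d, windows = regional_windows()) {
  out <- expand.grid(region = names(windows), component = comps,
                     stringsAsFactors = FALSE)
  out$true_abundance <- mapply(function(reg, comp) {
    w <- windows[[reg]]
    tt <- seq(w[1] / 100, w[2] / 100, length.out = 201)
    mean(ivd_profile(comp, tt, d))
  }, out$region, out$component)
  out[order(out$region, out$component), , drop = FALSE]
}

# Covariates as monotone functions of true NP abundances plus seeded noise.
# Caller provides the RNG state.
phantom_covariates <- function(regional, d, sample_id,
                               t2_echoes = c(5.7, 10.9, 16.05, 21.2, 26.4)) {
  regs <- unique(regional$region)
  grade <- as.integer(round(6 * d))
  rows <- lapply(regs, function(reg) {
    a1 <- regional$true_abundance[regional$region == reg &
                                    regional$component == "PG1"]
    c1 <- regional$true_abundance[regional$region == reg &
                                    regional$component == "collagen_I"]
    gag <- max(0, 10 + 80 * a1 + stats::rnorm(1, 0, 2))
    hyp <- max(0, 25 + 30 * c1 + stats::rnorm(1, 0, 2))
    t2_true <- 12 + 28 * a1
    train <- 600 * exp(-t2_echoes / t2_true) *
      exp(stats::rnorm(length(t2_echoes), 0, 0.02))
    t2 <- t2star_fit(t2_echoes, train)$t2star_ms
    data.frame(sample_id = sample_id, region = reg, grade = grade,
               gag_ug_per_mg = gag, hyp_ug_per_mg = hyp, t2star_ms = t2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Add measurement distortions to an absorbance image
#'
#' Per-pixel random polynomial baseline, per-pixel multiplicative factor
#' drawn uniformly from `multiplicative_range`, and additive white Gaussian
#' noise. Deterministic given `seed`.
#'
#' @param image Absorbance [hyper_image()] (`derivative_order = 0`).
#' @param baseline_order Polynomial order (-1 disables the baseline).
#' @param baseline_amplitude Standard deviation scale of the coefficients.
#' @param multiplicative_range Length-2 range of the gain factor.
#' @param noise_sigma Gaussian noise sigma (>= 0).
#' @param seed Integer seed.
#' @return Distorted `hyper_image`.
#' @export
add_distortions <- function(image, baseline_order = 2L, baseline_amplitude = 0.05,
                            multiplicative_range = c(0.9, 1.1),
                            noise_sigma = 0.01, seed = 1L) {
  if (image$derivative_order != 0L)
    stop("invalid-parameter: distortions apply to absorbance data", call. = FALSE)
  if (noise_sigma < 0)
    stop("invalid-parameter: noise_sigma must be >= 0", call. = FALSE)
  nr <- n_rows(image); nc <- n_cols(image); nch <- length(image$axis)
  npx <- nr * nc
  with_seed(seed, {
    D <- matrix(image$cube, nrow = npx)        # (r,c) column-major; consistent
    if (!isTRUE(all.equal(multiplicative_range, c(1, 1)))) {
      g <- stats::runif(npx, multiplicative_range[1], multiplicative_range[2])
      D <- D * g
    }
    if (baseline_order >= 0L) {
      u <- seq(-1, 1, length.out = nch)
      U <- t(vapply(0:baseline_order, function(p) u^p, numeric(nch)))
      cf <- matrix(stats::rnorm(npx * (baseline_order + 1L), 0,
                                baseline_amplitude / (seq_len(baseline_order + 1L))),
                   nrow = npx, byrow = TRUE)
      D <- D + cf %*% U
    }
    if (noise_sigma > 0) D <- D + stats::rnorm(length(D), 0, noise_sigma)
    hyper_image(array(D, dim = c(nr, nc, nch)), image$axis, 0L,
                image$pixel_size_um)
  })
}

#' Simulate a cohort of phantom samples with matched covariates
#'
#' Generates per-sample ground-truth regional abundances from the analytic
#' width profiles (no cubes are synthesised) together with degeneration
#' covariates: GAG and hydroxyproline as affine functions of the true NP
#' abundances plus Gaussian noise calibrated to a signal-to-noise ratio
#' `snr` across the cohort, T2* obtained by fitting a noisy synthetic echo
#' train with [t2star_fit()], and an ordinal grade (0-6) from quantile
#' binning of inverse PG1 abundance.
#'
#' @param n Number of samples.
#' @param degeneration_levels Vector of length `n` in `[0, 1]` (default
#'   evenly spaced 0..1).
#' @param snr Cohort signal-to-noise ratio of the planted GAG association
#'   (sd of the planted affine part over sd of the added noise; default 3).
#' @param seed Integer seed.
#' @param components Components carried in the truth table.
#' @return List with `regional` (long table: sample_id, region, component,
#'   value = true abundance) and `covariates` (one row per sample x region).
#' @export
simulate_cohort <- function(n = 40L, degeneration_levels = NULL, snr = 3,
                            seed = 1L,
                            components = c("collagen_I", "collagen_II",
                                           "PG1", "PG2", "paraffin")) {
  if (n < 3L) stop("invalid-parameter: need n >= 3", call. = FALSE)
  if (is.null(degeneration_levels))
    degeneration_levels <- seq(0, 1, length.out = n)
  if (length(degeneration_levels) != n)
    stop("invalid-parameter: degeneration_levels must have length n", call. = FALSE)
  ids <- sprintf("S%03d", seq_len(n))
  with_seed(seed, {
    reg_list <- lapply(seq_len(n), function(i) {
      rt <- phantom_regional_truth(components, degeneration_levels[i])
      # small sample-to-sample biological variability
      rt$true_abundance <- pmax(0, rt$true_abundance *
                                  exp(stats::rnorm(nrow(rt), 0, 0.03)))
      rt$sample_id <- ids[i]
      rt
    })
    regional <- do.call(rbind, reg_list)
    np_pg1 <- vapply(reg_list, function(rt)
      rt$true_abundance[rt$region == "NP" & rt$component == "PG1"], numeric(1))
    np_col1 <- vapply(reg_list, function(rt)
      rt$true_abundance[rt$region == "NP" & rt$component == "collagen_I"],
      numeric(1))
    cov_rows <- lapply(seq_len(n), function(i) {
      rt <- reg_list[[i]]
      rows <- lapply(unique(rt$region), function(reg) {
        a1 <- rt$true_abundance[rt$region == reg & rt$component == "PG1"]
        c1 <- rt$true_abundance[rt$region == reg & rt$component == "collagen_I"]
        sig_g <- 80 * a1
        gag <- max(0, 10 + sig_g + stats::rnorm(1, 0, stats::sd(80 * np_pg1) / snr))
        hyp <- max(0, 25 + 30 * c1 +
                     stats::rnorm(1, 0, stats::sd(30 * np_col1) / snr))
        t2_true <- 12 + 28 * a1
        te <- c(5.7, 10.9, 16.05, 21.2, 26.4)
        train <- 600 * exp(-te / t2_true) * exp(stats::rnorm(5, 0, 0.02))
        data.frame(sample_id = ids[i], region = reg,
                   gag_ug_per_mg = gag, hyp_ug_per_mg = hyp,
                   t2star_ms = t2star_fit(te, train)$t2star_ms,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
    covariates <- do.call(rbind, cov_rows)
    # ordinal grade: quantile binning of inverse NP PG1 abundance into 0..6
    inv <- -np_pg1
    qs <- stats::quantile(inv, probs = seq(0, 1, length.out = 8), type = 7)
    grade <- as.integer(cut(inv, breaks = unique(qs), include.lowest = TRUE,
                            labels = FALSE)) - 1L
    # guard against degenerate quantiles collapsing bins
    grade <- pmin(pmax(grade, 0L), 6L)
    covariates$grade <- grade[match(covariates$sample_id, ids)]
    covariates <- covariates[, c("sample_id", "region", "grade",
                                 "gag_ug_per_mg", "hyp_ug_per_mg", "t2star_ms")]
    regional <- regional[, c("sample_id", "region", "component", "true_abundance")]
    names(regional)[4] <- "value"
    rownames(regional) <- rownames(covariates) <- NULL
    list(regional = regional, covariates = covariates,
         degeneration_levels = degeneration_levels)
  })
}
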