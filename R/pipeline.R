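# End-to-end orchestration: simulate -> preprocess -> decompose -> maps ->
# gradients -> correlate, with every printed acquisition/analysis setting
# gathered in one validated configuration object.

#' Analysis configuration
#'
#' Collects every tunable of the pipeline with the standard defaults:
#' Savitzky-Golay window 15 / order 3 / 2nd derivative, mask marker
#' 1554 cm^-1 at threshold 0, MCR region 950-1300 cm^-1 with 5 factors,
#' amide III window 1186-1297 cm^-1, 10-row AoI, regional windows
#' aAF 10-20 % / NP 51-61 % / pAF 85-95 %, per-test alpha 0.05.
#'
#' @param n_samples Cohort size simulated by [run_pipeline()].
#' @param degeneration_levels Optional vector of per-sample severities.
#' @param n_rows,n_cols,noise_sigma Phantom geometry/noise (see
#'   [phantom_config()]).
#' @param sg_window,sg_poly Savitzky-Golay parameters.
#' @param mask_marker,mask_threshold Masking parameters.
#' @param mcr_region,k,init_method,constraint_alpha,max_iter,tol MCR
#'   parameters ([resolve()]; `k` may be a vector, e.g. `4:6`).
#' @param amide3_window Tissue-map window in cm^-1.
#' @param aoi_rows AoI height in rows.
#' @param windows Regional percent windows ([regional_windows()]).
#' @param alpha Significance level for associations.
#' @param pairs Association pairs (data frame `component`, `covariate`,
#'   `region`); `NULL` for the default PG/collagen panel.
#' @param covariates_path Optional CSV of external covariates; when set it
#'   must exist, and replaces the simulated covariates.
#' @param seed Master seed; all per-sample seeds derive from it.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(n_samples = 2L, degeneration_levels = NULL,
                            n_rows = 60L, n_cols = 208L, noise_sigma = 0.005,
                            sg_window = 15L, sg_poly = 3L,
                            mask_marker = 1554, mask_threshold = 0,
                            mcr_region = c(950, 1300), k = 5L,
                            init_method = "nipals", constraint_alpha = 0.5,
                            max_iter = 500L, tol = 1e-6,
                            amide3_window = c(1186, 1297), aoi_rows = 10L,
                            windows = regional_windows(), alpha = 0.05,
                            pairs = NULL, covariates_path = NULL, seed = 1L) {
  if (is.null(degeneration_levels))
    degeneration_levels <- if (n_samples == 1L) 0 else
      seq(0, 1, length.out = n_samples)
  if (length(degeneration_levels) != n_samples)
    stop("invalid-parameter: degeneration_levels must match n_samples", call. = FALSE)
  if (is.null(pairs))
    pairs <- expand.grid(component = c("PG1", "PG2"),
                         covariate = c("gag_ug_per_mg", "grade", "t2star_ms"),
                         region = "NP", stringsAsFactors = FALSE)
  structure(list(n_samples = as.integer(n_samples),
                 degeneration_levels = degeneration_levels,
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 noise_sigma = noise_sigma,
                 sg_window = as.integer(sg_window), sg_poly = as.integer(sg_poly),
                 mask_marker = mask_marker, mask_threshold = mask_threshold,
                 mcr_region = mcr_region, k = k, init_method = init_method,
                 constraint_alpha = constraint_alpha,
                 max_iter = as.integer(max_iter), tol = tol,
                 amide3_window = amide3_window, aoi_rows = as.integer(aoi_rows),
                 windows = windows, alpha = alpha, pairs = pairs,
                 covariates_path = covariates_path, seed = as.integer(seed)),
            class = "analysis_config")
}

stage_fail <- function(stage, sample_id, msg) {
  stop(sprintf("stage %s [%s]: %s", stage, sample_id, msg), call. = FALSE)
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Executes simulate, preprocess (2nd derivative + mask), decompose
#' (MCR-ALS), maps (factor assignment, tissue and ratio maps), gradients
#' (width-normalized profiles and regional parameters) and correlate.
#' Deterministic: two runs with the same configuration give identical
#' numerical outputs.
#'
#' @param config An [analysis_config()].
#' @return A `run_manifest`: `stages` (per-stage summaries), `config`,
#'   `assignments`, `regional` (cohort regional-parameter table),
#'   `covariates` and `associations`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  stages <- list()
  ids <- sprintf("S%02d", seq_len(config$n_samples))

  # -- simulate ---------------------------------------------------------------
  sims <- lapply(seq_len(config$n_samples), function(i) {
    cfg <- phantom_config(n_rows = config$n_rows, n_cols = config$n_cols,
                          degeneration_level = config$degeneration_levels[i],
                          noise_sigma = config$noise_sigma,
                          seed = config$seed + 1000L * i)
    ph <- generate_phantom(cfg)
    ph$covariates$sample_id <- ids[i]
    ph
  })
  stages$simulate <- list(n_samples = length(sims),
                          grid = c(config$n_rows, config$n_cols))

  # -- preprocess -------------------------------------------------------------
  prep <- lapply(seq_along(sims), function(i) {
    d2 <- second_derivative(sims[[i]]$image, config$sg_window, config$sg_poly)
    mask <- tryCatch(compute_mask(d2, config$mask_marker, config$mask_threshold),
                     error = function(e) stage_fail("preprocess", ids[i],
                                                    conditionMessage(e)))
    list(d2 = d2, mask = mask)
  })
  stages$preprocess <- list(pixels_retained =
                              vapply(prep, function(p) sum(p$mask), integer(1)))

  # -- decompose --------------------------------------------------------------
  models <- lapply(seq_along(prep), function(i) {
    tryCatch(resolve(prep[[i]]$d2, prep[[i]]$mask, k = config$k,
                     region = config$mcr_region,
                     init_method = config$init_method,
                     constraints = mcr_constraints(config$constraint_alpha),
                     max_iter = config$max_iter, tol = config$tol),
             error = function(e) stage_fail("decompose", ids[i],
                                            conditionMessage(e)))
  })
  first_model <- function(m) if (inherits(m, "mcr_model")) m else m[[1]]
  stages$decompose <- list(
    k = config$k,
    lack_of_fit = vapply(models, function(m)
      utils::tail(first_model(m)$lof_history, 1), numeric(1)))

  # -- maps -------------------------------------------------------------------
  lib <- default_library(wn_axis(900, 1800, 2))
  persample <- lapply(seq_along(models), function(i) {
    m <- first_model(models[[i]])
    asg <- assign_factors(m, lib)
    tmap <- tissue_map(prep[[i]]$d2, prep[[i]]$mask,
                       config$amide3_window[1], config$amide3_window[2])
    comps <- asg$component[asg$component != "extra"]
    rmaps <- lapply(stats::setNames(asg$factor[asg$component != "extra"], comps),
                    function(f) ratio_map(component_map(m, f), tmap))
    list(assignment = asg, tissue = tmap, ratio_maps = rmaps)
  })
  stages$maps <- list(assigned = lapply(persample, function(p)
    p$assignment$component))

  # -- gradients --------------------------------------------------------------
  samples <- lapply(seq_along(persample), function(i) {
    p <- persample[[i]]
    aoi <- centered_aoi(p$tissue, config$aoi_rows)
    t_aoi <- extract_aoi(p$tissue, aoi)
    profs <- lapply(names(p$ratio_maps), function(comp) {
      width_normalized_profile(extract_aoi(p$ratio_maps[[comp]], aoi), t_aoi,
                               component = comp, sample_id = ids[i])
    })
    stats::setNames(profs, names(p$ratio_maps))
  })
  regional <- regional_table(samples, config$windows)
  stages$gradients <- list(n_profiles = sum(lengths(samples)),
                           n_rows = nrow(regional))

  # -- correlate --------------------------------------------------------------
  covariates <- do.call(rbind, lapply(sims, `[[`, "covariates"))
  if (!is.null(config$covariates_path)) {
    if (!file.exists(config$covariates_path))
      stage_fail("correlate", "cohort",
                 paste("covariate file not found:", config$covariates_path))
    covariates <- read_covariates(config$covariates_path)
  }
  associations <- NULL
  if (config$n_samples >= 5L) {
    associations <- tryCatch(
      correlate_cohort(regional, covariates, config$pairs, config$alpha),
      error = function(e) stage_fail("correlate", "cohort", conditionMessage(e)))
    stages$correlate <- list(n_tests = nrow(associations),
                             n_significant = sum(associations$significant))
  } else {
    stages$correlate <- list(status = "insufficient-samples",
                             n_samples = config$n_samples)
  }

  structure(list(stages = stages, config = config,
                 assignments = lapply(persample, `[[`, "assignment"),
                 regional = regional, covariates = covariates,
                 associations = associations),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>", length(x$stages), "stages:",
      paste(names(x$stages), collapse = " -> "), "\n")
  invisible(x)
}
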