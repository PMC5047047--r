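# Non-parametric association of regional spectroscopic parameters with
# degeneration covariates (Theil-Sen slope + Kendall rank test), and the
# log-linear T2* relaxometry fit that produces the MRI covariate.

#' Mono-exponential T2* fit by log-linear least squares
#'
#' Ordinary least squares of `log(I)` on the echo time; `T2* = -1/slope`.
#'
#' @param echo_times_ms Echo times in ms (>= 2 values).
#' @param intensities Positive signal intensities, same length.
#' @return List with `t2star_ms` and `i0` (back-extrapolated intensity).
#' @examples
#' te <- c(5.7, 10.9, 16.05, 21.2, 26.4)
#' t2star_fit(te, 100 * exp(-te / 20))$t2star_ms   # 20
#' @export
t2star_fit <- function(echo_times_ms, intensities) {
  if (length(echo_times_ms) < 2L || length(intensities) != length(echo_times_ms))
    stop("invalid-input: need >= 2 paired echoes", call. = FALSE)
  if (any(!is.finite(intensities)) || any(intensities <= 0))
    stop("invalid-input: intensities must be positive", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, echo_times_ms), log(intensities))
  slope <- fit$coefficients[2]
  if (!is.finite(slope) || slope >= 0)
    stop("no-decay: non-decaying signal", call. = FALSE)
  list(t2star_ms = unname(-1 / slope), i0 = unname(exp(fit$coefficients[1])))
}

# Mahonian (inversion-count) null distribution of Kendall's S for n
# distinct observations: counts[j] = number of permutations with j
# inversions; S = n(n-1)/2 - 2j.
mahonian_counts <- function(n) {
  cnt <- 1
  for (i in 2:n) {                      # multiply by 1 + q + ... + q^(i-1)
    new <- numeric(length(cnt) + i - 1)
    for (s in 0:(i - 1))
      new[seq_along(cnt) + s] <- new[seq_along(cnt) + s] + cnt
    cnt <- new
  }
  cnt
}

#' Kendall rank-correlation test (tau-b)
#'
#' Exact two-sided p-value from the permutation (Mahonian) null for
#' `n <= 10` without ties; otherwise the normal approximation with
#' continuity correction and the standard tie-corrected variance of `S`.
#'
#' @param x,y Paired numeric vectors.
#' @param exact Force (`TRUE`) or suppress (`FALSE`) the exact null;
#'   `NULL` (default) chooses it automatically for `n <= 10` without ties.
#' @return List with `tau` (tau-b), `S`, `p_value`, `n`, `method`.
#' @export
kendall_test <- function(x, y, exact = NULL) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("degenerate-data: need n >= 3", call. = FALSE)
  dx <- sign(outer(x, x, "-")); dy <- sign(outer(y, y, "-"))
  S <- sum(dx[upper.tri(dx)] * dy[upper.tri(dy)])
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  Tx <- sum(tx * (tx - 1) / 2); Ty <- sum(ty * (ty - 1) / 2)
  denom <- sqrt((n0 - Tx) * (n0 - Ty))
  if (denom == 0) stop("degenerate-data: constant x or y", call. = FALSE)
  tau <- S / denom
  has_ties <- Tx > 0 || Ty > 0
  use_exact <- if (is.null(exact)) !has_ties && n <= 10L else isTRUE(exact)
  if (use_exact && has_ties)
    stop("invalid-parameter: exact null requires tie-free data", call. = FALSE)
  if (use_exact) {
    cnt <- mahonian_counts(n)
    svals <- n0 - 2 * (seq_along(cnt) - 1)
    p <- sum(cnt[abs(svals) >= abs(S)]) / sum(cnt)
    method <- "exact"
  } else {
    t1 <- sum(tx * (tx - 1) * (2 * tx + 5)); t2 <- sum(ty * (ty - 1) * (2 * ty + 5))
    v0 <- n * (n - 1) * (2 * n + 5)
    v1 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
    v2 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    varS <- (v0 - t1 - t2) / 18 + v1 + v2
    z <- (S - sign(S)) / sqrt(varS)       # continuity correction
    if (S == 0) z <- 0
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(tau = tau, S = S, p_value = p, n = n, method = method)
}

#' Theil-Sen slope and intercept
#'
#' Slope = median of all pairwise slopes (pairs with equal `x` skipped);
#' intercept = median of `y - slope * x`.
#'
#' @param x,y Paired numeric vectors.
#' @return List with `slope` and `intercept`.
#' @export
theil_sen <- function(x, y) {
  n <- length(x)
  if (n < 2L || length(y) != n)
    stop("degenerate-data: need >= 2 paired points", call. = FALSE)
  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  keep <- dx != 0
  if (!any(keep)) stop("degenerate-data: constant x", call. = FALSE)
  slope <- stats::median(dy[keep] / dx[keep])
  list(slope = slope, intercept = stats::median(y - slope * x))
}

#' Non-parametric linear regression
#'
#' The Theil-Sen slope/intercept with significance from the two-sided
#' Kendall rank-correlation test ([kendall_test()]).
#'
#' @param x,y Paired numeric vectors, `n >= 5`.
#' @param alpha Significance level (default 0.05).
#' @param x_label,y_label,region Labels carried into the result.
#' @return One-row data frame: `x`, `y`, `region`, `n`, `slope`,
#'   `intercept`, `kendall_tau`, `p_value`, `significant`.
#' @export
nonparametric_regression <- function(x, y, alpha = 0.05,
                                     x_label = "x", y_label = "y",
                                     region = NA_character_) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 5L) stop("degenerate-data: need n >= 5", call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("degenerate-data: constant x or y", call. = FALSE)
  ts <- theil_sen(x, y)
  kt <- kendall_test(x, y)
  data.frame(x = x_label, y = y_label, region = region, n = kt$n,
             slope = ts$slope, intercept = ts$intercept,
             kendall_tau = kt$tau, p_value = kt$p_value,
             significant = kt$p_value <= alpha, stringsAsFactors = FALSE)
}

#' Correlate regional spectroscopic parameters with covariates
#'
#' Joins the regional-parameter table with the covariate table on
#' `(sample_id, region)` and runs [nonparametric_regression()] for each
#' requested (component, covariate, region) pair. No multiplicity
#' adjustment is applied by default; set `p_adjust = "BH"` for
#' Benjamini-Hochberg across the requested pairs.
#'
#' @param regional Data frame (`sample_id`, `region`, `component`, `value`).
#' @param covariates Data frame with `sample_id`, `region` and covariate
#'   columns (`grade`, `gag_ug_per_mg`, `hyp_ug_per_mg`, `t2star_ms`).
#' @param pairs Data frame with columns `component`, `covariate`, `region`.
#' @param alpha Significance level.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return Data frame of association results, one row per pair.
#' @export
correlate_cohort <- function(regional, covariates, pairs, alpha = 0.05,
                             p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (anyDuplicated(regional[, c("sample_id", "region", "component")]))
    stop("incompatible-tables: duplicate (sample, region, component) rows",
         call. = FALSE)
  if (anyDuplicated(covariates[, c("sample_id", "region")]))
    stop("incompatible-tables: duplicate (sample, region) covariate rows",
         call. = FALSE)
  out <- list()
  dropped <- 0L
  for (i in seq_len(nrow(pairs))) {
    comp <- pairs$component[i]; covn <- pairs$covariate[i]; reg <- pairs$region[i]
    rsub <- regional[regional$component == comp & regional$region == reg, ]
    csub <- covariates[covariates$region == reg, ]
    m <- merge(rsub, csub, by = c("sample_id", "region"))
    if (nrow(m) < 5L || !covn %in% names(m)) { dropped <- dropped + 1L; next }
    out[[length(out) + 1L]] <-
      nonparametric_regression(m$value, m[[covn]], alpha,
                               x_label = comp, y_label = covn, region = reg)
  }
  if (!length(out))
    stop("incompatible-tables: empty join for every requested pair", call. = FALSE)
  res <- do.call(rbind, out)
  if (dropped > 0L) message("correlate_cohort: dropped ", dropped, " pair(s)")
  if (p_adjust == "BH") {
    res$p_value <- stats::p.adjust(res$p_value, method = "BH")
    res$significant <- res$p_value <= alpha
  }
  rownames(res) <- NULL
  res
}
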