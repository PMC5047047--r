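# Multivariate curve resolution by alternating least squares.
#
# The bilinear model D ~ C S^T is fitted to the (negated) second-derivative
# pixel matrix: abstract factors from NIPALS (or a truncated SVD) seed an
# alternating sequence of ordinary least-squares half-steps, each followed by
# a soft non-negativity operator X <- (1-alpha) X + alpha max(X, 0). Spectral
# profiles are kept unit-norm with the largest-magnitude lobe positive, so
# the concentration matrix carries all magnitude.

#' NIPALS factor extraction
#'
#' Sequentially extracts `k` rank-1 terms by the NIPALS power iteration with
#' deflation. No mean-centring is applied: the bilinear Beer-Lambert
#' structure of the data is preserved. Loadings are unit-norm.
#'
#' @param D Numeric matrix (pixels x channels).
#' @param k Number of factors, `1 <= k <= min(dim(D))`.
#' @param tol Relative convergence tolerance of the inner power iteration.
#' @param max_inner_iter Cap on inner iterations per factor.
#' @return List with `scores` (n x k) and `loadings` (m x k).
#' @export
nipals_decompose <- function(D, k, tol = 1e-10, max_inner_iter = 500L) {
  D <- as.matrix(D)
  if (!all(is.finite(D))) stop("invalid-parameter: D must be finite", call. = FALSE)
  if (k < 1L || k > min(dim(D)))
    stop("invalid-parameter: k must be in 1..min(dim(D))", call. = FALSE)
  E <- D
  scores <- matrix(0, nrow(D), k)
  loadings <- matrix(0, ncol(D), k)
  for (f in seq_len(k)) {
    j <- which.max(colSums(E^2))
    t_vec <- E[, j]
    if (sum(t_vec^2) == 0) t_vec <- stats::rnorm(nrow(E))
    ev_old <- 0
    converged <- FALSE
    for (it in seq_len(max_inner_iter)) {
      p <- drop(crossprod(E, t_vec))
      p <- p / sqrt(sum(p^2))
      t_vec <- drop(E %*% p)
      ev <- sum(t_vec^2)
      if (abs(ev - ev_old) <= tol * max(ev, .Machine$double.eps)) {
        converged <- TRUE
        break
      }
      ev_old <- ev
    }
    if (!converged)
      warning("nipals_decompose: inner loop for factor ", f,
              " did not converge; using best iterate")
    scores[, f] <- t_vec
    loadings[, f] <- p
    E <- E - tcrossprod(t_vec, p)
  }
  list(scores = scores, loadings = loadings)
}

#' Truncated-SVD initial estimates
#'
#' The alternative eigenanalysis initializer: the top-`k` singular triplets
#' in score/loading form (`scores = U_k d_k`, `loadings = V_k`).
#'
#' @inheritParams nipals_decompose
#' @return List with `scores` and `loadings`.
#' @export
svd_initial_estimates <- function(D, k) {
  D <- as.matrix(D)
  if (!all(is.finite(D))) stop("invalid-parameter: D must be finite", call. = FALSE)
  if (k < 1L || k > min(dim(D)))
    stop("invalid-parameter: k must be in 1..min(dim(D))", call. = FALSE)
  sv <- svd(D, nu = k, nv = k)
  list(scores = sv$u %*% diag(sv$d[seq_len(k)], k, k), loadings = sv$v)
}

#' Constraint specification for ALS
#'
#' With `alpha = 1` (the default) the concentration half-step is solved as
#' an exact non-negative least-squares problem (fast combinatorial NNLS), a
#' true descent step. With `alpha < 1` the unconstrained half-step is
#' instead blended toward its non-negative projection,
#' `X <- (1-alpha) X + alpha max(X, 0)` — a softer push that cannot fully
#' enforce the constraint; descent is then maintained by backtracking on
#' `alpha` within the iteration. `alpha = 0` disables the constraint.
#' Constraints always apply to the concentrations; spectral profiles keep
#' their negative 2nd-derivative side lobes by default.
#'
#' @param alpha Constraint strength in `[0, 1]` (default 1 = hard NNLS).
#' @param nonneg_C Apply to concentrations (default `TRUE`).
#' @param nonneg_S Apply to spectral profiles (default `FALSE`).
#' @return A `mcr_constraints` list.
#' @export
mcr_constraints <- function(alpha = 1, nonneg_C = TRUE, nonneg_S = FALSE) {
  if (alpha < 0 || alpha > 1)
    stop("invalid-parameter: alpha must be in [0, 1]", call. = FALSE)
  structure(list(alpha = alpha, nonneg_C = nonneg_C, nonneg_S = nonneg_S),
            class = "mcr_constraints")
}

soft_nonneg <- function(X, alpha) (1 - alpha) * X + alpha * pmax(X, 0)

# Fast combinatorial non-negative least squares (Benthem & Keenan style):
# solves min ||D - C B^T||_F over C >= 0 row-wise, grouping rows by passive
# set so each distinct support pattern costs one small solve. Exact
# minimizer per row, so the ALS half-step using it is a true descent step.
fcnnls <- function(D, B) {
  G <- crossprod(B)                  # k x k
  Rt <- t(D %*% B)                   # k x n  (rhs per row of C)
  k <- ncol(B); n <- ncol(Rt)
  C <- t(solve(G, Rt))               # unconstrained start, n x k
  P <- C > 0
  C[!P] <- 0
  solve_patterns <- function(rows) {
    pat <- apply(P[rows, , drop = FALSE], 1, function(p) paste(as.integer(p), collapse = ""))
    for (up in unique(pat)) {
      rr <- rows[pat == up]
      pp <- P[rr[1], ]
      if (!any(pp)) { C[rr, ] <<- 0; next }
      sol <- solve(G[pp, pp, drop = FALSE], Rt[pp, rr, drop = FALSE])
      Crr <- matrix(0, length(rr), k)
      Crr[, pp] <- t(sol)
      C[rr, ] <<- Crr
    }
  }
  for (outer in seq_len(30 * k)) {
    # inner feasibility loop: shrink passive sets until no negatives remain
    for (inner in seq_len(30 * k)) {
      bad <- which(rowSums(C < -1e-12 & P) > 0)
      if (!length(bad)) break
      Pb <- P[bad, , drop = FALSE]
      Pb[C[bad, , drop = FALSE] < -1e-12] <- FALSE
      P[bad, ] <- Pb
      solve_patterns(bad)
    }
    C[C < 0] <- 0
    # KKT: gradient w = r - G c must be <= 0 on active variables
    W <- Rt - G %*% t(C)             # k x n
    W[t(P)] <- -Inf
    mx <- apply(W, 2, max)
    grow <- which(mx > 1e-9 * max(1, max(abs(Rt))))
    if (!length(grow)) break
    jmax <- apply(W[, grow, drop = FALSE], 2, which.max)
    P[cbind(grow, jmax)] <- TRUE
    solve_patterns(grow)
  }
  C
}

# least-squares solve of X t(B) ~ D for X, with a scaled ridge fallback when
# the normal equations are numerically singular
ls_half_step <- function(D, B, transpose = FALSE) {
  G <- crossprod(B)
  R <- if (transpose) crossprod(D, B) else D %*% B
  X <- tryCatch(t(solve(G, t(R))), error = function(e) NULL)
  if (is.null(X) || !all(is.finite(X))) {
    lambda <- 1e-10 * sum(diag(G)) / ncol(G)
    warning("rank-deficient half-step; using ridge fallback")
    X <- t(solve(G + diag(lambda, ncol(G)), t(R)))
  }
  X
}

# unit-norm profile columns, largest-|.| lobe positive; magnitude and sign
# are pushed into C so C S^T is unchanged
normalize_profiles <- function(C, S) {
  nrm <- sqrt(colSums(S^2))
  nrm[nrm == 0] <- 1
  sgn <- vapply(seq_len(ncol(S)), function(j) {
    v <- S[, j][which.max(abs(S[, j]))]
    if (v < 0) -1 else 1
  }, numeric(1))
  S <- sweep(S, 2, nrm * sgn, "/")
  C <- sweep(C, 2, nrm * sgn, "*")
  list(C = C, S = S)
}

#' Alternating least-squares refinement
#'
#' Alternates concentration and profile least-squares half-steps with the
#' soft non-negativity operator of [mcr_constraints()], starting from `k`
#' unit-norm initial profiles. Iterations stop when the relative change of
#' the lack of fit drops below `tol`, when an iteration fails to improve the
#' fit (the previous iterate is kept, so the recorded lack-of-fit history is
#' non-increasing), or at `max_iter`.
#'
#' @param D Data matrix (pixels x channels), working orientation.
#' @param init_S Channels x k matrix of initial profiles (unit-norm columns).
#' @param constraints A [mcr_constraints()].
#' @param max_iter Maximum iterations (default 500).
#' @param tol Relative lack-of-fit change tolerance (default 1e-6).
#' @return An `mcr_model`: `k`, `C`, `S`, `iterations_run`, `lof_history`,
#'   `converged`, `init_method`, `constraints`.
#' @export
als_optimize <- function(D, init_S, constraints = mcr_constraints(),
                         max_iter = 500L, tol = 1e-6) {
  D <- as.matrix(D)
  if (!all(is.finite(D))) stop("invalid-parameter: D must be finite", call. = FALSE)
  if (sum(D^2) == 0) stop("degenerate-input: all-zero data matrix", call. = FALSE)
  S <- as.matrix(init_S)
  if (nrow(S) != ncol(D))
    stop("invalid-parameter: init_S must have one row per channel", call. = FALSE)
  k <- ncol(S)
  denom <- sum(D^2)
  lof_of <- function(C, S) 100 * sqrt(sum((D - tcrossprod(C, S))^2) / denom)

  lof_hist <- numeric(0)
  lof_prev <- Inf
  converged <- FALSE
  it <- 0L
  C <- NULL
  hard <- constraints$alpha == 1
  while (it < max_iter) {
    it <- it + 1L
    if (hard) {
      # exact NNLS half-steps: each minimizes the residual over a feasible
      # set containing the previous iterate, so descent is guaranteed
      C_new <- if (constraints$nonneg_C) fcnnls(D, S) else ls_half_step(D, S)
      S_new <- if (constraints$nonneg_S) fcnnls(t(D), C_new) else
        ls_half_step(D, C_new, transpose = TRUE)
      ns <- normalize_profiles(C_new, S_new)
      lof <- lof_of(ns$C, ns$S)
    } else {
      # soft blend; backtracking on the blend weight keeps the iteration
      # monotone (alpha -> 0 is plain alternating least squares, which can
      # never increase the residual)
      alpha_eff <- constraints$alpha
      repeat {
        C_new <- ls_half_step(D, S)
        if (constraints$nonneg_C) C_new <- soft_nonneg(C_new, alpha_eff)
        S_new <- ls_half_step(D, C_new, transpose = TRUE)
        if (constraints$nonneg_S) S_new <- soft_nonneg(S_new, alpha_eff)
        ns <- normalize_profiles(C_new, S_new)
        lof <- lof_of(ns$C, ns$S)
        if (lof <= lof_prev + 1e-12 || alpha_eff < 1e-6) break
        alpha_eff <- alpha_eff / 2
      }
    }
    lof <- min(lof, lof_prev)
    C <- ns$C; S <- ns$S
    lof_hist <- c(lof_hist, lof)
    if (is.finite(lof_prev) &&
        abs(lof_prev - lof) <= tol * max(lof_prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    if (lof <= 1e-10) { converged <- TRUE; break }
    lof_prev <- lof
  }
  if (is.null(C)) {                        # max_iter = 0: constrained init fit
    C <- ls_half_step(D, S)
    if (constraints$nonneg_C) C <- soft_nonneg(C, constraints$alpha)
  }
  structure(list(k = k, C = C, S = S, iterations_run = it,
                 lof_history = lof_hist, converged = converged,
                 init_method = "custom", constraints = constraints),
            class = "mcr_model")
}

#' @export
print.mcr_model <- function(x, ...) {
  cat(sprintf("<mcr_model> k = %d, %d pixels x %d channels, LOF %.4g%% after %d iterations (%s)\n",
              x$k, nrow(x$C), nrow(x$S),
              if (length(x$lof_history)) utils::tail(x$lof_history, 1) else NA,
              x$iterations_run,
              if (isTRUE(x$converged)) "converged" else "max_iter"))
  invisible(x)
}

#' Lack of fit of a bilinear reconstruction
#'
#' `100 * sqrt(sum((D - C S^T)^2) / sum(D^2))`.
#'
#' @param D Data matrix.
#' @param model An `mcr_model`, or a list with `C` and `S`.
#' @return Percentage lack of fit.
#' @export
lack_of_fit <- function(D, model) {
  D <- as.matrix(D)
  if (sum(D^2) == 0) stop("degenerate-input: all-zero data matrix", call. = FALSE)
  R <- D - tcrossprod(model$C, model$S)
  100 * sqrt(sum(R^2) / sum(D^2))
}

#' Resolve a 2nd-derivative image into components
#'
#' Orchestrates the full unmixing of one image: spectral-region selection,
#' masked-pixel matrix assembly (the matrix fed to ALS is the negated 2nd
#' derivative, so absorbance bands appear as positive peaks and the
#' non-negativity constraint is meaningful), abstract-factor initialisation,
#' and ALS refinement. With a vector `k`, one model per factor count is
#' returned.
#'
#' @param image A `hyper_image` with `derivative_order = 2`.
#' @param mask A [pixel_mask()] / logical matrix of retained pixels.
#' @param k Number of factors, or a vector of counts (e.g. `4:6`).
#' @param region `c(lo, hi)` spectral region in cm^-1 (default 950-1300).
#' @param init_method `"nipals"` or `"svd"` (eigenanalysis backend for the
#'   abstract-factor stages).
#' @param constraints A [mcr_constraints()].
#' @param max_iter,tol Passed to [als_optimize()].
#' @param strategy `"auto"` (default), `"local_rank"` or `"abstract"`. The
#'   staged local-rank strategy anchors the embedding-medium factor on
#'   masked-out pixels and its selective 1440-1490 cm^-1 window, resolves
#'   the collagens on the amide II window (1520-1600 cm^-1), recovers the
#'   remaining factors from the deflated residual, and polishes jointly; it
#'   needs an image axis spanning those windows, a mask that excludes some
#'   pixels and `k` between 3 and 6, otherwise (or with `"abstract"`) plain
#'   abstract-factor initialisation feeds [als_optimize()] directly.
#' @return An `mcr_model` (with `axis`, `mask` and `region` recorded), or a
#'   named list of models when `length(k) > 1`.
#' @export
resolve <- function(image, mask, k = 5L, region = c(950, 1300),
                    init_method = c("nipals", "svd"),
                    constraints = mcr_constraints(), max_iter = 500L,
                    tol = 1e-6, strategy = c("auto", "local_rank", "abstract")) {
  init_method <- match.arg(init_method)
  strategy <- match.arg(strategy)
  if (image$derivative_order != 2L)
    stop("invalid-parameter: resolve needs a 2nd-derivative image", call. = FALSE)
  mask_check(mask, image)
  sub <- select_region(image, region[1], region[2])
  Dfull <- cube_matrix(sub)
  sel <- as.vector(t(unclass(mask)))            # row-major pixel order
  D <- -Dfull[sel, , drop = FALSE]              # working orientation
  fit_one <- function(kk) {
    res <- NULL
    use_lr <- strategy != "abstract" && local_rank_applicable(image, region, kk)
    if (use_lr)
      res <- resolve_local_rank(image, mask, kk, region, init_method,
                                constraints, max_iter, tol)
    if (is.null(res)) {
      if (strategy == "local_rank")
        stop("invalid-parameter: local-rank strategy not applicable here",
             call. = FALSE)
      init <- if (init_method == "nipals") nipals_decompose(D, kk)
              else svd_initial_estimates(D, kk)
      S0 <- normalize_profiles(init$scores, init$loadings)$S
      m <- als_optimize(D, S0, constraints, max_iter, tol)
    } else {
      m <- structure(list(k = kk, C = res$C, S = res$S,
                          iterations_run = res$iterations_run,
                          lof_history = res$lof_history,
                          converged = res$converged,
                          init_method = init_method,
                          constraints = constraints),
                     class = "mcr_model")
    }
    m$init_method <- init_method
    m$axis <- sub$axis
    m$region <- region
    m$mask <- unclass(mask)
    m$grid <- dim(image$cube)[1:2]
    m
  }
  if (length(k) == 1L) return(fit_one(k))
  out <- lapply(k, fit_one)
  names(out) <- paste0("k", k)
  out
}
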