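# Staged ("local-rank") resolution strategy for IVD transflectance images.
#
# Fully data-driven: no reference spectra enter. The stages exploit spectral
# selectivity the data themselves provide:
#   1. The embedding-medium (paraffin) profile is anchored on the average
#      spectrum of the pixels the amide-II mask EXCLUDES (paraffin/substrate
#      only), and its concentration map read off the paraffin-dominated
#      1440-1490 cm^-1 CH2/CH3 deformation window.
#   2. The two collagens are resolved by a 2-factor MCR of the amide II
#      window (1520-1600 cm^-1), where polysaccharides are silent and both
#      margin (collagen I) and nucleus (collagen II) pixels are near-pure.
#   3. The remaining factors (the PG populations) are resolved from the
#      collagen/paraffin-deflated residual, where their pure zones surface.
#   4. Profiles are assembled and polished by a short hard-constrained ALS
#      plus sparse refits (which undo the NNLS clipping-bias tail) over the
#      full analysis region.
# Mirrors classical local-rank / selectivity reasoning in curve resolution;
# degenerate inputs (axis lacking the anchor windows, other k) fall back to
# the plain abstract-factor ALS path.

# purest-rows vertex estimates: successive projection with top-m averaging
spa_vertices <- function(M, k, m = 20L) {
  R <- M
  out <- matrix(0, k, ncol(M))
  for (j in seq_len(k)) {
    i <- which.max(rowSums(R^2))
    v <- R[i, ] / sqrt(sum(R[i, ]^2))
    proj <- drop(R %*% v)
    top <- order(-proj)[seq_len(min(m, nrow(M)))]
    out[j, ] <- colMeans(M[top, , drop = FALSE])
    R <- R - outer(proj, v)
  }
  out
}


# sparse refit: zero sub-threshold concentrations (the NNLS clipping-bias
# tail) and re-derive all profiles by one full least-squares solve
sparse_refit <- function(D, S, floor_frac = 0.02) {
  C <- fcnnls(D, S)
  cmx <- apply(C, 2, max)
  C[sweep(C, 2, floor_frac * cmx, "<")] <- 0
  normalize_profiles(C, ls_half_step(D, C, transpose = TRUE))$S
}



# whether the staged strategy applies to this image/region/k
local_rank_applicable <- function(image, region, k) {
  ax <- image$axis
  k >= 3L && k <= 6L &&
    min(ax) <= 1020 && max(ax) >= 1600 &&
    region[1] <= 1020 && region[2] >= 1150 && region[2] <= 1520
}

# The staged resolution. Returns list(C, S, lof_history, iterations_run,
# converged) on the restricted region for the masked pixels.
resolve_local_rank <- function(image, mask, k, region, init_method,
                               constraints, max_iter, tol) {
  nr <- n_rows(image); nc <- n_cols(image)
  sel <- as.vector(t(unclass(mask)))
  Dfull <- -cube_matrix(image)
  ridx <- wn_window(image$axis, region[1], region[2], min_channels = 2L)
  D <- Dfull[sel, ridx, drop = FALSE]
  axr <- image$axis[ridx]

  # -- stage 1: embedding-medium anchor -----------------------------------
  s_par <- NULL; C_par <- NULL
  if (any(!sel)) {
    Dex <- Dfull[!sel, , drop = FALSE]
    nrm <- sqrt(rowSums(Dex^2))
    strong <- nrm > stats::median(nrm)
    if (sum(strong) >= 5L) {
      s_par_full <- colMeans(Dex[strong, , drop = FALSE])
      wsel <- wn_window(image$axis, 1440, 1490)
      spw <- s_par_full[wsel]
      if (sum(spw^2) > 0) {
        C_par0 <- pmax(drop(Dfull[sel, wsel, drop = FALSE] %*% spw) /
                         sum(spw^2), 0)
        spr <- s_par_full[ridx]
        if (sum(spr^2) > 0) {
          s_par <- spr / sqrt(sum(spr^2))
          C_par <- C_par0 * sqrt(sum(spr^2))
        }
      }
    }
  }
  if (is.null(s_par)) return(NULL)           # caller falls back

  # -- stage 2: collagens from the amide II window ------------------------
  aidx <- wn_window(image$axis, 1520, 1600)
  DaAll <- Dfull[sel, aidx, drop = FALSE]
  anorm <- sqrt(rowSums(DaAll^2))
  hs <- which(anorm > stats::quantile(anorm, 0.25))
  Sa <- normalize_profiles(matrix(0, 1, 2),
                           t(spa_vertices(DaAll[hs, , drop = FALSE], 2)))$S
  ma <- als_optimize(DaAll[hs, , drop = FALSE], Sa, mcr_constraints(1),
                     max_iter = 200L, tol = tol)
  C_col <- fcnnls(DaAll, ma$S)

  Dnp <- D - tcrossprod(C_par, s_par)

  # annulus-margin key set: pixels dominated by the PG-poor collagen (the
  # outer annulus is collagen I with essentially no polysaccharide signal);
  # used to re-extract that collagen's profile independent of the PG factors
  cos_ch <- which(axr >= 1105 & axr <= 1145)
  pg_index <- sqrt(rowSums(Dnp[, cos_ch, drop = FALSE]^2))
  cshare <- C_col / pmax(rowSums(C_col), 1e-12)
  cstren <- sqrt(rowSums(C_col^2))
  medpg <- vapply(1:2, function(j)
    stats::median(pg_index[order(-cshare[, j] * cstren)[1:200]]), numeric(1))
  iI <- which.min(medpg)
  C_col <- C_col[, c(iI, 3L - iI), drop = FALSE]   # margin collagen first
  low_pg <- pg_index <= stats::median(pg_index)
  cand <- order(-cshare[, iI] * cstren * low_pg)
  margin_key <- cand[seq_len(min(300L, sum(low_pg)))]

  # -- stage 3: semi-fixed full-region pass + PG sub-resolution -----------
  n_free <- k - 3L
  P <- C_col %*% solve(crossprod(C_col), t(C_col))
  if (n_free >= 1L) {
    S_pg <- normalize_profiles(matrix(0, 1, n_free),
                               t(spa_vertices(Dnp - P %*% Dnp, n_free)))$S
    C_pg <- fcnnls(Dnp, S_pg)
    for (it in 1:15) {
      S_all <- ls_half_step(Dnp, cbind(C_col, C_pg), transpose = TRUE)
      S_col <- S_all[, 1:2, drop = FALSE]
      Dres <- Dnp - tcrossprod(C_col, S_col)
      S_pg <- normalize_profiles(C_pg,
                S_all[, 2L + seq_len(n_free), drop = FALSE])$S
      C_pg <- fcnnls(Dres, S_pg)
    }
    # dedicated sub-resolution of the deflated residual
    mpg <- als_optimize(Dres,
             normalize_profiles(matrix(0, 1, n_free),
                                t(spa_vertices(Dres, n_free)))$S,
             mcr_constraints(1), max_iter = 150L, tol = tol)
    S_pg <- mpg$S
    for (r in 1:4) S_pg <- sparse_refit(Dres, S_pg)
  } else {
    S_all <- ls_half_step(Dnp, C_col, transpose = TRUE)
    S_col <- S_all[, 1:2, drop = FALSE]
    S_pg <- NULL
  }

  # -- stage 4: assembly + constrained polish over the full region --------
  S0 <- cbind(normalize_profiles(matrix(0, 1, 2), S_col)$S, S_pg, s_par)
  S0 <- S0[, seq_len(k), drop = FALSE]
  m <- als_optimize(D, S0, constraints, max_iter = min(25L, max_iter),
                    tol = tol)
  S <- m$S
  for (r in 1:3) S <- sparse_refit(D, S)
  C <- fcnnls(D, S)
  S <- normalize_profiles(C, ls_half_step(D, C, transpose = TRUE))$S
  C <- fcnnls(D, S)
  # decouple the outer-annulus collagen profile from the PG factors: re-read
  # it from the margin key set, subtracting only the factors genuinely
  # present there (the other collagen and paraffin; the keys are PG-free by
  # construction, and the apparent PG concentrations at such pixels are
  # NNLS clipping bias, not signal)
  subtract_cols <- c(2L, k)            # assembly order: [colI, colII, PG..., par]
  for (r in 1:2) {
    resid <- D[margin_key, , drop = FALSE] -
      tcrossprod(C[margin_key, subtract_cols, drop = FALSE],
                 S[, subtract_cols, drop = FALSE])
    denom <- sum(C[margin_key, 1L]^2)
    if (denom > 0) {
      sI_new <- drop(crossprod(resid, C[margin_key, 1L])) / denom
      nrmI <- sqrt(sum(sI_new^2))
      if (nrmI > 0) {
        S[, 1L] <- sI_new / nrmI
        C <- fcnnls(D, S)
        Sls <- normalize_profiles(C, ls_half_step(D, C, transpose = TRUE))$S
        Sls[, 1L] <- sI_new / nrmI
        S <- Sls
        C <- fcnnls(D, S)
      }
    }
  }
  list(C = C, S = S, lof_history = m$lof_history,
       iterations_run = m$iterations_run, converged = m$converged)
}
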