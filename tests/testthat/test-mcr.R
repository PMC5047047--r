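# NIPALS, SVD initial estimates and the constrained ALS engine.

test_that("NIPALS recovers a rank-1 factorization exactly", {
  set.seed(21)
  u <- runif(12); v <- rnorm(7)
  D <- u %o% v
  dec <- nipals_decompose(D, 1)
  expect_equal(abs(sum(dec$loadings[, 1] * v / sqrt(sum(v^2)))), 1,
               tolerance = 1e-8)
  expect_lt(sum((D - tcrossprod(dec$scores, dec$loadings))^2), 1e-16)
})

test_that("NIPALS matches the dense SVD oracle factor by factor", {
  set.seed(22)
  D <- matrix(rnorm(48), 8, 6)
  dec <- nipals_decompose(D, 3)
  sv <- svd(D)
  expect_equal(sqrt(colSums(dec$scores^2)), sv$d[1:3], tolerance = 1e-6)
  for (j in 1:3)
    expect_equal(abs(sum(dec$loadings[, j] * sv$v[, j])), 1, tolerance = 1e-6)
  # full-rank recovery
  full <- nipals_decompose(D, 6)
  expect_lt(max(abs(D - tcrossprod(full$scores, full$loadings))), 1e-8)
})

test_that("NIPALS and SVD k-term reconstruction errors agree on 50 seeded matrices", {
  set.seed(23)
  for (rep in 1:50) {
    n <- sample(5:20, 1); m <- sample(5:20, 1); k <- sample(1:4, 1)
    D <- matrix(rnorm(n * m), n, m)
    ni <- suppressWarnings(nipals_decompose(D, k))
    sv <- svd_initial_estimates(D, k)
    e_ni <- sum((D - tcrossprod(ni$scores, ni$loadings))^2)
    e_sv <- sum((D - tcrossprod(sv$scores, sv$loadings))^2)
    expect_lt(abs(e_ni - e_sv) / max(e_sv, 1e-12), 1e-6)
  }
})

test_that("svd_initial_estimates handles orthogonal columns and rejects k = 0", {
  set.seed(30)
  # bilinear matrix with orthonormal profiles and orthogonal score columns:
  # the loadings must recover the profiles up to sign
  S <- qr.Q(qr(matrix(rnorm(64), 8, 8)))[, 1:3]
  Cc <- cbind(c(rep(1, 4), rep(0, 8)), c(rep(0, 4), rep(1, 4), rep(0, 4)),
              c(rep(0, 8), rep(1, 4))) %*% diag(c(3, 2, 1))
  Q <- tcrossprod(Cc, S)
  dec <- svd_initial_estimates(Q, 3)
  for (j in 1:3)
    expect_equal(abs(sum(dec$loadings[, j] * S[, j])), 1, tolerance = 1e-8)
  expect_error(svd_initial_estimates(Q, 0), "invalid-parameter")
  expect_error(nipals_decompose(Q, 10), "invalid-parameter")
})

test_that("ALS recovers planted factors from perturbed-truth initial profiles", {
  set.seed(24)
  k <- 3
  # distinct non-negative components: separated bands and separated maps
  ch <- 1:40
  S_true <- apply(cbind(exp(-(ch - 8)^2 / 8), exp(-(ch - 20)^2 / 8),
                        exp(-(ch - 32)^2 / 8)), 2,
                  function(v) v / sqrt(sum(v^2)))
  t <- seq(0, 1, length.out = 200)
  C_true <- cbind(pmax(0, 1 - 4 * t), pmax(0, 1 - 5 * abs(t - 0.5)),
                  pmax(0, 4 * t - 3))
  D <- tcrossprod(C_true, S_true)
  init <- apply(S_true + matrix(rnorm(40 * k, 0, 0.05), 40, k), 2,
                function(v) v / sqrt(sum(v^2)))
  m <- als_optimize(D, init)
  expect_lt(utils::tail(m$lof_history, 1), 1e-6)
  for (j in 1:k)
    expect_gt(max(abs(stats::cor(m$S, S_true[, j]))), 0.999)
})

test_that("ALS at an exact fixed point converges immediately with zero lack of fit", {
  set.seed(25)
  S_true <- apply(matrix(runif(30 * 2), 30, 2), 2,
                  function(v) v / sqrt(sum(v^2)))
  C_true <- matrix(runif(80 * 2), 80, 2)
  D <- tcrossprod(C_true, S_true)
  m <- als_optimize(D, S_true)
  expect_lte(m$iterations_run, 2L)
  expect_true(m$converged)
  expect_lt(utils::tail(m$lof_history, 1), 1e-8)
})

test_that("lack-of-fit history is non-increasing for hard and soft constraints", {
  set.seed(26)
  D <- matrix(abs(rnorm(600)), 60, 10) %*% diag(10) +
    matrix(rnorm(600, 0, 0.1), 60, 10)
  for (alpha in c(1, 0.5, 0)) {
    init <- svd_initial_estimates(D, 3)
    S0 <- ivdmcr:::normalize_profiles(init$scores, init$loadings)$S
    m <- als_optimize(D, S0, mcr_constraints(alpha), max_iter = 100)
    expect_true(all(diff(m$lof_history) <= 1e-12))
    expect_true(all(is.finite(m$C)) && all(is.finite(m$S)))
    expect_equal(unname(colSums(m$S^2)), rep(1, 3), tolerance = 1e-10)
  }
})

test_that("lack_of_fit matches its closed forms and a summation oracle", {
  set.seed(27)
  D <- matrix(rnorm(40), 8, 5)
  sv <- svd_initial_estimates(D, 2)
  model <- list(C = sv$scores, S = sv$loadings)
  r <- D - tcrossprod(model$C, model$S)
  expect_equal(lack_of_fit(D, model),
               100 * sqrt(sum(r^2) / sum(D^2)))
  full <- svd_initial_estimates(D, 5)
  expect_lt(lack_of_fit(D, list(C = full$scores, S = full$loadings)), 1e-8)
  expect_equal(lack_of_fit(D, list(C = model$C * 0, S = model$S)), 100)
  expect_error(lack_of_fit(D * 0, model), "degenerate-input")
})

test_that("two-component phantom with overlapping maps is recovered up to subspace", {
  # heavily overlapping concentration profiles: assert subspace agreement
  # (principal angles), not factor identity
  set.seed(28)
  t <- seq(0, 1, length.out = 150)
  C_true <- cbind(exp(-(t - 0.45)^2 / 0.02), exp(-(t - 0.55)^2 / 0.02))
  S_true <- apply(matrix(runif(30 * 2)^2, 30, 2), 2,
                  function(v) v / sqrt(sum(v^2)))
  D <- tcrossprod(C_true, S_true) + matrix(rnorm(150 * 30, 0, 1e-4), 150, 30)
  init <- svd_initial_estimates(D, 2)
  m <- als_optimize(D, ivdmcr:::normalize_profiles(init$scores, init$loadings)$S)
  angles <- svd(crossprod(qr.Q(qr(m$S)), qr.Q(qr(S_true))))$d
  expect_true(all(acos(pmin(angles, 1)) < pi / 180))
})

test_that("resolve returns one valid model per requested factor count", {
  fx <- default_phantom()
  ms <- resolve(fx$d2, fx$mask, k = 4:6, region = c(950, 1300))
  expect_named(ms, c("k4", "k5", "k6"))
  for (m in ms) {
    expect_s3_class(m, "mcr_model")
    expect_equal(unname(colSums(m$S^2)), rep(1, m$k), tolerance = 1e-8)
    expect_true(all(diff(m$lof_history) <= 1e-12))
  }
  # PG1-assigned profile is stable across the factor range
  lib <- default_library()
  prof <- lapply(ms, function(m) {
    a <- assign_factors(m, lib)
    m$S[, a$factor[a$component == "PG1"][1]]
  })
  expect_gt(abs(stats::cor(prof$k4, prof$k5)), 0.9)
  expect_gt(abs(stats::cor(prof$k5, prof$k6)), 0.9)
  expect_error(resolve(fx$d2, pixel_mask(matrix(TRUE, 1, 1))),
               "incompatible-image")
})
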