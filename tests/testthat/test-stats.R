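# T2* relaxometry fit and non-parametric association machinery.

test_that("T2* log-linear fit inverts a noiseless decay at the acquisition echo times", {
  te <- c(5.7, 10.9, 16.05, 21.2, 26.4)
  fit <- t2star_fit(te, 100 * exp(-te / 20))
  expect_equal(fit$t2star_ms, 20, tolerance = 1e-9)
  expect_equal(fit$i0, 100, tolerance = 1e-9)
  # two echoes: closed-form two-point slope
  fit2 <- t2star_fit(c(5, 15), c(80, 80 * exp(-10 / 12)))
  expect_equal(fit2$t2star_ms, 12, tolerance = 1e-9)
  expect_error(t2star_fit(te, c(1, 2, 3, 4, -1)), "invalid-input")
  expect_error(t2star_fit(te, exp(te / 30)), "no-decay")
})

test_that("noisy T2* recovery is unbiased at the 1 % level", {
  te <- c(5.7, 10.9, 16.05, 21.2, 26.4)
  set.seed(51)
  est <- replicate(10000, {
    I <- 100 * exp(-te / 18) * exp(rnorm(5, 0, 0.01))
    t2star_fit(te, I)$t2star_ms
  })
  expect_lt(abs(mean(est) - 18) / 18, 0.01)
})

test_that("Kendall test matches cor.test and a brute-force concordance count", {
  set.seed(52)
  x <- rnorm(9); y <- rnorm(9)
  ours <- kendall_test(x, y)
  ref <- stats::cor.test(x, y, method = "kendall")
  expect_equal(ours$tau, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  # ties: tau-b against an O(n^2) concordance oracle
  xt <- c(1, 2, 2, 3, 4, 5, 6, 7)
  yt <- -xt; yt[3] <- yt[2]
  tt <- kendall_test(xt, yt)
  conc <- 0; n <- length(xt)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    conc <- conc + sign(xt[j] - xt[i]) * sign(yt[j] - yt[i])
  n0 <- n * (n - 1) / 2
  tx <- table(xt); ty <- table(yt)
  taub <- conc / sqrt((n0 - sum(tx * (tx - 1) / 2)) *
                        (n0 - sum(ty * (ty - 1) / 2)))
  expect_equal(tt$tau, taub, tolerance = 1e-12)
  expect_lt(tt$p_value, 0.05)
})

test_that("normal-approximation p-values track the exact null closely at n = 10", {
  set.seed(53)
  worst <- 0
  for (rep in 1:100) {
    x <- rnorm(10); y <- rnorm(10)
    worst <- max(worst, abs(kendall_test(x, y, exact = TRUE)$p_value -
                              kendall_test(x, y, exact = FALSE)$p_value))
  }
  # the continuity-corrected approximation sits right at the 0.01 level
  expect_lt(worst, 0.0105)
  # tie-free large-n path agrees with the reference implementation
  x <- rnorm(30); y <- x + rnorm(30, 0, 2)
  ours <- kendall_test(x, y)
  ref <- stats::cor.test(x, y, method = "kendall")
  expect_equal(ours$p_value, ref$p.value, tolerance = 0.01)
})

test_that("exhaustive permutation type-I error of the Kendall test is at most alpha", {
  x <- 1:8
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(q) c(v[i], q))))
  }
  allp <- perms(1:8)
  pvals <- vapply(allp, function(y) kendall_test(x, y)$p_value, numeric(1))
  expect_lte(mean(pvals <= 0.05), 0.05)
})

test_that("Theil-Sen estimates are exact on lines and affine-equivariant", {
  x <- c(1, 3, 4, 6, 7, 9, 10, 12)
  y <- 2 * x + 1
  ts <- theil_sen(x, y)
  expect_equal(ts$slope, 2)
  expect_equal(ts$intercept, 1)
  # swapping two points changes nothing
  ts2 <- theil_sen(x[c(2, 1, 3:8)], y[c(2, 1, 3:8)])
  expect_equal(ts2$slope, ts$slope)
  # affine transform: slope scales as dy/dx
  set.seed(54)
  xr <- rnorm(12); yr <- rnorm(12)
  s0 <- theil_sen(xr, yr)$slope
  s1 <- theil_sen(2 * xr + 3, 5 * yr - 1)$slope
  expect_equal(s1, s0 * 5 / 2, tolerance = 1e-12)
})

test_that("nonparametric regression reports a perfect monotone line", {
  x <- 1:8
  res <- nonparametric_regression(x, 2 * x + 1)
  expect_equal(res$slope, 2)
  expect_equal(res$intercept, 1)
  expect_equal(res$kendall_tau, 1)
  exact_p <- 2 / factorial(8)        # both perfect orderings
  expect_equal(res$p_value, exact_p, tolerance = 1e-12)
  expect_true(res$significant)
  expect_error(nonparametric_regression(rep(1, 8), rnorm(8)),
               "degenerate-data")
  expect_error(nonparametric_regression(1:4, 1:4), "degenerate-data")
})

test_that("cohort correlation joins tables, drops missing pairs, and flags duplicates", {
  co <- simulate_cohort(n = 30, seed = 55)
  pairs <- data.frame(component = c("PG1", "PG1", "nope"),
                      covariate = c("gag_ug_per_mg", "grade", "gag_ug_per_mg"),
                      region = "NP", stringsAsFactors = FALSE)
  res <- suppressMessages(
    correlate_cohort(co$regional, co$covariates, pairs))
  expect_equal(nrow(res), 2L)
  gag <- res[res$y == "gag_ug_per_mg", ]
  expect_gt(gag$kendall_tau, 0)
  expect_true(gag$significant)
  dup <- rbind(co$covariates, co$covariates[1, ])
  expect_error(correlate_cohort(co$regional, dup, pairs),
               "incompatible-tables")
  none <- pairs[3, , drop = FALSE]
  expect_error(suppressMessages(
    correlate_cohort(co$regional, co$covariates, none)),
    "incompatible-tables")
})

test_that("a seeded shuffle of the covariate destroys the planted association", {
  co <- simulate_cohort(n = 40, seed = 56)
  covs <- co$covariates
  set.seed(57)
  shuffled <- covs[covs$region == "NP", ]
  shuffled$gag_ug_per_mg <- sample(shuffled$gag_ug_per_mg)
  np <- co$regional[co$regional$region == "NP" &
                      co$regional$component == "PG1", ]
  m <- merge(np, shuffled, by = c("sample_id", "region"))
  res <- nonparametric_regression(m$value, m$gag_ug_per_mg)
  expect_gt(res$p_value, 0.05)
})
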