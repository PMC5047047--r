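# AoI extraction, width-normalized profiles and regional integrals.

test_that("AoI extraction returns the requested block and validates bounds", {
  m <- matrix(rnorm(60 * 208), 60, 208)
  aoi <- area_of_interest(26, 10)
  sub <- extract_aoi(m, aoi)
  expect_equal(dim(sub), c(10L, 208L))
  expect_equal(sub, m[26:35, ])
  whole <- extract_aoi(m, area_of_interest(1, 60))
  expect_equal(whole, m)
  expect_error(extract_aoi(m, area_of_interest(55, 10)), "outside grid")
})

test_that("centred AoI follows the tissue-row centroid", {
  tis <- matrix(NA_real_, 40, 50)
  tis[11:30, ] <- 1
  aoi <- centered_aoi(tis, 10)
  expect_equal(aoi$row_start + aoi$row_count / 2, 21, tolerance = 1.5)
})

test_that("width normalization is exact on flat and linear sections", {
  tis <- matrix(1, 10, 101)
  flat <- width_normalized_profile(matrix(1, 10, 101), tis)
  expect_equal(flat$values, rep(1, 101))
  ramp <- matrix(rep(seq(0, 1, length.out = 101), each = 10), 10, 101)
  pr <- width_normalized_profile(ramp, tis)
  expect_equal(pr$values, (0:100) / 100, tolerance = 1e-6)
  expect_equal(pr$percent, 0:100)
  expect_error(width_normalized_profile(matrix(1, 10, 2), matrix(1, 10, 2)),
               "degenerate-section")
})

test_that("width-normalized profile tracks the phantom ground truth", {
  cfg <- phantom_config(noise_sigma = 0, baseline_order = -1L, seed = 41)
  ph <- generate_phantom(cfg)
  gt <- ph$ground_truth
  ext <- gt$width_extent
  grid <- gt$true_concentrations[, , "PG1"]
  tis <- ifelse(gt$tissue_mask, 1, NA_real_)
  aoi <- centered_aoi(tis, 10)
  pr <- width_normalized_profile(extract_aoi(grid, aoi), extract_aoi(tis, aoi))
  # oracle: the same interpolator applied to the analytic column profile,
  # scaled by the AoI's mean row factor
  tcols <- (seq(ext[1], ext[2]) - ext[1]) / diff(ext)
  truth <- stats::approx(100 * tcols,
                         colMeans(extract_aoi(grid, aoi)[, ext[1]:ext[2]]),
                         xout = 0:100)$y
  expect_lt(max(abs(pr$values - truth)), 0.05)
})

test_that("regional integrals match closed forms and are additive", {
  flat <- width_normalized_profile(matrix(1, 10, 101), matrix(1, 10, 101),
                                   component = "x", sample_id = "s")
  expect_equal(integrate_region(flat, 10, 20)$value, 10)
  ramp <- width_normalized_profile(
    matrix(rep(seq(0, 1, length.out = 101), each = 10), 10, 101),
    matrix(1, 10, 101), component = "x", sample_id = "s")
  expect_equal(integrate_region(ramp, 51, 61)$value, 5.6, tolerance = 1e-9)
  # additivity over adjacent windows, including non-integer boundaries
  set.seed(42)
  noisy <- flat
  noisy$values <- runif(101)
  a <- integrate_region(noisy, 10, 15.5)$value
  b <- integrate_region(noisy, 15.5, 20)$value
  ab <- integrate_region(noisy, 10, 20)$value
  expect_equal(a + b, ab, tolerance = 1e-9)
  # fine-grid quadrature oracle on [85, 95]
  f <- stats::approxfun(noisy$percent, noisy$values)
  xs <- seq(85, 95, length.out = 20001)
  oracle <- sum(diff(xs) * (f(xs[-length(xs)]) + f(xs[-1])) / 2)
  expect_equal(integrate_region(noisy, 85, 95)$value, oracle, tolerance = 1e-6)
  bad <- flat; bad$values[50] <- NA
  expect_error(integrate_region(bad, 40, 60), "missing-data")
  expect_error(integrate_region(flat, 30, 20), "invalid-parameter")
})

test_that("regional table has full cardinality and order-invariant content", {
  mk_sample <- function(id, seed) {
    set.seed(seed)
    profs <- lapply(c("A", "B", "C", "D"), function(comp) {
      v <- matrix(rep(runif(101), each = 6), 6, 101)
      width_normalized_profile(v, matrix(1, 6, 101), component = comp,
                               sample_id = id)
    })
    stats::setNames(profs, c("A", "B", "C", "D"))
  }
  s <- list(mk_sample("s1", 1), mk_sample("s2", 2), mk_sample("s3", 3))
  tab <- regional_table(s)
  expect_equal(nrow(tab), 3 * 3 * 4)
  shuffled <- regional_table(s[c(3, 1, 2)])
  expect_equal(tab, shuffled)
  # single sample equals direct integrate_region calls
  direct <- integrate_region(s[[1]][["B"]], 51, 61, "NP")$value
  expect_equal(tab$value[tab$sample_id == "s1" & tab$component == "B" &
                           tab$region == "NP"], direct)
  expect_error(regional_table(list(mk_sample("dup", 1), mk_sample("dup", 2))),
               "duplicate")
})

test_that("width normalization is robust to column-duplication stretching", {
  # smooth section profile, as component maps are in practice
  tt <- seq(0, 1, length.out = 80)
  base <- matrix(rep(1 + 0.4 * sin(2 * pi * tt) + 0.2 * tt, each = 8), 8, 80)
  tis <- matrix(1, 8, 80)
  stretched <- base[, rep(seq_len(80), each = 2)]
  tis2 <- tis[, rep(seq_len(80), each = 2)]
  p1 <- width_normalized_profile(base, tis)
  p2 <- width_normalized_profile(stretched, tis2)
  rms <- sqrt(mean((p1$values - p2$values)^2)) / sqrt(mean(p1$values^2))
  expect_lt(rms, 0.02)
})
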