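# Spectral data model and preprocessing.

test_that("Savitzky-Golay 2nd derivative is exact on polynomials and matches a polyfit oracle", {
  i <- 1:200
  # quadratic: derivative 2a everywhere, including the one-sided edges
  for (w in c(7L, 15L, 21L)) {
    d2 <- second_derivative(ir_spectrum(3 * i^2 - 5 * i + 2, i), w, 3L)
    expect_lt(max(abs(d2$intensities - 6)), 1e-8)
  }
  # cubic: derivative 6a*i + 2b, exact for polynomial order 3
  cub <- 0.5 * i^3 + 2 * i^2 + 3
  d2 <- second_derivative(ir_spectrum(cub, i), 15L, 3L)
  expect_lt(max(abs(d2$intensities - (3 * i + 4))), 1e-7)
  # constant in, zeros out
  d2c <- second_derivative(ir_spectrum(rep(7, 50), 1:50), 15L, 3L)
  expect_lt(max(abs(d2c$intensities)), 1e-10)
  # sine: interior point equals an explicit local least-squares polyfit oracle
  y <- sin(2 * pi * i / 50)
  d2s <- second_derivative(ir_spectrum(y, i), 15L, 3L)
  at <- 100L
  win <- (at - 7L):(at + 7L)
  fit <- lm(y[win] ~ poly(win, 3, raw = TRUE))
  oracle <- 2 * fit$coefficients[3] + 6 * fit$coefficients[4] * at
  expect_equal(d2s$intensities[at], unname(oracle), tolerance = 1e-9)
})

test_that("second_derivative validates its inputs", {
  sp <- ir_spectrum(rnorm(30), 1:30)
  expect_error(second_derivative(sp, 14L), "odd")
  expect_error(second_derivative(sp, 35L), "longer than trace")
  d2 <- second_derivative(sp)
  expect_error(second_derivative(d2), "derivative_order")
})

test_that("vector normalization uses the window norm and is idempotent", {
  ax <- seq(900, 1900, by = 2)
  set.seed(1)
  y <- runif(length(ax), 0.1, 1)
  n1 <- vector_normalize(ir_spectrum(y, ax), 950, 1800)
  idx <- which(ax >= 950 & ax <= 1800)
  # direct-summation oracle
  expect_equal(n1$intensities, y / sqrt(sum(y[idx]^2)))
  expect_equal(sqrt(sum(n1$intensities[idx]^2)), 1)
  n2 <- vector_normalize(n1, 950, 1800)
  expect_equal(n1$intensities, n2$intensities)
  # all-equal value v over an n-channel window: in-window values 1/sqrt(n)
  ce <- vector_normalize(ir_spectrum(rep(3, length(ax)), ax), 950, 1800)
  expect_equal(unique(round(ce$intensities[idx], 12)),
               round(1 / sqrt(length(idx)), 12))
  expect_error(vector_normalize(ir_spectrum(rep(0, length(ax)), ax)),
               "degenerate-spectrum")
})

test_that("offset correction zeroes the window minimum and is shift-invariant", {
  ax <- seq(900, 1900, by = 2)
  set.seed(2)
  y <- rnorm(length(ax))
  oc <- offset_correct(ir_spectrum(y, ax), 950, 1800)
  idx <- which(ax >= 950 & ax <= 1800)
  expect_equal(min(oc$intensities[idx]), 0)
  oc5 <- offset_correct(ir_spectrum(y + 5, ax), 950, 1800)
  expect_equal(oc$intensities, oc5$intensities)
})

test_that("region selection keeps inclusive bounds and nests", {
  ax <- seq(900, 1800, by = 2)
  img <- hyper_image(array(rnorm(3 * 4 * length(ax)), c(3, 4, length(ax))), ax)
  expect_equal(length(select_region(img, 950, 1600)$axis), 326L)
  expect_equal(length(select_region(img, 950, 1300)$axis), 176L)
  # full span is the identity
  full <- select_region(img, 900, 1800)
  expect_equal(full$cube, img$cube)
  # selecting a nested range twice equals the inner selection
  a <- select_region(select_region(img, 950, 1600), 1000, 1200)
  b <- select_region(img, 1000, 1200)
  expect_equal(a$cube, b$cube)
  expect_error(select_region(img, 2000, 2100), "invalid-region")
})

test_that("masking recovers the phantom tissue mask exactly in the noise-free case", {
  cfg <- phantom_config(n_rows = 20, n_cols = 40, noise_sigma = 0,
                        baseline_order = -1L, border_rows = 3L,
                        border_cols = 5L, substrate_cols = 2L, seed = 3)
  ph <- generate_phantom(cfg)
  d2 <- second_derivative(ph$image)
  mask <- compute_mask(d2)
  expect_equal(unclass(mask), ph$ground_truth$tissue_mask,
               ignore_attr = TRUE)
  # counting oracle: configured border frame
  expect_equal(sum(mask), (20 - 6) * (40 - 10))
  # threshold -Inf excludes everything
  expect_error(compute_mask(d2, threshold = -Inf), "empty-mask")
})

test_that("region averaging equals the per-channel summation oracle", {
  img <- tiny_image()
  m <- matrix(FALSE, 4, 5)
  m[1, 2] <- TRUE
  one <- region_average(img, pixel_mask(m))
  expect_equal(one$intensities, img$cube[1, 2, ])
  set.seed(4)
  m2 <- matrix(runif(20) < 0.5, 4, 5)
  m2[1, 1] <- TRUE
  avg <- region_average(img, pixel_mask(m2))
  acc <- 0
  for (r in 1:4) for (c in 1:5) if (m2[r, c]) acc <- acc + img$cube[r, c, ]
  expect_equal(avg$intensities, acc / sum(m2))
})

test_that("collation stacks rows and is associative", {
  ax <- wn_axis(1000, 1100, 2)
  mk <- function(nr) hyper_image(array(rnorm(nr * 228 * length(ax)),
                                       c(nr, 228, length(ax))), ax)
  a <- mk(92); b <- mk(92); c3 <- mk(10)
  ab <- collate(list(a, b))
  expect_equal(dim(ab$cube)[1:2], c(184L, 228L))
  expect_equal(collate(list(a))$cube, a$cube)
  lhs <- collate(list(collate(list(a, b)), c3))
  rhs <- collate(list(a, b, c3))
  expect_equal(lhs$cube, rhs$cube)
  bad <- hyper_image(array(0, c(5, 10, length(ax))), ax)
  expect_error(collate(list(a, bad)), "incompatible-image")
})

test_that("mosaic geometry reproduces the goat and human image dimensions", {
  expect_equal(unname(mosaic_dimensions(23, 57, 64, 64, 256)), c(92L, 228L))
  expect_equal(unname(mosaic_dimensions(28, 62, 64, 64, 256)), c(112L, 248L))
  expect_equal(unname(mosaic_dimensions(1, 1, 64, 64, 1)), c(64L, 64L))
  expect_error(mosaic_dimensions(2, 2, 64, 64, 200), "perfect square")
  expect_error(mosaic_dimensions(2, 2, 60, 64, 256), "divide")
})

test_that("cube flattening is row-major and invertible", {
  img <- tiny_image()
  D <- cube_matrix(img)
  # pixel (r, c) is row (r-1)*n_cols + c
  expect_equal(D[(2 - 1) * 5 + 3, ], img$cube[2, 3, ])
  back <- ivdmcr:::matrix_cube(D, 4, 5)
  expect_equal(back, img$cube)
})
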