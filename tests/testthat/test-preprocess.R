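test_that("demosaic rearranges a single mosaic block without interpolation", {
  # raw block holding values 0..24 in layout order -> band b holds value b
  # (0-based), under the row-major default layout
  L <- default_band_layout()
  raw <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) raw[i, j] <- L[i, j] - 1
  cube <- demosaic(raw)
  expect_equal(dim(cube), c(1L, 1L, 25L))
  expect_equal(as.vector(unclass(cube)[1, 1, ]), 0:24)
})

test_that("sensor-sized frames demosaic to the documented cube size", {
  raw <- matrix(0, 2045, 1085)
  cube <- demosaic(raw)
  expect_equal(dim(cube), c(409L, 217L, 25L))
})

test_that("constant frames give constant cubes and bad dims are rejected", {
  expect_true(all(unclass(demosaic(matrix(7.5, 10, 15))) == 7.5))
  expect_error(demosaic(matrix(0, 12, 10)), "not divisible")
})

test_that("demosaic is a bijection (remosaic reconstructs the frame)", {
  set.seed(4)
  raw <- matrix(rnorm(50 * 35), 50, 35)
  expect_identical(remosaic(demosaic(raw)), raw)
  # and under a scrambled layout convention
  L <- matrix(sample(25), 5, 5)
  expect_identical(remosaic(demosaic(raw, L), L), raw)
})

test_that("calibration follows the white/dark reflectance formula", {
  d <- c(2L, 2L, 25L)
  I <- hsi_cube(array(0.5, d)); W <- hsi_cube(array(0.9, d))
  D <- hsi_cube(array(0.1, d))
  expect_equal(as.vector(unclass(calibrate(I, W, D))), rep(0.5, prod(d)))
  expect_true(all(unclass(calibrate(W, W, D)) == 1))
  expect_true(all(unclass(calibrate(D, W, D)) == 0))
  expect_equal(cube_stage(calibrate(I, W, D)), "calibrated")
})

test_that("calibration clamps near-zero denominators with a counted warning", {
  d <- c(2L, 2L, 2L)
  I <- hsi_cube(array(0.5, d))
  W <- hsi_cube(array(c(0.9, 0.2), d))   # W == D for half the entries
  D <- hsi_cube(array(c(0.1, 0.2), d))
  expect_warning(out <- calibrate(I, W, D, eps = 1e-6), "4.*clamped")
  expect_equal(attr(out, "n_clamped"), 4L)
  expect_true(all(is.finite(unclass(out))))
  expect_error(calibrate(I, W, hsi_cube(array(0, c(1, 1, 2)))),
               "identical dimensions")
})

test_that("spectral correction right-multiplies pixel rows by the matrix", {
  d <- c(3L, 2L, 25L)
  set.seed(1)
  Ic <- hsi_cube(array(rnorm(prod(d)), d), stage = "calibrated")
  expect_equal(unclass(spectral_correct(Ic, diag(25))), unclass(Ic),
               ignore_attr = TRUE)
  expect_equal(unclass(spectral_correct(Ic, 2 * diag(25))),
               2 * unclass(Ic), ignore_attr = TRUE)
  # pixel e1 picks out the first row of the matrix
  scm <- matrix(rnorm(625), 25, 25)
  one <- hsi_cube(array(c(1, rep(0, 24)), c(1, 1, 25)), stage = "calibrated")
  expect_equal(as.vector(unclass(spectral_correct(one, scm))), scm[1, ])
  expect_error(spectral_correct(Ic, diag(10)), "band count")
})

test_that("RMS normalization matches its closed form and flags zeros", {
  # 2-band pixel (3, 4): coef = sqrt(12.5), INorm = (3, 4)/coef
  x <- hsi_cube(array(c(3, 4), c(1, 1, 2)))
  res <- rms_normalize(x)
  expect_equal(res$coef[1, 1], sqrt(12.5))
  expect_equal(as.vector(unclass(res$cube)), c(3, 4) / sqrt(12.5),
               tolerance = 1e-12)
  # constant spectrum v -> coef v, all bands 1
  v <- hsi_cube(array(0.7, c(1, 1, 25)))
  resv <- rms_normalize(v)
  expect_equal(resv$coef[1, 1], 0.7)
  expect_equal(as.vector(unclass(resv$cube)), rep(1, 25))
  # scale invariance
  set.seed(2)
  y <- array(abs(rnorm(4 * 4 * 25)), c(4, 4, 25))
  expect_equal(unclass(rms_normalize(hsi_cube(3.7 * y))$cube),
               unclass(rms_normalize(hsi_cube(y))$cube), tolerance = 1e-12)
  # degenerate all-zero pixel propagates zeros, flagged
  z <- y; z[2, 2, ] <- 0
  resz <- rms_normalize(hsi_cube(z))
  expect_true(resz$degenerate[2, 2])
  expect_equal(unclass(resz$cube)[2, 2, ], rep(0, 25))
  expect_equal(cube_stage(resz$cube), "normalized")
})

test_that("normalized cubes have unit per-pixel RMS", {
  img <- fix_image(seed = 21, rows = 16, cols = 16)
  P <- matrix(unclass(img$cube), 256, 25)
  expect_equal(sqrt(rowMeans(P^2)), rep(1, 256), tolerance = 1e-9)
})

test_that("the full chain inverts the forward model exactly (noise-free)", {
  lib <- fix_library()
  sc <- make_phantom_scene(lib, 20, 20, illum_amplitude = 0.4, noise_sd = 0,
                           seed = 13)
  xt <- crosstalk_model(leak = 0.2)
  cap <- render_capture(sc, xt)
  res <- preprocess_capture(cap$raw, cap$white, cap$dark, xt)
  # recovered normalized spectra match RMS-normalized true signatures
  worst <- 0
  for (k in 1:5) {
    idx <- which(sc$region_map == k)
    tru <- lib$signatures[k, ] / sqrt(mean(lib$signatures[k, ]^2))
    P <- matrix(unclass(res$cube), 400, 25)[idx, , drop = FALSE]
    worst <- max(worst, max(abs(sweep(P, 2, tru))))
  }
  expect_lt(worst, 1e-6)
})

test_that("illumination differences vanish after normalization", {
  lib <- fix_library()
  sc <- make_phantom_scene(lib, 24, 24, illum_amplitude = 0.5, noise_sd = 0,
                           seed = 6)
  xt <- crosstalk_model()
  cap <- render_capture(sc, xt)
  res <- preprocess_capture(cap$raw, cap$white, cap$dark, xt)
  idx <- which(sc$region_map == 1L)
  expect_gt(length(idx), 2)
  P <- matrix(unclass(res$cube), 24 * 24, 25)
  a <- P[idx[1], ]; b <- P[idx[length(idx)], ]
  expect_lt(sam(a, b), 1e-9)
  # while the unnormalized cube does depend on illumination
  expect_gt(diff(range(sc$illumination[idx])), 0)
})

test_that("a positive scalar field on I - D is removed by the chain", {
  lib <- fix_library()
  sc <- make_phantom_scene(lib, 15, 15, noise_sd = 0, seed = 8)
  xt <- crosstalk_model()
  cap <- render_capture(sc, xt)
  I <- demosaic(cap$raw); W <- demosaic(cap$white); D <- demosaic(cap$dark)
  set.seed(1)
  kfield <- matrix(runif(15 * 15, 0.5, 2), 15, 15)
  Ik <- hsi_cube(
    (unclass(I) - unclass(D)) * as.vector(kfield) + unclass(D))
  base <- rms_normalize(spectral_correct(calibrate(I, W, D), xt))$cube
  scaled <- rms_normalize(spectral_correct(calibrate(Ik, W, D), xt))$cube
  expect_equal(unclass(scaled), unclass(base), tolerance = 1e-9,
               ignore_attr = TRUE)
})
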