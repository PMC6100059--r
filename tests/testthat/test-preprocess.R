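# Reference signal and its single-level Daubechies-7 decomposition with
# symmetric extension, computed independently with PyWavelets 1.9
# (pywt.dwt(x, "db7", mode="symmetric")) and frozen here.
pywt_x <- c(0.304717, -1.039984, 0.750451, 0.940565, -1.951035, -1.30218,
            0.12784, -0.316243, -0.016801, -0.853044, 0.879398, 0.777792,
            0.066031, 1.127241, 0.467509, -0.859292, 0.368751, -0.958883,
            0.87845, -0.049926)
pywt_cA <- c(-0.5159197529078017, 0.5453196679319152, -2.1745007257516966,
             0.11307280395210424, 0.17113008183721035, -0.7908403728248472,
             1.182920023739306, -1.6665876382114702, -0.42137086408175006,
             -0.7345920337824687, 0.38231374389694195, 0.9978525015046392,
             0.586883350750499, -0.5161569136351948, 0.07526998411295348,
             0.42436368323915336)
pywt_cD <- c(-0.5657121525208894, 1.3702596717939435, -1.292028089601942,
             0.18999764560391053, 0.5463370397769627, 0.8003776052192226,
             -0.33213206668991585, -0.5608965982823055, 1.198715516758646,
             0.9463344677336284, 0.2701034668645229, -1.2316241760057154,
             -0.9140383425364409, -0.10712553600913248, 0.9112129033828714,
             -0.939319357364653)

test_that("the db7 filter bank reproduces the reference decomposition", {
  dec <- seedhsi:::dwt_level(pywt_x, seedhsi:::wt_filters("db7"))
  expect_equal(dec$cA, pywt_cA, tolerance = 1e-9)
  expect_equal(dec$cD, pywt_cD, tolerance = 1e-9)
  rec <- seedhsi:::idwt_level(dec$cA, dec$cD, length(pywt_x),
                              seedhsi:::wt_filters("db7"))
  expect_equal(rec, pywt_x, tolerance = 1e-10)
})

test_that("multi-level decomposition has the expected block sizes and inverts", {
  x <- stats::rnorm(200)
  dec <- seedhsi:::wavedec(x, "db7", 3)
  expect_identical(vapply(dec$coeffs, length, integer(1)),
                   c(36L, 36L, 59L, 106L))
  expect_equal(seedhsi:::waverec(dec), x, tolerance = 1e-10)
  ops <- seedhsi:::wt_operators(200, "db7", 3)
  expect_lt(max(abs(ops$S %*% ops$A - diag(200))), 1e-9)
})

test_that("spectra below the decomposition-length floor are rejected by name", {
  expect_error(denoise_spectrum(stats::rnorm(50), denoise_config()),
               "need >= 104")
})

test_that("denoising leaves constants and ramps essentially untouched", {
  cfg <- denoise_config()
  const <- rep(0.42, 200)
  expect_lt(max(abs(denoise_spectrum(const, cfg) - const)), 1e-8)
  ramp <- seq(0, 1, length.out = 200)
  expect_lt(max(abs(denoise_spectrum(ramp, cfg) - ramp)), 1e-8)
})

test_that("wavelet smoothing strictly reduces RMSE on noisy spectra", {
  wl <- seq(975, 1646, length.out = 200)
  clean <- 0.6 - 0.2 * exp(-(wl - 1200)^2 / (2 * 30^2)) -
    0.25 * exp(-(wl - 1450)^2 / (2 * 25^2))
  set.seed(11)
  noisy <- clean + stats::rnorm(200, sd = 0.01)
  den <- denoise_spectrum(noisy, denoise_config())
  rmse <- function(a) sqrt(mean((a - clean)^2))
  expect_lt(rmse(den), rmse(noisy))
})

test_that("approximation-only reconstruction is idempotent on smooth spectra", {
  # the symmetric-extension transform is oversampled, so zeroing details is
  # only approximately a projection near the boundaries; on spectra in the
  # approximation space the second pass is a no-op to high accuracy
  cfg <- denoise_config(threshold_rule = "approximation-only")
  wl <- seq(975, 1646, length.out = 200)
  smooth <- 0.62 - 0.2 * exp(-(wl - 1200)^2 / (2 * 30^2)) -
    0.25 * exp(-(wl - 1450)^2 / (2 * 25^2))
  once <- denoise_spectrum(smooth, cfg)
  twice <- denoise_spectrum(once, cfg)
  expect_lt(max(abs(twice - once)), 1e-4)

  # on a noisy spectrum the second pass is, away from the boundary-handling
  # region, a small correction relative to the smoothing itself
  set.seed(12)
  noisy <- smooth + stats::rnorm(200, sd = 0.02)
  a <- denoise_spectrum(noisy, cfg)
  b <- denoise_spectrum(a, cfg)
  interior <- 15:186
  expect_lt(max(abs(b - a)[interior]), 0.05 * max(abs(a - noisy)))
})

test_that("cube denoising touches exactly the masked foreground", {
  cfg <- small_scene_config(rng_seed = 8)
  sc <- generate_scene(cfg)
  corr <- correct_reflectance(sc$raw, reference_pair(sc$dark, sc$white))
  mask <- matrix(as.integer(sc$truth$label_map > 0), nrow(sc$truth$label_map))
  den <- denoise_cube(corr, mask, denoise_config())
  vm0 <- cube_pixel_matrix(corr)
  vm1 <- cube_pixel_matrix(den)
  expect_identical(vm1[mask == 0, ], vm0[mask == 0, ])
  changed <- rowSums(vm1 != vm0) > 0
  expect_identical(sum(changed), sum(mask == 1))

  # denoising the foreground improves cube-level RMSE to the clean signal
  class_img <- seedhsi:::labels2class(sc$truth$label_map, sc$truth$classes)
  fg <- mask == 1
  clean <- sc$truth$endmembers[class_img[fg], , drop = FALSE]
  rmse0 <- sqrt(mean((vm0[fg, ] - clean)^2))
  rmse1 <- sqrt(mean((vm1[fg, ] - clean)^2))
  expect_lt(rmse1, rmse0)
})

test_that("ROI mean spectra match an independent accumulation oracle", {
  cfg <- small_scene_config(rng_seed = 9)
  sc <- generate_scene(cfg)
  corr <- correct_reflectance(sc$raw, reference_pair(sc$dark, sc$white))
  sp <- roi_mean_spectra(corr, sc$truth$label_map)
  brute <- brute_roi_means(corr, sc$truth$label_map)
  expect_equal(unname(as.matrix(sp[, grep("^wl_", names(sp))])), brute,
               tolerance = 1e-12)
})

test_that("ROI means are exact on degenerate ROIs", {
  vals <- array(0, dim = c(2, 2, 3))
  vals[1, 1, ] <- c(0.2, 0.4, 0.6)
  vals[1, 2, ] <- c(0.2, 0.4, 0.6)   # roi 1: identical pixels
  vals[2, 1, ] <- 0
  vals[2, 2, ] <- 1                  # roi 2: pixels at 0 and 1
  cube <- hyper_cube(vals, c(1000, 1100, 1200))
  labels <- matrix(c(1L, 2L, 1L, 2L), 2, 2)
  sp <- roi_mean_spectra(cube, labels)
  m <- as.matrix(sp[, grep("^wl_", names(sp))])
  expect_equal(unname(m[1, ]), c(0.2, 0.4, 0.6))
  expect_equal(unname(m[2, ]), c(0.5, 0.5, 0.5))
})
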