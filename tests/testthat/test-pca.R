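test_that("rank-1 data loads entirely on the first component", {
  base <- stats::rnorm(20)
  X <- outer(c(1, 2, 3, 4.5, -2, 0.5), base)
  model <- fit_pixel_pca(X, n_components = 1)
  expect_equal(model$explained_variance_fraction[1], 1, tolerance = 1e-12)
  expect_error(fit_pixel_pca(X, n_components = 3), "rank")
})

test_that("PCA agrees with a covariance eigendecomposition oracle", {
  set.seed(21)
  X <- matrix(stats::rnorm(500 * 50), 500, 50)
  model <- fit_pixel_pca(X, n_components = 6)
  C <- stats::cov(X)
  eig <- eigen(C, symmetric = TRUE)
  frac <- eig$values / sum(eig$values)
  expect_equal(model$explained_variance_fraction, frac[1:6], tolerance = 1e-8)
  for (j in 1:6) {
    v <- eig$vectors[, j]
    i <- which.max(abs(v))
    if (v[i] < 0) v <- -v  # same sign convention as the model
    expect_lt(max(abs(model$loadings[, j] - v)), 1e-8)
  }
})

test_that("loadings are orthonormal and variance fractions conserve and decrease", {
  set.seed(22)
  X <- matrix(stats::rnorm(100 * 12), 100, 12)
  model <- fit_pixel_pca(X, n_components = 6)
  G <- crossprod(model$loadings)
  expect_lt(max(abs(G - diag(6))), 1e-8)
  expect_true(all(diff(model$explained_all) <= 1e-12))
  expect_equal(sum(model$explained_all), 1, tolerance = 1e-8)
  # sign convention: largest-magnitude entry of each column is positive
  expect_true(all(apply(model$loadings, 2,
                        function(v) v[which.max(abs(v))] > 0)))
})

test_that("score images are masked projections", {
  cfg <- small_scene_config(rng_seed = 31)
  sc <- generate_scene(cfg)
  corr <- correct_reflectance(sc$raw, reference_pair(sc$dark, sc$white))
  mask <- matrix(as.integer(sc$truth$label_map > 0), nrow(sc$truth$label_map))
  vm <- cube_pixel_matrix(corr)
  model <- fit_pixel_pca(vm[mask == 1, ], 6,
                         wavelengths_nm = corr$wavelengths_nm)
  imgs <- score_images(model, corr, mask)
  expect_length(imgs, 6L)
  expect_true(all(imgs[[1]][mask == 0] == 0))
  # direct projection oracle at an arbitrary foreground pixel
  px <- which(mask == 1)[17]
  proj <- sum((vm[px, ] - model$mean_spectrum) * model$loadings[, 2])
  expect_equal(imgs[[2]][px], proj, tolerance = 1e-10)

  # class 3 sits apart from classes 1/2 along PC1: mean PC1 scores differ
  # in sign between the groups
  class_img <- seedhsi:::labels2class(sc$truth$label_map, sc$truth$classes)
  m3 <- mean(imgs[[1]][class_img == 3])
  m12 <- mean(imgs[[1]][class_img %in% 1:2])
  expect_lt(sign(m3) * sign(m12), 0)

  short <- crop_bands(corr, 1000, 1300)
  expect_error(score_images(model, short, mask), "band mismatch")
})

test_that("a single Gaussian loading bump yields exactly one EW at its center", {
  wl <- seq(1000, 1600, length.out = 121)
  bump <- exp(-(wl - 1300)^2 / (2 * 40^2))
  model <- structure(list(loadings = cbind(PC1 = bump / sqrt(sum(bump^2))),
                          mean_spectrum = numeric(121), n_components = 1L,
                          wavelengths_nm = wl),
                     class = "pca_model")
  ews <- select_ews(model)
  expect_identical(nrow(ews), 1L)
  expect_identical(ews$wavelength_nm, 1300)
  expect_identical(ews$kind, "peak")
})

test_that("monotone loadings yield no EWs (endpoints excluded)", {
  wl <- seq(1000, 1600, length.out = 50)
  mono <- seq(0.01, 0.9, length.out = 50)
  model <- structure(list(loadings = cbind(PC1 = mono),
                          mean_spectrum = numeric(50), n_components = 1L,
                          wavelengths_nm = wl),
                     class = "pca_model")
  expect_warning(ews <- select_ews(model), "no effective wavelengths")
  expect_identical(nrow(ews), 0L)
})

test_that("proximity deduplication keeps the stronger of two close extrema", {
  wl <- seq(1000, 1600, length.out = 121)  # 5 nm spacing
  b1 <- 0.8 * exp(-(wl - 1300)^2 / (2 * 40^2))
  b2 <- exp(-(wl - 1305)^2 / (2 * 40^2))   # extremum one band away
  model <- structure(list(loadings = cbind(PC1 = b1, PC2 = b2),
                          mean_spectrum = numeric(121), n_components = 2L,
                          wavelengths_nm = wl),
                     class = "pca_model")
  ews <- select_ews(model, dedup_window_nm = 10)
  expect_identical(nrow(ews), 1L)
  expect_identical(ews$wavelength_nm, 1305)  # larger |loading| wins
  expect_identical(ews$component, 2L)
  # all retained EWs are at least a window apart
  expect_true(all(diff(ews$wavelength_nm) >= 10))
})

test_that("restricting a table to EWs equals a brute-force column filter", {
  set.seed(23)
  wl <- seq(975, 1646, length.out = 200)
  tab <- spectra_table(id = 1:4, spectra = matrix(stats::rnorm(800), 4),
                       wavelengths_nm = wl, class = c(1, 2, 3, 1))
  ews <- data.frame(wavelength_nm = wl[c(10, 60, 120)],
                    band = c(10L, 60L, 120L))
  out <- restrict_to_ews(tab, ews)
  expect_identical(names(out),
                   c("id", "class", paste0("wl_", formatC(wl[c(10, 60, 120)],
                                                          format = "f",
                                                          digits = 2))))
  expect_identical(ncol(out), 5L)
  expect_equal(table_wavelengths(out), wl[c(10, 60, 120)], tolerance = 0.01)

  expect_error(restrict_to_ews(tab, ews[0, ]), "empty")
  bad <- data.frame(wavelength_nm = 1234.5678, band = 1L)
  expect_error(restrict_to_ews(tab, bad), "not present")
})

test_that("planted absorption centers are recovered as EWs", {
  cfg <- small_scene_config(rng_seed = 77)
  sc <- generate_scene(cfg)
  corr <- correct_reflectance(sc$raw, reference_pair(sc$dark, sc$white))
  mask <- matrix(as.integer(sc$truth$label_map > 0), nrow(sc$truth$label_map))
  den <- denoise_cube(corr, mask)
  model <- fit_pixel_pca(cube_pixel_matrix(den)[mask == 1, ], 6,
                         wavelengths_nm = corr$wavelengths_nm)
  ews <- select_ews(model)
  centers <- unique(unlist(cfg$feature_centers_nm))
  hit <- vapply(centers, function(ctr)
    any(abs(ews$wavelength_nm - ctr) <= 10), logical(1))
  expect_true(all(hit))
})
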