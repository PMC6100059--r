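# Shared fixtures: all scenes are generated in code at test time.

# compact scene for unit tests: full working band grid, fewer/smaller seeds
small_scene_config <- function(rng_seed = 1, ...) {
  scene_config(image_height = 90, image_width = 120, n_seeds_per_class = 3,
               rng_seed = rng_seed, ...)
}

# minimal flat config for CLI runs
tiny_flat_config <- function(rng_seed = 1) {
  list(image_height = 80, image_width = 100, n_seeds_per_class = 2,
       n_images = 4, pixel_cap = 4000, cost_exponents = c(-2, 0, 2, 4, 6),
       gamma_exponents = c(-4, -2, 0, 2), cv_folds = 3, rng_seed = rng_seed)
}

# brute-force per-label spectral mean, an accumulation oracle independent of
# roi_mean_spectra()'s rowsum path
brute_roi_means <- function(cube, labels) {
  K <- max(labels)
  B <- dim(cube$values)[3]
  out <- matrix(NA_real_, K, B)
  for (k in seq_len(K)) {
    idx <- which(labels == k, arr.ind = TRUE)
    acc <- numeric(B)
    for (i in seq_len(nrow(idx)))
      acc <- acc + cube$values[idx[i, 1], idx[i, 2], ]
    out[k, ] <- acc / nrow(idx)
  }
  out
}
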