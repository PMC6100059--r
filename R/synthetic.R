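# Synthetic hyperspectral scene generator with known ground truth. Scenes
# emulate the statistical structure the analysis chain assumes: three seed
# classes whose mean spectra share absorption features near 1100, 1200,
# 1300 and 1450 nm, classes 1 and 2 spectrally close and class 3 well
# separated, laid out as non-touching elliptical blobs on a dark plate,
# recorded as raw counts against dark and white reference frames.

#' Synthetic scene configuration
#'
#' Defaults describe the working conditions of the analysis: a 200-band
#' grid over 975-1646 nm, five seeds per class, per-pixel reflectance noise
#' of 0.02, a mild illumination gradient along the scan axis, and a class-1
#' vs class-2 endmember separation scaled by `class_overlap` (0 makes them
#' identical). `grid = "sensor"` instead emits a 256-band grid at the
#' instrument-like 3.36 nm spacing (875-1731.8 nm) to exercise band
#' cropping.
#'
#' @param image_height,image_width scene size in pixels.
#' @param band_count number of spectral bands.
#' @param wavelength_start_nm,wavelength_end_nm band-grid limits (nm).
#' @param n_seeds_per_class seeds per class (3 classes).
#' @param feature_centers_nm list of 3 numeric vectors: absorption-feature
#'   centers (nm) per class.
#' @param feature_depths list of 3 numeric vectors in `[0, 1)`: reflectance
#'   dip depth at each feature. Class 2's effective depths are
#'   `class1 + class_overlap * (class2 - class1)`.
#' @param class_overlap scalar scaling the class-1/class-2 endmember
#'   difference (0 = identical).
#' @param noise_sd per-pixel reflectance noise standard deviation.
#' @param illumination_gradient relative illumination slope across the scan
#'   (row) axis.
#' @param rng_seed integer seed; identical configs generate bit-identical
#'   scenes.
#' @param grid `"working"` (default band grid) or `"sensor"` (256-band wide
#'   grid); explicit band arguments override.
#' @return list of class `scene_config`.
#' @export
scene_config <- function(image_height = 160, image_width = 200,
                         band_count = NULL, wavelength_start_nm = NULL,
                         wavelength_end_nm = NULL, n_seeds_per_class = 5,
                         feature_centers_nm = NULL, feature_depths = NULL,
                         class_overlap = 0.4, noise_sd = 0.02,
                         illumination_gradient = 0.05, rng_seed = 1,
                         grid = c("working", "sensor")) {
  grid <- match.arg(grid)
  if (grid == "working") {
    if (is.null(band_count)) band_count <- 200
    if (is.null(wavelength_start_nm)) wavelength_start_nm <- 975
    if (is.null(wavelength_end_nm)) wavelength_end_nm <- 1646
  } else {
    # sensor-like wide grid at the instrument's ~3.36 nm spacing
    if (is.null(band_count)) band_count <- 256
    if (is.null(wavelength_start_nm)) wavelength_start_nm <- 875
    if (is.null(wavelength_end_nm))
      wavelength_end_nm <- 875 + 3.36 * (band_count - 1)
  }
  if (is.null(feature_centers_nm))
    feature_centers_nm <- rep(list(c(1100, 1200, 1300, 1450)), 3L)
  if (is.null(feature_depths))
    feature_depths <- list(c(0.10, 0.14, 0.12, 0.22),
                           c(0.15, 0.10, 0.16, 0.28),
                           c(0.18, 0.07, 0.20, 0.32))
  cfg <- list(image_height = as.integer(image_height),
              image_width = as.integer(image_width),
              band_count = as.integer(band_count),
              wavelength_start_nm = wavelength_start_nm,
              wavelength_end_nm = wavelength_end_nm,
              n_seeds_per_class = as.integer(n_seeds_per_class),
              feature_centers_nm = feature_centers_nm,
              feature_depths = feature_depths,
              class_overlap = class_overlap, noise_sd = noise_sd,
              illumination_gradient = illumination_gradient,
              rng_seed = as.integer(rng_seed))
  validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

validate_scene_config <- function(cfg) {
  if (cfg$band_count < 2) stop("band_count must be >= 2")
  if (cfg$wavelength_end_nm <= cfg$wavelength_start_nm)
    stop("wavelength grid must be strictly increasing")
  if (cfg$n_seeds_per_class < 0) stop("n_seeds_per_class must be >= 0")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  depths <- unlist(cfg$feature_depths)
  if (any(depths < 0 | depths >= 1)) stop("feature depths must lie in [0, 1)")
  if (length(cfg$feature_centers_nm) != 3L || length(cfg$feature_depths) != 3L)
    stop("feature_centers_nm and feature_depths must list all 3 classes")
  invisible(cfg)
}

scene_wavelengths <- function(cfg) {
  seq(cfg$wavelength_start_nm, cfg$wavelength_end_nm,
      length.out = cfg$band_count)
}

# internal spectral constants (documented in the methods vignette):
# absorption features are Gaussian dips of 25 nm width; class 2 sits
# class_overlap * 0.02 above the shared baseline and class 3 a further
# +0.10, which separates it along PC1.
.dip_sigma_nm <- 25
.base2_offset <- 0.02
.base3_offset <- 0.10
.bg_reflectance <- 0.02

#' Per-class endmember spectra
#'
#' Each endmember is a smooth quadratic reflectance baseline minus Gaussian
#' dips at the configured absorption-feature centers; all values lie in
#' `[0, 1]`. Class 2 is pulled towards class 1 by `class_overlap`; class 3
#' carries its own depths plus a baseline offset, so it separates clearly.
#'
#' @param config a [scene_config()].
#' @return `3 x band_count` matrix, rows = classes 1..3, with the
#'   wavelength grid in the `"wavelengths_nm"` attribute.
#' @export
make_endmembers <- function(config) {
  validate_scene_config(config)
  wl <- scene_wavelengths(config)
  for (cl in 1:3) {
    ctr <- config$feature_centers_nm[[cl]]
    if (any(ctr < min(wl) | ctr > max(wl)))
      stop("feature center outside wavelength range: ",
           paste(ctr[ctr < min(wl) | ctr > max(wl)], collapse = ", "), " nm")
    if (length(ctr) != length(config$feature_depths[[cl]]))
      stop("feature centers and depths disagree for class ", cl)
  }
  u <- (wl - min(wl)) / diff(range(wl))
  base1 <- 0.58 + 0.10 * u - 0.06 * u^2
  dips <- function(centers, depths) {
    s <- numeric(length(wl))
    for (j in seq_along(centers))
      s <- s + depths[j] * exp(-(wl - centers[j])^2 / (2 * .dip_sigma_nm^2))
    s
  }
  d1 <- config$feature_depths[[1L]]
  d2 <- d1 + config$class_overlap * (config$feature_depths[[2L]] - d1)
  em <- rbind(
    base1 - dips(config$feature_centers_nm[[1L]], d1),
    base1 + config$class_overlap * .base2_offset -
      dips(config$feature_centers_nm[[2L]], d2),
    base1 + .base3_offset -
      dips(config$feature_centers_nm[[3L]], config$feature_depths[[3L]]))
  em <- pmin(pmax(em, 0), 1)
  rownames(em) <- paste0("class", 1:3)
  attr(em, "wavelengths_nm") <- wl
  em
}

# rejection-sampled layout of non-touching ellipses; conservative
# bounding-circle test with a minimum gap (px)
place_blobs <- function(cfg, gap = 2, max_tries = 300L) {
  K <- 3L * cfg$n_seeds_per_class
  out <- data.frame(row = numeric(K), col = numeric(K), a = numeric(K),
                    b = numeric(K), theta = numeric(K),
                    class = rep(1:3, each = cfg$n_seeds_per_class))
  if (K == 0L) return(out)
  for (k in seq_len(K)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      a <- stats::runif(1, 6, 10)   # semi-axes in px
      b <- stats::runif(1, 4, 7)
      theta <- stats::runif(1, 0, pi)
      m <- a + gap
      if (cfg$image_height - 2 * m < 2 || cfg$image_width - 2 * m < 2)
        stop("image too small for seed blobs: increase image size")
      r0 <- stats::runif(1, 1 + m, cfg$image_height - m)
      c0 <- stats::runif(1, 1 + m, cfg$image_width - m)
      ok <- TRUE
      if (k > 1L) {
        prev <- out[seq_len(k - 1L), ]
        dist <- sqrt((prev$row - r0)^2 + (prev$col - c0)^2)
        ok <- all(dist >= prev$a + a + gap)
      }
      if (ok) {
        out[k, 1:5] <- c(r0, c0, a, b, theta)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place seed ", k, " without touching after ", max_tries,
           " tries: reduce n_seeds_per_class or enlarge the image")
  }
  out
}

blob_label_map <- function(cfg, blobs) {
  labels <- matrix(0L, cfg$image_height, cfg$image_width)
  for (k in seq_len(nrow(blobs))) {
    bb <- blobs[k, ]
    rr <- max(1L, floor(bb$row - bb$a)):min(cfg$image_height, ceiling(bb$row + bb$a))
    cc <- max(1L, floor(bb$col - bb$a)):min(cfg$image_width, ceiling(bb$col + bb$a))
    dr <- outer(rr - bb$row, rep(1, length(cc)))
    dc <- outer(rep(1, length(rr)), cc - bb$col)
    xr <- dr * cos(bb$theta) + dc * sin(bb$theta)
    yr <- -dr * sin(bb$theta) + dc * cos(bb$theta)
    inside <- (xr / bb$a)^2 + (yr / bb$b)^2 <= 1
    sub <- labels[rr, cc]
    sub[inside] <- k
    labels[rr, cc] <- sub
  }
  labels
}

#' Generate a raw synthetic scene with references and ground truth
#'
#' Every in-blob pixel carries its class endmember spectrum mapped to raw
#' counts through the white/dark references (`raw = dark + R * (white -
#' dark) + noise`); the background is a dark plate of reflectance 0.02.
#' The white frame carries the configured illumination gradient along the
#' row (scan) axis; reference frames carry a reduced share (20%) of the
#' configured noise. Applying the reflectance correction therefore recovers
#' the endmembers up to noise, exactly so at `noise_sd = 0`.
#'
#' @param config a [scene_config()].
#' @param gap minimum inter-blob gap in px (default 2).
#' @return list of class `hsi_scene`: `raw` ([hyper_cube()]), `dark` and
#'   `white` reference arrays, and `truth` (ground-truth `label_map`,
#'   per-ROI `classes`, `endmembers`).
#' @export
generate_scene <- function(config, gap = 2) {
  validate_scene_config(config)
  em <- make_endmembers(config)
  wl <- attr(em, "wavelengths_nm")
  h <- config$image_height; w <- config$image_width; B <- config$band_count
  npx <- h * w
  with_local_seed(config$rng_seed, {
    blobs <- place_blobs(config, gap = gap)
    labels <- blob_label_map(config, blobs)
    dark_level <- 100; white_level <- 4000
    range_level <- white_level - dark_level
    frame_sd <- 0.2 * config$noise_sd * range_level
    dark <- array(dark_level + stats::rnorm(npx * B, sd = frame_sd),
                  dim = c(h, w, B))
    grad <- 1 + config$illumination_gradient *
      ((seq_len(h) - 1) / max(h - 1, 1) - 0.5)
    white <- array(rep(grad * range_level, times = w * B),
                   dim = c(h, w, B)) + dark_level +
      array(stats::rnorm(npx * B, sd = frame_sd), dim = c(h, w, B))
    u <- (wl - min(wl)) / diff(range(wl))
    bg <- .bg_reflectance + 0.005 * u
    em_all <- rbind(bg, em)          # row 1 = background, rows 2..4 = classes
    refl <- em_all[as.vector(labels2class(labels, blobs$class)) + 1L, ,
                   drop = FALSE]
    raw_m <- matrix(dark, npx, B) +
      refl * (matrix(white, npx, B) - matrix(dark, npx, B)) +
      matrix(stats::rnorm(npx * B, sd = config$noise_sd * range_level), npx, B)
    raw <- hyper_cube(array(raw_m, dim = c(h, w, B)), wl, kind = "raw")
    structure(list(raw = raw, dark = dark, white = white,
                   truth = list(label_map = labels, classes = blobs$class,
                                endmembers = em),
                   config = config),
              class = "hsi_scene")
  })
}

# map a label image to a class image given per-label classes (0 stays 0)
labels2class <- function(labels, classes) {
  cls <- matrix(0L, nrow(labels), ncol(labels))
  nz <- labels != 0L
  cls[nz] <- as.integer(classes)[labels[nz]]
  cls
}

#' @export
print.hsi_scene <- function(x, ...) {
  cat(sprintf("<hsi_scene> %d seeds (%d per class), ", length(x$truth$classes),
              x$config$n_seeds_per_class))
  print(x$raw)
  invisible(x)
}

#' True class of each segmented ROI
#'
#' Matches segmented ROIs to the generator's ground truth by majority
#' pixel overlap.
#'
#' @param rois a [label_rois()] result on the scene.
#' @param truth the `truth` element of a [generate_scene()] result.
#' @return integer class per segmented ROI label.
#' @export
roi_truth_classes <- function(rois, truth) {
  labels <- if (inherits(rois, "roi_label_map")) rois$labels else rois
  class_img <- labels2class(truth$label_map, truth$classes)
  K <- max(labels)
  vapply(seq_len(K), function(k) {
    cls <- class_img[labels == k]
    cls <- cls[cls != 0L]
    if (!length(cls)) return(NA_integer_)
    as.integer(names(which.max(table(cls))))
  }, integer(1))
}

#' Write a scene's artifacts to disk
#'
#' Raw cube and reference frames as ENVI pairs, ground truth as a CSV of
#' `(roi_label, class)` plus a PNG label image, and the configuration as a
#' flat key = value file.
#'
#' @param scene a [generate_scene()] result.
#' @param dir output directory (created if needed).
#' @param name base name for the artifact files.
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir, name = "scene") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wl <- scene$raw$wavelengths_nm
  write_cube(scene$raw, file.path(dir, paste0(name, "_raw")))
  write_cube(hyper_cube(scene$dark, wl), file.path(dir, paste0(name, "_dark")))
  write_cube(hyper_cube(scene$white, wl), file.path(dir, paste0(name, "_white")))
  write_table(data.frame(roi_label = seq_along(scene$truth$classes),
                         class = scene$truth$classes),
              file.path(dir, paste0(name, "_truth.csv")))
  write_label_png(scene$truth$label_map, file.path(dir, paste0(name, "_labels.png")))
  cfg <- scene$config
  flat <- cfg
  flat$feature_centers_nm <- unlist(cfg$feature_centers_nm)
  flat$feature_depths <- unlist(cfg$feature_depths)
  write_config(flat, file.path(dir, paste0(name, "_config.txt")))
  invisible(dir)
}
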