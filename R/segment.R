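# Seed/background segmentation. The mask is built on the single band where
# sample/background contrast is maximal, thresholded by Otsu's method, and
# each connected foreground component becomes one region of interest (ROI).

#' Find the maximum-contrast band
#'
#' At each band the image is provisionally split at the `rough_fg_quantile`
#' gray-level quantile; the band maximizing the absolute difference between
#' provisional foreground and background means is returned. Ties go to the
#' lower band index.
#'
#' @param cube a corrected [hyper_cube()].
#' @param rough_fg_quantile quantile for the provisional split (default 0.5).
#' @return list with `band` (index), `wavelength_nm` and `contrast`.
#' @export
select_contrast_band <- function(cube, rough_fg_quantile = 0.5) {
  stopifnot(inherits(cube, "hyper_cube"))
  if (cube$kind != "corrected")
    stop("contrast band selection expects a corrected cube")
  vm <- cube_pixel_matrix(cube)
  contrast <- vapply(seq_len(ncol(vm)), function(b) {
    v <- vm[, b]
    thr <- stats::quantile(v, rough_fg_quantile, names = FALSE)
    fg <- v > thr
    if (!any(fg) || all(fg)) return(0)
    abs(mean(v[fg]) - mean(v[!fg]))
  }, numeric(1))
  if (all(contrast == 0))
    stop("flat cube: zero foreground/background contrast at every band")
  b <- which.max(contrast)  # which.max returns the first (lowest) maximum
  list(band = b, wavelength_nm = cube$wavelengths_nm[b], contrast = contrast[b])
}

#' Build the binary sample mask at one band
#'
#' Otsu's threshold on the selected band's grayscale image; background
#' pixels carry 0 and sample pixels 1, so multiplying the mask into the
#' cube zeroes background spectra and leaves sample spectra untouched.
#'
#' @param cube a [hyper_cube()].
#' @param band band index to threshold.
#' @param opening if `TRUE`, apply a 3x3 morphological opening to the mask.
#' @return integer matrix of 0/1.
#' @export
build_mask <- function(cube, band, opening = FALSE) {
  stopifnot(inherits(cube, "hyper_cube"))
  img <- cube$values[, , band]
  rng <- range(img)
  if (diff(rng) == 0)
    stop("degenerate histogram: band image has a single gray level")
  scaled <- (img - rng[1L]) / diff(rng)
  thr <- rng[1L] + diff(rng) * EBImage::otsu(scaled, range = c(0, 1), levels = 256)
  mask <- matrix(as.integer(img > thr), nrow = nrow(img))
  if (!any(mask == 1L) || all(mask == 1L))
    stop("degenerate threshold: mask is empty or full")
  if (opening) {
    kern <- EBImage::makeBrush(3, shape = "box")
    mask <- matrix(as.integer(EBImage::opening(mask, kern) > 0), nrow = nrow(img))
  }
  attr(mask, "threshold") <- thr
  mask
}

#' Label connected foreground components as ROIs
#'
#' Components are discovered in raster-scan order (top-left origin, rows
#' scanned left to right) and labeled consecutively `1..K`; components
#' smaller than `min_roi_size` pixels are removed. Border-touching ROIs are
#' retained but flagged.
#'
#' @param mask 0/1 integer matrix.
#' @param min_roi_size minimum component size in pixels.
#' @param connectivity 4 or 8 (default 8).
#' @return An object of class `roi_label_map`: list with `labels` matrix,
#'   `sizes`, `centroids` (`K x 2`, row/col), `border` flags and `n_removed`.
#' @export
label_rois <- function(mask, min_roi_size = 10, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  h <- nrow(mask); w <- ncol(mask)
  dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  if (connectivity == 8) {
    dr <- c(dr, -1L, -1L, 1L, 1L); dc <- c(dc, -1L, 1L, -1L, 1L)
  }
  labels <- matrix(0L, h, w)
  fg <- mask == 1L
  k <- 0L
  # raster scan: row by row, left to right
  for (r0 in seq_len(h)) for (c0 in seq_len(w)) {
    if (!fg[r0, c0] || labels[r0, c0] != 0L) next
    k <- k + 1L
    queue <- matrix(c(r0, c0), ncol = 2L)
    labels[r0, c0] <- k
    while (nrow(queue) > 0L) {
      cur <- queue[nrow(queue), , drop = FALSE]
      queue <- queue[-nrow(queue), , drop = FALSE]
      for (j in seq_along(dr)) {
        rr <- cur[1L] + dr[j]; cc <- cur[2L] + dc[j]
        if (rr >= 1L && rr <= h && cc >= 1L && cc <= w &&
            fg[rr, cc] && labels[rr, cc] == 0L) {
          labels[rr, cc] <- k
          queue <- rbind(queue, c(rr, cc))
        }
      }
    }
  }
  sizes <- tabulate(labels, nbins = k)
  keep <- which(sizes >= min_roi_size)
  relab <- integer(k)
  relab[keep] <- seq_along(keep)
  nz <- labels != 0L
  labels[nz] <- relab[labels[nz]]
  sizes <- sizes[keep]
  K <- length(keep)
  centroids <- matrix(NA_real_, K, 2L, dimnames = list(NULL, c("row", "col")))
  border <- logical(K)
  if (K > 0L) {
    idx <- which(labels != 0L, arr.ind = TRUE)
    lab <- labels[labels != 0L]
    centroids[, 1L] <- tapply(idx[, 1L], lab, mean)
    centroids[, 2L] <- tapply(idx[, 2L], lab, mean)
    on_border <- idx[, 1L] == 1L | idx[, 1L] == h | idx[, 2L] == 1L | idx[, 2L] == w
    border <- as.logical(tapply(on_border, lab, any))
  }
  structure(list(labels = labels, sizes = sizes, centroids = centroids,
                 border = border, n_removed = k - K),
            class = "roi_label_map")
}

#' @export
print.roi_label_map <- function(x, ...) {
  cat(sprintf("<roi_label_map> %d ROIs (%d undersized removed), %d x %d image\n",
              length(x$sizes), x$n_removed, nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' ROI bookkeeping table
#'
#' @param rois a [label_rois()] result.
#' @return data.frame with 0-based centroid coordinates, one row per ROI.
#' @export
roi_table <- function(rois) {
  data.frame(label = seq_along(rois$sizes), size = rois$sizes,
             centroid_row = rois$centroids[, 1L] - 1,
             centroid_col = rois$centroids[, 2L] - 1,
             border = rois$border)
}
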