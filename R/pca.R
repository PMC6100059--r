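# Pixel-level principal component analysis. Score images render each
# foreground pixel's projection onto a component (background zeroed by mask
# multiplication); effective wavelengths (EWs) are the prominent local
# extrema of the loading curves, deduplicated by proximity.

#' Fit PCA on a pixel-spectra matrix
#'
#' Spectra are centered on their mean; components are ordered by explained
#' variance. Each loading column's sign is fixed so that its
#' largest-magnitude entry is positive, making score images and extremum
#' kinds reproducible.
#'
#' @param X numeric matrix, rows = pixel spectra.
#' @param n_components number of components to retain (default 6).
#' @param wavelengths_nm optional wavelength vector stored in the model.
#' @param clamp_rank if `TRUE`, a request beyond the achievable rank keeps
#'   as many components as the data support (with a warning) instead of
#'   failing; degenerate data (e.g. noiseless scenes) stay analysable.
#' @return list of class `pca_model`: `mean_spectrum`, `loadings`
#'   (bands x components), `explained_variance_fraction` (retained
#'   components), `explained_all` (all `min(n-1, p)` fractions),
#'   `n_components`, `wavelengths_nm`.
#' @export
fit_pixel_pca <- function(X, n_components = 6, wavelengths_nm = NULL,
                          clamp_rank = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < n_components + 1L)
    stop("need at least n_components + 1 = ", n_components + 1L, " rows, got ", n)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc, nu = 0L)
  ev <- sv$d^2 / (n - 1L)
  tol <- max(n, p) * .Machine$double.eps * sv$d[1L]
  rank <- sum(sv$d > tol)
  if (rank < n_components) {
    if (!clamp_rank)
      stop("data rank ", rank, " is below requested n_components = ",
           n_components)
    warning("data rank ", rank, " below requested n_components = ",
            n_components, "; keeping ", rank, " components")
    n_components <- rank
  }
  frac_all <- ev / sum(ev)
  loadings <- sv$v[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(n_components)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) loadings[, j] <- -loadings[, j]
  }
  colnames(loadings) <- paste0("PC", seq_len(n_components))
  structure(list(mean_spectrum = mu, loadings = loadings,
                 explained_variance_fraction = frac_all[seq_len(n_components)],
                 explained_all = frac_all, n_components = n_components,
                 wavelengths_nm = wavelengths_nm),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components over %d bands; explained: %s\n",
              x$n_components, nrow(x$loadings),
              paste(sprintf("%.2f%%", 100 * x$explained_variance_fraction),
                    collapse = ", ")))
  invisible(x)
}

#' Principal component score images
#'
#' Foreground pixel value = projection of the (mean-centered) pixel
#' spectrum onto the component; background pixels are exactly 0.
#'
#' @param model a [fit_pixel_pca()] model.
#' @param cube a [hyper_cube()] with the same bands as the model.
#' @param mask 0/1 matrix.
#' @return list of `height x width` matrices, one per component.
#' @export
score_images <- function(model, cube, mask) {
  stopifnot(inherits(model, "pca_model"), inherits(cube, "hyper_cube"))
  if (length(model$mean_spectrum) != n_bands(cube))
    stop("band mismatch: model has ", length(model$mean_spectrum),
         " bands, cube has ", n_bands(cube))
  d <- dim(cube$values)
  idx <- which(mask == 1L)
  vm <- cube_pixel_matrix(cube)
  scores <- sweep(vm[idx, , drop = FALSE], 2L, model$mean_spectrum) %*% model$loadings
  lapply(seq_len(model$n_components), function(j) {
    img <- matrix(0, d[1L], d[2L])
    img[idx] <- scores[, j]
    img
  })
}

# topographic prominence of local maxima of `y` (scipy-style): for each
# peak, walk outward to the next higher point (or signal edge) on each
# side; the base is the higher of the two interval minima.
peak_prominences <- function(y, peaks) {
  vapply(peaks, function(i) {
    lmin <- y[i]
    j <- i
    while (j > 1L && y[j - 1L] <= y[i]) {
      j <- j - 1L
      if (y[j] < lmin) lmin <- y[j]
    }
    rmin <- y[i]
    k <- i
    while (k < length(y) && y[k + 1L] <= y[i]) {
      k <- k + 1L
      if (y[k] < rmin) rmin <- y[k]
    }
    y[i] - max(lmin, rmin)
  }, numeric(1))
}

local_extrema <- function(y) {
  n <- length(y)
  if (n < 3L) return(list(peaks = integer(), valleys = integer()))
  i <- 2:(n - 1L)
  list(peaks = i[y[i] > y[i - 1L] & y[i] > y[i + 1L]],
       valleys = i[y[i] < y[i - 1L] & y[i] < y[i + 1L]])
}

#' Select effective wavelengths from PCA loading extrema
#'
#' For each retained component, interior local maxima and minima of the
#' loading curve with topographic prominence at least `prominence_fraction`
#' times the curve's maximum absolute loading become EW candidates.
#' Candidates pooled over components are deduplicated: repeatedly keep the
#' candidate with the largest absolute loading (ties to the lower
#' wavelength) and drop all others within `dedup_window_nm` of it.
#' Endpoint bands are never candidates.
#'
#' @param model a [fit_pixel_pca()] model.
#' @param wavelengths_nm wavelength vector (defaults to the model's).
#' @param prominence_fraction prominence threshold as a fraction of the
#'   curve's max |loading| (default 0.1).
#' @param dedup_window_nm proximity window in nm (default 10).
#' @return data.frame of class `ew_set`, sorted by wavelength:
#'   `wavelength_nm`, `band`, `component`, `kind` (peak/valley),
#'   `abs_loading`.
#' @export
select_ews <- function(model, wavelengths_nm = model$wavelengths_nm,
                       prominence_fraction = 0.1, dedup_window_nm = 10) {
  stopifnot(inherits(model, "pca_model"))
  if (is.null(wavelengths_nm))
    stop("no wavelengths in model; supply `wavelengths_nm`")
  if (length(wavelengths_nm) != nrow(model$loadings))
    stop("wavelength vector does not match loading rows")
  cand <- list()
  for (j in seq_len(model$n_components)) {
    curve <- model$loadings[, j]
    thr <- prominence_fraction * max(abs(curve))
    ex <- local_extrema(curve)
    pk <- ex$peaks[peak_prominences(curve, ex$peaks) >= thr]
    vl <- ex$valleys[peak_prominences(-curve, ex$valleys) >= thr]
    if (length(pk) || length(vl))
      cand[[length(cand) + 1L]] <- data.frame(
        wavelength_nm = wavelengths_nm[c(pk, vl)], band = c(pk, vl),
        component = j,
        kind = rep(c("peak", "valley"), c(length(pk), length(vl))),
        abs_loading = abs(curve[c(pk, vl)]))
  }
  if (!length(cand)) {
    warning("no effective wavelengths found")
    out <- data.frame(wavelength_nm = numeric(), band = integer(),
                      component = integer(), kind = character(),
                      abs_loading = numeric())
    class(out) <- c("ew_set", "data.frame")
    return(out)
  }
  cand <- do.call(rbind, cand)
  # greedy non-maximum suppression by |loading|, ties to lower wavelength
  cand <- cand[order(-cand$abs_loading, cand$wavelength_nm), ]
  kept <- list()
  while (nrow(cand) > 0L) {
    top <- cand[1L, ]
    kept[[length(kept) + 1L]] <- top
    cand <- cand[abs(cand$wavelength_nm - top$wavelength_nm) >= dedup_window_nm, ]
  }
  out <- do.call(rbind, kept)
  out <- out[order(out$wavelength_nm), ]
  rownames(out) <- NULL
  class(out) <- c("ew_set", "data.frame")
  out
}

#' Restrict a spectra table to the selected effective wavelengths
#'
#' @param table a [spectra_table()].
#' @param ews an [select_ews()] result.
#' @return the table with identifier/class columns and exactly the EW
#'   spectral columns, in increasing wavelength order.
#' @export
restrict_to_ews <- function(table, ews) {
  if (!nrow(ews)) stop("empty effective-wavelength set")
  tab_wl <- table_wavelengths(table)
  hit <- match(round(ews$wavelength_nm, 2), round(tab_wl, 2))
  if (anyNA(hit))
    stop("EW(s) not present in table: ",
         paste(sprintf("%.2f", ews$wavelength_nm[is.na(hit)]), collapse = ", "))
  meta <- setdiff(names(table), grep("^wl_", names(table), value = TRUE))
  wl_cols <- grep("^wl_", names(table), value = TRUE)
  out <- table[, c(meta, wl_cols[hit]), drop = FALSE]
  class(out) <- c("spectra_table", "data.frame")
  out
}
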