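# Pixel-wise spectral smoothing and per-seed spectrum extraction. Each
# foreground pixel's spectrum is denoised by a decimated Daubechies wavelet
# transform; the per-seed spectrum is the arithmetic mean over the ROI.

#' Wavelet denoising configuration
#'
#' Defaults follow common chemometric practice for NIR reflectance spectra:
#' Daubechies-7 wavelet, decomposition level 3, symmetric boundary
#' extension, universal soft-thresholding of all detail levels with the
#' noise level estimated from the finest-scale coefficients (median
#' absolute deviation / 0.6745). The `"approximation-only"` rule instead
#' reconstructs from the approximation band alone (details zeroed), which
#' is idempotent.
#'
#' @param wavelet_name `"db7"` (default), `"db4"` or `"db2"`.
#' @param level decomposition level (default 3).
#' @param threshold_rule `"universal-soft"` or `"approximation-only"`.
#' @param boundary_mode boundary extension; only `"symmetric"` is provided.
#' @return list of class `denoise_config`.
#' @export
denoise_config <- function(wavelet_name = "db7", level = 3,
                           threshold_rule = c("universal-soft",
                                              "approximation-only"),
                           boundary_mode = "symmetric") {
  threshold_rule <- match.arg(threshold_rule)
  if (boundary_mode != "symmetric")
    stop("only symmetric boundary extension is implemented")
  if (level < 1) stop("level must be >= 1")
  wt_filters(wavelet_name)  # validates the name
  structure(list(wavelet_name = wavelet_name, level = as.integer(level),
                 threshold_rule = threshold_rule,
                 boundary_mode = boundary_mode),
            class = "denoise_config")
}

#' Denoise a single spectrum
#'
#' @param spectrum numeric vector (length must support the configured
#'   decomposition level; the error names the required length).
#' @param config a [denoise_config()].
#' @return denoised numeric vector, same length.
#' @export
denoise_spectrum <- function(spectrum, config = denoise_config()) {
  as.vector(wt_denoise_rows(matrix(spectrum, nrow = 1L),
                            config$wavelet_name, config$level,
                            config$threshold_rule))
}

#' Denoise every foreground pixel of a cube
#'
#' Background pixels (mask 0) are left bit-identical.
#'
#' @param cube a [hyper_cube()].
#' @param mask 0/1 matrix aligned with the cube.
#' @param config a [denoise_config()].
#' @return the cube with denoised foreground spectra.
#' @export
denoise_cube <- function(cube, mask, config = denoise_config()) {
  stopifnot(inherits(cube, "hyper_cube"))
  d <- dim(cube$values)
  if (!identical(dim(mask), d[1:2])) stop("mask does not align with cube")
  idx <- which(mask == 1L)
  if (!length(idx)) return(cube)
  vm <- cube_pixel_matrix(cube)
  vm[idx, ] <- wt_denoise_rows(vm[idx, , drop = FALSE], config$wavelet_name,
                               config$level, config$threshold_rule)
  cube_from_pixel_matrix(vm, cube)
}

#' Per-ROI mean spectra
#'
#' Row `r` is the arithmetic mean, per band, over all pixels labeled `r`.
#'
#' @param cube a [hyper_cube()].
#' @param rois a [label_rois()] result (or a bare label matrix).
#' @return a [spectra_table()] with `id = 1..K`.
#' @export
roi_mean_spectra <- function(cube, rois) {
  labels <- if (inherits(rois, "roi_label_map")) rois$labels else rois
  d <- dim(cube$values)
  if (!identical(dim(labels), d[1:2])) stop("label map does not align with cube")
  idx <- which(labels != 0L)
  vm <- cube_pixel_matrix(cube)
  sums <- rowsum(vm[idx, , drop = FALSE], group = labels[idx])
  counts <- as.vector(table(labels[idx]))
  means <- sums / counts
  spectra_table(id = as.integer(rownames(sums)), spectra = means,
                wavelengths_nm = cube$wavelengths_nm)
}
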