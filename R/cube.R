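#' Hyperspectral cube
#'
#' Container for a rank-3 hyperspectral image: `height x width x bands`
#' array of raw sensor counts or relative reflectance, together with the
#' wavelength (nm) of every band. Pixel coordinates are 0-based in all
#' exported artifacts, row-major with the origin at the top-left; inside R
#' the usual 1-based `[row, col, band]` indexing applies.
#'
#' @param values numeric array `height x width x bands`.
#' @param wavelengths_nm strictly increasing numeric vector, one entry per
#'   band, in nanometres.
#' @param kind `"raw"` for uncalibrated counts, `"corrected"` for relative
#'   reflectance after white/dark correction.
#' @return An object of class `hyper_cube`.
#' @export
hyper_cube <- function(values, wavelengths_nm, kind = c("raw", "corrected")) {
  kind <- match.arg(kind)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a height x width x bands array")
  wavelengths_nm <- as.numeric(wavelengths_nm)
  if (length(wavelengths_nm) != dim(values)[3L])
    stop("wavelength vector length (", length(wavelengths_nm),
         ") does not match band axis (", dim(values)[3L], ")")
  if (length(wavelengths_nm) >= 2L && any(diff(wavelengths_nm) <= 0))
    stop("wavelengths must be strictly increasing")
  structure(list(values = values, wavelengths_nm = wavelengths_nm, kind = kind),
            class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hyper_cube> %d x %d pixels, %d bands (%.1f-%.1f nm), kind: %s\n",
              d[1L], d[2L], d[3L], min(x$wavelengths_nm), max(x$wavelengths_nm),
              x$kind))
  invisible(x)
}

#' @export
dim.hyper_cube <- function(x) dim(x$values)

n_bands <- function(cube) dim(cube$values)[3L]

#' Flatten a cube to a pixel-by-band matrix
#'
#' Rows are pixels in R's column-major order over `(row, col)`; use the same
#' linear indices on a mask or label map to select pixels.
#'
#' @param cube a [hyper_cube()].
#' @return numeric matrix `(height*width) x bands`.
#' @export
cube_pixel_matrix <- function(cube) {
  d <- dim(cube$values)
  matrix(cube$values, nrow = d[1L] * d[2L], ncol = d[3L])
}

cube_from_pixel_matrix <- function(m, template) {
  d <- dim(template$values)
  template$values <- array(m, dim = d)
  template
}
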