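# Reflectance calibration: relative reflectance R = (raw - dark) /
# (white - dark), element-wise against the dark-current and white-reference
# frames, followed by cropping to the low-noise working spectral range.

#' Bundle dark and white reference frames
#'
#' Frames may be full per-pixel cubes (`height x width x bands`, matching
#' the raw cube) or per-column line references (`width x bands` matrices,
#' broadcast down the scan axis, as line-scan systems commonly store them).
#' References are flagged invalid when `white > dark` fails on more than 1%
#' of elements.
#'
#' @param dark,white numeric arrays (rank 3) or matrices (rank 2).
#' @return An object of class `reference_pair`.
#' @export
reference_pair <- function(dark, white) {
  if (!identical(dim(dark), dim(white)))
    stop("dark and white frames must have identical shape")
  rank <- length(dim(dark))
  if (!rank %in% c(2L, 3L))
    stop("reference frames must be rank-2 (width x bands) or rank-3 arrays")
  bad <- mean(white <= dark)
  if (bad > 0.01)
    stop(sprintf("invalid references: white <= dark on %.1f%% of elements",
                 100 * bad))
  structure(list(dark = dark, white = white, rank = rank),
            class = "reference_pair")
}

broadcast_ref <- function(frame, d) {
  if (length(dim(frame)) == 3L) {
    if (!identical(dim(frame), d)) stop("reference frame shape does not match cube")
    return(frame)
  }
  if (!identical(dim(frame), d[2:3]))
    stop("line reference must be width x bands")
  # replicate one line across all rows
  aperm(array(frame, dim = c(d[2L], d[3L], d[1L])), c(3L, 1L, 2L))
}

#' White/dark reflectance correction
#'
#' Computes `(raw - dark) / (white - dark)` element-wise. Pixels where
#' `white - dark < eps` are set to 0 and counted; corrected values are
#' clipped to `clip` and the clip counts recorded in the
#' `correction_stats` attribute. Correcting an already-corrected cube is
#' refused.
#'
#' @param raw a [hyper_cube()] with `kind = "raw"`.
#' @param refs a [reference_pair()].
#' @param eps division guard on the white-dark dynamic range.
#' @param clip length-2 numeric, admissible reflectance range.
#' @return A corrected [hyper_cube()].
#' @export
correct_reflectance <- function(raw, refs, eps = 1e-6, clip = c(-0.05, 1.5)) {
  stopifnot(inherits(raw, "hyper_cube"), inherits(refs, "reference_pair"))
  if (raw$kind == "corrected")
    stop("cube is already corrected; refusing to correct twice")
  d <- dim(raw$values)
  dark <- broadcast_ref(refs$dark, d)
  white <- broadcast_ref(refs$white, d)
  denom <- white - dark
  guarded <- denom < eps
  denom[guarded] <- 1
  r <- (raw$values - dark) / denom
  r[guarded] <- 0
  n_low <- sum(r < clip[1L])
  n_high <- sum(r > clip[2L])
  r[r < clip[1L]] <- clip[1L]
  r[r > clip[2L]] <- clip[2L]
  out <- hyper_cube(r, raw$wavelengths_nm, kind = "corrected")
  attr(out, "correction_stats") <-
    list(n_guarded = sum(guarded), n_clipped_low = n_low, n_clipped_high = n_high)
  out
}

#' Crop a cube to a wavelength interval
#'
#' Retains exactly the bands with `low_nm <= lambda <= high_nm`. Defaults
#' crop the noisy spectral edges to the 975-1646 nm working range.
#'
#' @param cube a [hyper_cube()].
#' @param low_nm,high_nm inclusive crop bounds in nm.
#' @return A [hyper_cube()] with the retained bands.
#' @export
crop_bands <- function(cube, low_nm = 975, high_nm = 1646) {
  stopifnot(inherits(cube, "hyper_cube"))
  keep <- which(cube$wavelengths_nm >= low_nm & cube$wavelengths_nm <= high_nm)
  if (!length(keep))
    stop(sprintf("no bands in [%g, %g] nm", low_nm, high_nm))
  out <- hyper_cube(cube$values[, , keep, drop = FALSE],
                    cube$wavelengths_nm[keep], kind = cube$kind)
  attr(out, "correction_stats") <- attr(cube, "correction_stats")
  out
}
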