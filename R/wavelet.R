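# Discrete wavelet transform with symmetric (half-sample mirror) boundary
# extension, implemented as an orthogonal Daubechies filter bank. The
# decimated transform with symmetric extension is linear in the input, so
# for batch denoising the analysis and synthesis maps are materialized once
# per spectrum length as dense operators and applied to whole pixel-by-band
# matrices with BLAS.

# Daubechies scaling (lowpass decomposition) filters; highpass/reconstruction
# filters follow by quadrature-mirror relations.
.db_dec_lo <- list(
  db2 = c(-0.12940952255126037, 0.22414386804201339, 0.83651630373780794,
          0.48296291314453416),
  db4 = c(-0.010597401785069032, 0.032883011666885197, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.63088076792985892,
          0.71484657055291567, 0.23037781330889651),
  db7 = c(3.53713800001040093e-04, -1.80164070399983204e-03,
          4.29577972921480623e-04, 1.25509985560993331e-02,
          -1.65745416310156006e-02, -3.80299369350104557e-02,
          8.06126091510774346e-02, 7.13092192670500225e-02,
          -2.24036184993841073e-01, -1.43906003929106105e-01,
          4.69782287405359422e-01, 7.29132090846485135e-01,
          3.96539319482306287e-01, 7.78520540850624472e-02)
)

wt_filters <- function(wavelet_name) {
  dec_lo <- .db_dec_lo[[wavelet_name]]
  if (is.null(dec_lo))
    stop("unsupported wavelet '", wavelet_name, "'; available: ",
         paste(names(.db_dec_lo), collapse = ", "))
  F <- length(dec_lo)
  dec_hi <- rev(dec_lo) * (-1)^seq_len(F)
  list(dec_lo = dec_lo, dec_hi = dec_hi,
       rec_lo = rev(dec_lo), rec_hi = rev(dec_hi), length = F)
}

full_conv <- function(v, h) {
  n <- length(v) + length(h) - 1L
  y <- numeric(n)
  for (j in seq_along(h)) {
    idx <- j:(j + length(v) - 1L)
    y[idx] <- y[idx] + h[j] * v
  }
  y
}

# one analysis level: symmetric extension by F-1 samples each side, full
# convolution, downsample by 2
dwt_level <- function(x, filt) {
  F <- filt$length
  L <- length(x)
  ext <- c(x[(F - 1L):1L], x, x[L:(L - F + 2L)])
  outlen <- (L + F - 1L) %/% 2L
  take <- seq(F + 1L, by = 2L, length.out = outlen)
  ya <- full_conv(ext, filt$dec_lo)
  yd <- full_conv(ext, filt$dec_hi)
  list(cA = ya[take], cD = yd[take])
}

# one synthesis level: upsample, convolve with reconstruction filters, crop
idwt_level <- function(cA, cD, outlen, filt) {
  F <- filt$length
  up <- function(v) {
    u <- numeric(2L * length(v) - 1L)
    u[seq(1L, by = 2L, length.out = length(v))] <- v
    u
  }
  y <- full_conv(up(cA), filt$rec_lo) + full_conv(up(cD), filt$rec_hi)
  y[(F - 1L):(F - 2L + outlen)]
}

wt_min_length <- function(wavelet_name, level) {
  (wt_filters(wavelet_name)$length - 1L) * 2L^level
}

#' Multi-level wavelet decomposition / reconstruction
#'
#' Symmetric-extension decimated DWT. `wavedec` returns the coefficient
#' blocks from coarsest approximation to finest detail; `waverec` inverts it
#' exactly (to floating-point precision).
#'
#' @param x numeric vector.
#' @param wavelet_name one of `"db2"`, `"db4"`, `"db7"`.
#' @param level decomposition depth.
#' @return `wavedec`: list with `coeffs` (list cA_L, cD_L, ..., cD_1) and
#'   bookkeeping lengths; `waverec`: the reconstructed numeric vector.
#' @keywords internal
wavedec <- function(x, wavelet_name = "db7", level = 3L) {
  filt <- wt_filters(wavelet_name)
  if (length(x) < wt_min_length(wavelet_name, level))
    stop(sprintf("spectrum too short for level-%d '%s' decomposition: need >= %d points, got %d",
                 level, wavelet_name, wt_min_length(wavelet_name, level), length(x)))
  lens <- integer(level + 1L)
  lens[level + 1L] <- length(x)
  details <- vector("list", level)
  cA <- x
  for (l in seq_len(level)) {
    dec <- dwt_level(cA, filt)
    details[[level - l + 1L]] <- dec$cD
    cA <- dec$cA
    lens[level - l + 1L] <- length(cA)
  }
  list(coeffs = c(list(cA), details), lengths = lens,
       wavelet = wavelet_name, level = level)
}

#' @rdname wavedec
#' @param dec a `wavedec` result.
#' @keywords internal
waverec <- function(dec) {
  filt <- wt_filters(dec$wavelet)
  cA <- dec$coeffs[[1L]]
  for (l in seq_len(dec$level)) {
    cA <- idwt_level(cA, dec$coeffs[[l + 1L]], dec$lengths[l + 1L], filt)
  }
  cA
}

# cache of analysis/synthesis operators keyed by (length, wavelet, level)
.wt_op_cache <- new.env(parent = emptyenv())

# Dense operators: A (n_coeff x n) maps a spectrum to its stacked
# coefficients, S (n x n_coeff) maps coefficients back; S %*% A == I.
# `blocks` gives the column ranges of each coefficient block in the stacked
# layout (cA_L, cD_L, ..., cD_1); `finest` indexes the level-1 details.
wt_operators <- function(n, wavelet_name = "db7", level = 3L) {
  key <- paste(n, wavelet_name, level, sep = "_")
  if (!is.null(.wt_op_cache[[key]])) return(.wt_op_cache[[key]])
  probe <- wavedec(numeric(n), wavelet_name, level)
  blk_len <- vapply(probe$coeffs, length, integer(1))
  ends <- cumsum(blk_len)
  starts <- ends - blk_len + 1L
  m <- ends[length(ends)]
  A <- matrix(0, m, n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- 1
    A[, j] <- unlist(wavedec(e, wavelet_name, level)$coeffs)
  }
  S <- matrix(0, n, m)
  tmpl <- probe
  for (j in seq_len(m)) {
    v <- numeric(m); v[j] <- 1
    tmpl$coeffs <- lapply(seq_along(blk_len), function(b) v[starts[b]:ends[b]])
    S[, j] <- waverec(tmpl)
  }
  blocks <- lapply(seq_along(blk_len), function(b) starts[b]:ends[b])
  names(blocks) <- c(paste0("cA", level), paste0("cD", level:1))
  ops <- list(A = A, S = S, blocks = blocks,
              finest = blocks[[length(blocks)]],
              detail_cols = unlist(blocks[-1L], use.names = FALSE))
  .wt_op_cache[[key]] <- ops
  ops
}

# Batch denoising core: rows of X are spectra. Universal soft threshold per
# spectrum, with the noise level estimated from the finest-scale detail
# coefficients by median absolute deviation / 0.6745.
wt_denoise_rows <- function(X, wavelet_name = "db7", level = 3L,
                            threshold_rule = c("universal-soft",
                                               "approximation-only")) {
  threshold_rule <- match.arg(threshold_rule)
  n <- ncol(X)
  ops <- wt_operators(n, wavelet_name, level)
  C <- X %*% t(ops$A)
  if (threshold_rule == "approximation-only") {
    C[, ops$detail_cols] <- 0
  } else {
    fin <- abs(C[, ops$finest, drop = FALSE])
    sigma <- apply(fin, 1L, stats::median) / 0.6745
    thr <- sigma * sqrt(2 * log(n))
    D <- C[, ops$detail_cols, drop = FALSE]
    D <- sign(D) * pmax(abs(D) - thr, 0)  # thr recycles down columns
    C[, ops$detail_cols] <- D
  }
  C %*% t(ops$S)
}
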