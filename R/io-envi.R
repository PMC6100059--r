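# ENVI-style cube I/O. Dialect written: BSQ interleave, little-endian
# 32-bit float (data type 4), wavelengths in the header. BIL is accepted on
# read; BIP and other data types are rejected with distinct errors.

envi_paths <- function(path) {
  base <- sub("\\.(hdr|dat)$", "", path)
  list(hdr = paste0(base, ".hdr"), dat = paste0(base, ".dat"))
}

#' Write a hyperspectral cube as ENVI header + binary
#'
#' @param cube a [hyper_cube()].
#' @param path base path (with or without `.hdr`/`.dat` extension); the pair
#'   `<path>.hdr` / `<path>.dat` is written.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "hyper_cube"))
  p <- envi_paths(path)
  d <- dim(cube$values)
  hdr <- c(
    "ENVI",
    "description = {seedhsi hyperspectral cube}",
    paste0("samples = ", d[2L]),
    paste0("lines = ", d[1L]),
    paste0("bands = ", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    paste0("data kind = ", cube$kind),
    "wavelength units = Nanometers",
    paste0("wavelength = {",
           paste(formatC(cube$wavelengths_nm, format = "g", digits = 12),
                 collapse = ", "), "}")
  )
  writeLines(hdr, p$hdr)
  # BSQ: band-major, line-major within band, sample fastest
  v <- as.vector(aperm(cube$values, c(2L, 1L, 3L)))
  con <- file(p$dat, "wb")
  on.exit(close(con))
  writeBin(v, con, size = 4L, endian = "little")
  invisible(path)
}

parse_envi_header <- function(hdr_file) {
  txt <- paste(readLines(hdr_file, warn = FALSE), collapse = "\n")
  fields <- list()
  # tokenize: key = value, where value may be {...} spanning lines
  pos <- gregexpr("([a-zA-Z][a-zA-Z0-9 ]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)", txt, perl = TRUE)[[1]]
  if (pos[1L] != -1) {
    starts <- as.vector(pos)
    lens <- attr(pos, "match.length")
    for (i in seq_along(starts)) {
      piece <- substr(txt, starts[i], starts[i] + lens[i] - 1L)
      key <- trimws(sub("=.*$", "", piece))
      val <- trimws(sub("^[^=]*=", "", piece))
      fields[[tolower(key)]] <- val
    }
  }
  fields
}

header_numeric_list <- function(val) {
  val <- gsub("[{}]", "", val)
  as.numeric(trimws(strsplit(val, ",")[[1]]))
}

#' Read an ENVI-style hyperspectral cube
#'
#' Supports BSQ and BIL interleaves of little-endian 32-bit floats. The
#' binary file size must agree with the header geometry and a wavelength
#' list must be present; violations raise distinct errors.
#'
#' @param path base path or path to the `.hdr` / `.dat` file.
#' @return A [hyper_cube()].
#' @export
read_cube <- function(path) {
  p <- envi_paths(path)
  if (!file.exists(p$hdr)) stop("header file not found: ", p$hdr)
  if (!file.exists(p$dat)) stop("binary file not found: ", p$dat)
  h <- parse_envi_header(p$hdr)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(h))
  if (length(miss)) stop("header missing field(s): ", paste(miss, collapse = ", "))
  samples <- as.integer(h[["samples"]])
  lines <- as.integer(h[["lines"]])
  bands <- as.integer(h[["bands"]])
  dtype <- as.integer(h[["data type"]])
  interleave <- tolower(h[["interleave"]])
  if (dtype != 4L)
    stop("unsupported data type ", dtype, " (only 4 = float32 supported)")
  if (!interleave %in% c("bsq", "bil"))
    stop("unsupported interleave '", interleave, "' (bsq or bil required)")
  if (is.null(h[["wavelength"]]))
    stop("header missing wavelength list")
  wl <- header_numeric_list(h[["wavelength"]])
  if (length(wl) != bands)
    stop("wavelength list length (", length(wl), ") does not match bands (",
         bands, ")")
  n <- as.double(samples) * lines * bands
  expected <- n * 4
  actual <- file.size(p$dat)
  if (actual != expected)
    stop("size mismatch: header implies ", expected, " bytes but binary has ",
         actual)
  con <- file(p$dat, "rb")
  on.exit(close(con))
  v <- readBin(con, what = "numeric", n = n, size = 4L, endian = "little")
  values <- switch(interleave,
    bsq = aperm(array(v, dim = c(samples, lines, bands)), c(2L, 1L, 3L)),
    bil = aperm(array(v, dim = c(samples, bands, lines)), c(3L, 1L, 2L)))
  kind <- if (!is.null(h[["data kind"]]) &&
              tolower(h[["data kind"]]) == "corrected") "corrected" else "raw"
  hyper_cube(values, wl, kind = kind)
}
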