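# CSV / PNG artifact writers. All writers are deterministic given identical
# inputs; label maps round-trip losslessly through 8-bit grayscale PNG
# (labels are capped at 255).

wl_colnames <- function(wavelengths_nm) {
  paste0("wl_", formatC(wavelengths_nm, format = "f", digits = 2))
}

#' Build a spectra table
#'
#' One row per object (or pixel), identifier and optional class columns
#' followed by one reflectance column per wavelength (`wl_<nm>`).
#'
#' @param id identifier vector.
#' @param spectra numeric matrix, rows aligned with `id`, one column per band.
#' @param wavelengths_nm wavelength (nm) of each spectral column.
#' @param class optional integer class per row, values in `{1, 2, 3}`.
#' @return A `data.frame` of class `spectra_table`.
#' @export
spectra_table <- function(id, spectra, wavelengths_nm, class = NULL) {
  spectra <- as.matrix(spectra)
  if (ncol(spectra) != length(wavelengths_nm))
    stop("spectra column count does not match wavelength vector")
  if (!is.null(class) && !all(class %in% 1:3))
    stop("classes must be in {1, 2, 3}")
  tab <- data.frame(id = id, stringsAsFactors = FALSE)
  if (!is.null(class)) tab$class <- as.integer(class)
  sp <- as.data.frame(spectra)
  names(sp) <- wl_colnames(wavelengths_nm)
  tab <- cbind(tab, sp)
  class(tab) <- c("spectra_table", "data.frame")
  tab
}

#' Wavelengths of a spectra table
#' @param table a [spectra_table()] (or any data.frame with `wl_` columns).
#' @return numeric vector of wavelengths in nm, in column order.
#' @export
table_wavelengths <- function(table) {
  cols <- grep("^wl_", names(table), value = TRUE)
  as.numeric(sub("^wl_", "", cols))
}

table_spectra <- function(table) {
  as.matrix(table[, grep("^wl_", names(table)), drop = FALSE])
}

#' Write / read a table as CSV
#'
#' RFC-4180 CSV with a header row. An empty table round-trips as a
#' header-only file.
#'
#' @param table data.frame.
#' @param path file path.
#' @return `write_table` returns `path` invisibly; `read_table` the data.frame.
#' @export
write_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Write an integer label map as a grayscale PNG
#'
#' Lossless for labels 0..255 (the label value is the 8-bit gray level).
#'
#' @param labels integer matrix, 0 = background.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_label_png <- function(labels, path) {
  if (max(labels) > 255L) stop("label PNG supports at most 255 labels")
  png::writePNG(labels / 255, path)
  invisible(path)
}

#' @rdname write_label_png
#' @export
read_label_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  matrix(as.integer(round(img * 255)), nrow = nrow(img))
}

#' Write a class image as a paletted RGB PNG
#'
#' @param image integer matrix of class codes (0 = background).
#' @param path file path.
#' @param palette named character vector mapping class code to hex color;
#'   must cover every value present in `image`.
#' @return `path`, invisibly.
#' @export
write_map <- function(image, path,
                      palette = c(`0` = "#000000", `1` = "#FF0000",
                                  `2` = "#00CC00", `3` = "#0066FF")) {
  present <- sort(unique(as.vector(image)))
  missing <- setdiff(as.character(present), names(palette))
  if (length(missing))
    stop("palette missing class(es): ", paste(missing, collapse = ", "))
  rgb <- grDevices::col2rgb(palette[as.character(as.vector(image))]) / 255
  arr <- array(0, dim = c(nrow(image), ncol(image), 3L))
  arr[, , 1L] <- matrix(rgb[1L, ], nrow(image))
  arr[, , 2L] <- matrix(rgb[2L, ], nrow(image))
  arr[, , 3L] <- matrix(rgb[3L, ], nrow(image))
  png::writePNG(arr, path)
  invisible(path)
}

#' Write / read a flat key = value configuration file
#'
#' Values are written with full precision; numeric-looking values are read
#' back as numerics, comma-separated values as vectors.
#'
#' @param config named list of scalars or flat vectors.
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` a named list.
#' @export
write_config <- function(config, path) {
  fmt <- function(v) {
    if (is.numeric(v)) paste(formatC(v, format = "g", digits = 17), collapse = ", ")
    else paste(as.character(v), collapse = ", ")
  }
  writeLines(paste0(names(config), " = ", vapply(config, fmt, "")), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln)) stop("malformed config line: ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(strsplit(sub("^[^=]*=", "", ln), ",")[[1]])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!anyNA(num)) num else val
  }
  out
}
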