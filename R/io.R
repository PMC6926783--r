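# File I/O: RGB images (PNG, TIFF), label masks as single-channel PNG, and
# two-column 2theta/intensity diffraction traces as plain text.

#' Read an RGB image
#'
#' Reads PNG or TIFF (by extension) into an `h x w x 3` numeric array with
#' intensities in `[0, 255]`. Alpha channels are dropped; grayscale images
#' are replicated across the three channels.
#'
#' @param path image path (`.png`, `.tif`, `.tiff`).
#' @return Numeric array `h x w x 3`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: .", ext))
  if (length(dim(img)) == 2) img <- array(img, c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  round(img * 255)
}

#' Write an RGB image
#'
#' @param image numeric array `h x w x 3`, intensities in `[0, 255]`.
#' @param path output path; format chosen by extension (PNG or TIFF).
#' @export
write_image <- function(image, path) {
  arr <- pmin(pmax(image / 255, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(arr, path),
         tif = ,
         tiff = tiff::writeTIFF(arr, path),
         stop("unsupported image format: .", ext))
  invisible(path)
}

#' Read / write a label mask as single-channel PNG
#'
#' Class codes are stored directly as 8-bit gray levels (0..255), so a
#' round trip is lossless.
#'
#' @param path PNG path.
#' @return `read_label_mask` returns a [label_mask].
#' @export
read_label_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  label_mask(matrix(as.integer(round(img * 255)), nrow(img), ncol(img)))
}

#' @rdname read_label_mask
#' @param mask a [label_mask] to write.
#' @export
write_label_mask <- function(mask, path) {
  png::writePNG(unclass(mask) / 255, path)
  invisible(path)
}

#' Read / write a diffraction pattern as two-column XY text
#'
#' The format is whitespace-separated `2theta intensity` pairs, one per
#' line; lines starting with `#` are comments.
#'
#' @param path file path.
#' @param wavelength wavelength in Angstrom recorded on the returned
#'   pattern (the XY format does not carry it).
#' @return `read_xy` returns a [diffraction_pattern].
#' @export
read_xy <- function(path, wavelength = CU_KALPHA1) {
  df <- read.table(path, comment.char = "#", col.names = c("two_theta", "intensity"))
  diffraction_pattern(df$two_theta, df$intensity, wavelength = wavelength)
}

#' @rdname read_xy
#' @param pattern a [diffraction_pattern] to write.
#' @export
write_xy <- function(pattern, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# wavelength_A %.6f", pattern$wavelength), con)
  writeLines(sprintf("%.6f %.8g", pattern$two_theta, pattern$intensity), con)
  invisible(path)
}
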