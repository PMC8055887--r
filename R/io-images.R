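#' Read an 8-bit RGB microscopy tile
#'
#' PNG files are read with \pkg{png}, anything else (e.g. JPEG) through
#' \pkg{EBImage}. Grayscale images are expanded to three channels; an alpha
#' channel is dropped.
#'
#' @param path Image file (PNG or JPEG).
#' @return `height x width x 3` array of values in `[0, 1]`.
#' @export
read_image_rgb <- function(path) {
  if (!file.exists(path)) abort(sprintf("image not found: %s", path))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
  } else {
    eb <- EBImage::readImage(path)
    img <- aperm(as.array(eb), if (length(dim(eb)) == 3L) c(2, 1, 3) else c(2, 1))
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] != 3L) abort(sprintf("%s: expected an RGB image", path))
  img
}

#' Write an RGB array as PNG
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}
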