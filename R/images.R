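# In-memory images are numeric arrays dim c(height, width, 3), values in
# [0, 1], row = y (top-down), column = x. Masks are logical matrices.

assert_rgb_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("expected an RGB image: numeric array of dim (height, width, 3)")
  if (!is.numeric(img) || anyNA(img) || min(img) < -1e-9 || max(img) > 1 + 1e-9)
    stop("RGB intensities must be numeric in [0, 1]")
  invisible(img)
}

#' Read an 8-bit RGB image from a PNG file
#'
#' @param path PNG file path. Grayscale images are expanded to three
#'   channels; an alpha channel, if present, is dropped.
#' @return numeric array of dim (height, width, 3) with values in `[0, 1]`.
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] >= 4L) img <- img[, , 1:3, drop = FALSE]
  assert_rgb_image(img[, , 1:3, drop = FALSE])
}

#' Write an RGB image (or a binary mask) to a PNG file
#'
#' Masks are written as 0/255 grayscale, images as 8-bit RGB.
#'
#' @param img RGB array as produced by [render_fruit_image()], or a logical
#'   matrix mask.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  if (is.logical(img) && is.matrix(img)) {
    png::writePNG(matrix(as.numeric(img), nrow(img), ncol(img)), path)
  } else {
    assert_rgb_image(img)
    png::writePNG(pmin(pmax(img, 0), 1), path)
  }
  invisible(path)
}

#' Read a binary mask from a PNG file written by [write_image()]
#' @param path PNG file path.
#' @return logical matrix (TRUE = foreground).
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0.5
}
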