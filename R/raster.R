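#' Raster image container
#'
#' A photoquadrat image is represented as a `height x width x 3` integer array
#' of 8-bit sRGB channel values in `[0, 255]`, row-major with the origin at
#' the top-left pixel. User-facing pixel coordinates (annotation points,
#' bounding boxes) are 0-based to match common annotation-export conventions;
#' R's internal 1-based indexing is converted at the boundary.
#'
#' @param pixels Numeric array `h x w x 3` with values in `[0, 255]`.
#' @return An integer array of class `raster_image`.
#' @examples
#' img <- raster_image(array(128, dim = c(64, 64, 3)))
#' dim(img)
#' @export
raster_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop_reefquad("`pixels` must be a height x width x 3 array", "reefquad_invalid_image")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop_reefquad("channel values must lie in [0, 255]", "reefquad_invalid_image")
  storage.mode(pixels) <- "integer"
  structure(pixels, class = c("raster_image", class(pixels)))
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<raster_image> %d x %d px, 3 channels, range [%d, %d]\n",
              d[1], d[2], min(x), max(x)))
  invisible(x)
}

assert_raster <- function(img, min_side = 1L) {
  if (!inherits(img, "raster_image")) img <- raster_image(img)
  d <- dim(img)
  if (d[1] < min_side || d[2] < min_side)
    stop_reefquad(sprintf("image must be at least %d px on each side", min_side),
                  "reefquad_invalid_image")
  img
}

#' Read a PNG image as a raster_image
#'
#' @param path Path to an 8-bit PNG file.
#' @return A [raster_image()].
#' @export
read_image <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]
  raster_image(round_half_up(px * 255))
}

#' Write a raster_image to a PNG file
#'
#' @param img A [raster_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  img <- assert_raster(img)
  png::writePNG(unclass(img) / 255, target = path)
  invisible(path)
}
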