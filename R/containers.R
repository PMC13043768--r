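#' RGB histology tile
#'
#' Lightweight container for an 8-bit RGB image together with its physical
#' pixel spacing. Pixels are stored as a `height x width x 3` integer array
#' in 0-255, row 1 at the top of the image (the convention of
#' [png::readPNG()] and [tiff::readTIFF()]).
#'
#' @param pixels `H x W x 3` numeric array with values in 0-255 (integers)
#'   or 0-1 (doubles, as returned by the PNG/TIFF readers; rescaled).
#' @param spacing_um physical size of one pixel in micrometres (the slides
#'   this package targets are scanned at 0.5 um/px).
#' @return An object of class `rgb_tile` with elements `pixels` and
#'   `spacing_um`.
#' @examples
#' px <- array(220, dim = c(16, 16, 3))
#' tile <- rgb_tile(px, spacing_um = 0.5)
#' dim(tile$pixels)
#' @export
rgb_tile <- function(pixels, spacing_um) {
  stopifnot_scalar_pos(spacing_um, "spacing_um")
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("pixels must be a H x W x 3 array", call. = FALSE)
  if (max(pixels) <= 1 && is.double(pixels) && any(pixels != round(pixels)))
    pixels <- pixels * 255
  pixels <- array(as.integer(round(clamp(pixels, 0, 255))), dim = dim(pixels))
  structure(list(pixels = pixels, spacing_um = as.numeric(spacing_um)),
            class = "rgb_tile")
}

#' Binary vessel mask
#'
#' A boolean raster marking vessel foreground, carrying the pixel spacing of
#' the tile it was derived from.
#'
#' @param pixels logical (or 0/1 numeric) `H x W` matrix; `TRUE` = vessel.
#' @param spacing_um micrometres per pixel.
#' @return An object of class `binary_mask` with elements `pixels`
#'   (logical matrix) and `spacing_um`.
#' @examples
#' m <- binary_mask(matrix(c(TRUE, FALSE, FALSE, TRUE), 2), spacing_um = 0.5)
#' sum(m$pixels)
#' @export
binary_mask <- function(pixels, spacing_um) {
  stopifnot_scalar_pos(spacing_um, "spacing_um")
  if (is.null(dim(pixels)) || length(dim(pixels)) != 2L)
    stop("pixels must be a 2-d matrix", call. = FALSE)
  px <- matrix(as.logical(pixels), nrow(pixels), ncol(pixels))
  if (anyNA(px)) stop("mask pixels must not contain NA", call. = FALSE)
  structure(list(pixels = px, spacing_um = as.numeric(spacing_um)),
            class = "binary_mask")
}

#' @export
print.rgb_tile <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_tile> %d x %d px @ %g um/px (%.0f x %.0f um)\n",
              d[1], d[2], x$spacing_um, d[1] * x$spacing_um,
              d[2] * x$spacing_um))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<binary_mask> %d x %d px @ %g um/px, %d foreground (%.1f%%)\n",
              d[1], d[2], x$spacing_um, sum(x$pixels),
              100 * mean(x$pixels)))
  invisible(x)
}

#' Read an RGB tile from a PNG or TIFF file
#'
#' @param path file path; format chosen by extension (.png, .tif, .tiff).
#' @param spacing_um micrometres per pixel to attach to the tile.
#' @return An [rgb_tile()].
#' @export
read_tile <- function(path, spacing_um = 0.5) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3L), c(dim(arr), 3L))
  if (dim(arr)[3] > 3L) arr <- arr[, , 1:3, drop = FALSE]
  rgb_tile(arr * 255, spacing_um)
}

#' Write an RGB tile to PNG
#'
#' @param tile an [rgb_tile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tile <- function(tile, path) {
  stopifnot(inherits(tile, "rgb_tile"))
  png::writePNG(tile$pixels / 255, path)
  invisible(path)
}

#' Read a binary mask from an 8-bit PNG
#'
#' Pixels above 127 are taken as foreground.
#'
#' @param path PNG file path.
#' @param spacing_um micrometres per pixel.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, spacing_um = 0.5) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1]
  binary_mask(arr > 0.5, spacing_um)
}

#' Write a binary mask as an 8-bit PNG (foreground = 255)
#'
#' @param mask a [binary_mask()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  png::writePNG(matrix(as.numeric(mask$pixels), nrow(mask$pixels)), path)
  invisible(path)
}

check_congruent <- function(a, b) {
  if (!identical(dim(a$pixels)[1:2], dim(b$pixels)[1:2]))
    stop("inputs have different raster shapes", call. = FALSE)
  invisible(TRUE)
}
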