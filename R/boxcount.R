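#' Default dyadic box-size schedule
#'
#' Powers of two from 1 up to the largest that fits the raster.
#'
#' @param max_px largest admissible box size (typically the tile side).
#' @return Integer vector of box sizes.
#' @export
dyadic_box_sizes <- function(max_px) {
  stopifnot(max_px >= 1)
  2L^(0:floor(log2(max_px)))
}

#' Fixed-grid box counting
#'
#' Counts, for every box size `s`, the number of `s x s` boxes of a fixed
#' grid anchored at the top-left pixel that contain at least one
#' foreground pixel. Partial boxes at the right/bottom edges are counted
#' (irrelevant whenever `s` divides the raster side).
#'
#' @param mask a non-empty [binary_mask()].
#' @param box_sizes_px integer box sizes, each in `[1, max(H, W)]`.
#' @return A `box_count_curve`: list with `box_sizes_px` (ascending),
#'   `counts` and `spacing_um`.
#' @examples
#' m <- generate_ideal_fractal(ideal_fractal_spec("sierpinski_carpet", 3))
#' box_count(m, c(1, 3, 9, 27))$counts
#' @export
box_count <- function(mask, box_sizes_px = dyadic_box_sizes(max(dim(mask$pixels)))) {
  stopifnot(inherits(mask, "binary_mask"))
  M <- mask$pixels
  H <- nrow(M); W <- ncol(M)
  s <- sort(unique(as.integer(box_sizes_px)))
  if (length(s) != length(box_sizes_px))
    stop("duplicate box sizes", call. = FALSE)
  if (any(s < 1L) || any(s > max(H, W)))
    stop("box sizes must lie in [1, max(H, W)]", call. = FALSE)
  idx <- which(M, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("mask is empty: box counting is undefined on blank tiles",
         call. = FALSE)
  counts <- vapply(s, function(si) {
    br <- (idx[, 1] - 1L) %/% si
    bc <- (idx[, 2] - 1L) %/% si
    length(unique(br * (((W - 1L) %/% si) + 1L) + bc))
  }, integer(1))
  structure(list(box_sizes_px = s, counts = counts,
                 spacing_um = mask$spacing_um),
            class = "box_count_curve")
}

#' Scale-resolved fractal dimension from a box-count curve
#'
#' The fractal dimension at scale `s` is the negative local derivative of
#' `log N` with respect to `log s`: central differences at interior box
#' sizes, one-sided differences at the two ends.
#'
#' @param curve a `box_count_curve` from [box_count()] with at least two
#'   box sizes.
#' @return A `fractal_profile`: list with `box_sizes_px`, `df` and
#'   `spacing_um`.
#' @examples
#' m <- generate_ideal_fractal(ideal_fractal_spec("filled_square", 4,
#'                                                size_px = 64))
#' local_dimension(box_count(m, c(1, 2, 4, 8, 16)))$df
#' @export
local_dimension <- function(curve) {
  stopifnot(inherits(curve, "box_count_curve"))
  s <- curve$box_sizes_px
  n <- length(s)
  if (n < 2L) stop("need at least two box sizes", call. = FALSE)
  if (anyDuplicated(s)) stop("duplicate box sizes", call. = FALSE)
  ls <- log(s); ln <- log(curve$counts)
  df <- numeric(n)
  df[1] <- -(ln[2] - ln[1]) / (ls[2] - ls[1])
  df[n] <- -(ln[n] - ln[n - 1]) / (ls[n] - ls[n - 1])
  if (n > 2L) {
    i <- 2:(n - 1)
    df[i] <- -(ln[i + 1] - ln[i - 1]) / (ls[i + 1] - ls[i - 1])
  }
  structure(list(box_sizes_px = s, df = df, spacing_um = curve$spacing_um),
            class = "fractal_profile")
}

#' Read the fractal dimension at a physical scale
#'
#' Converts `scale_um` to pixels using the profile's spacing and returns
#' the dimension at the nearest available box size (ties break to the
#' smaller size). At 0.5 um/px the reference scales 1, 16 and 128 um map
#' to box sizes 2, 32 and 256 px.
#'
#' @param profile a `fractal_profile` from [local_dimension()].
#' @param scale_um requested physical box size in micrometres.
#' @return The dimension (scalar) at the matched box size.
#' @export
df_at_scale <- function(profile, scale_um) {
  stopifnot(inherits(profile, "fractal_profile"))
  target <- scale_um / profile$spacing_um
  s <- profile$box_sizes_px
  if (target < min(s) || target > max(s))
    stop(sprintf(
      "scale %g um (%g px) outside available box-size range [%d, %d] px",
      scale_um, target, min(s), max(s)), call. = FALSE)
  d <- abs(s - target)
  profile$df[order(d, s)[1]]
}

#' @export
print.box_count_curve <- function(x, ...) {
  cat("<box_count_curve>\n")
  print(data.frame(box_size_px = x$box_sizes_px, N = x$counts))
  invisible(x)
}

#' @export
print.fractal_profile <- function(x, ...) {
  cat("<fractal_profile>\n")
  print(data.frame(box_size_px = x$box_sizes_px,
                   box_size_um = x$box_sizes_px * x$spacing_um,
                   df = round(x$df, 4)))
  invisible(x)
}
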