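# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators behave as pure functions of their arguments.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Shoelace area of a closed polygon
#'
#' @param xy two-column matrix of vertices (x, y); the closing edge is
#'   implicit.
#' @return Non-negative area.
#' @keywords internal
#' @noRd
polygon_area <- function(xy) {
  if (is.null(xy) || nrow(xy) < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(seq_len(nrow(xy))[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Clip a polygon to an axis-aligned rectangle (Sutherland-Hodgman)
#'
#' @param xy two-column vertex matrix.
#' @param xlim,ylim rectangle bounds.
#' @return Clipped vertex matrix (possibly with 0 rows).
#' @keywords internal
#' @noRd
clip_polygon_rect <- function(xy, xlim, ylim) {
  clip_halfplane <- function(p, inside, intersect) {
    n <- nrow(p)
    if (n == 0) return(p)
    out <- vector("list", 2L * n)
    k <- 0L
    for (i in seq_len(n)) {
      a <- p[i, ]
      b <- p[if (i == n) 1L else i + 1L, ]
      ia <- inside(a); ib <- inside(b)
      if (ia) {
        k <- k + 1L; out[[k]] <- a
        if (!ib) { k <- k + 1L; out[[k]] <- intersect(a, b) }
      } else if (ib) {
        k <- k + 1L; out[[k]] <- intersect(a, b)
      }
    }
    if (k == 0L) matrix(numeric(0), 0, 2) else do.call(rbind, out[seq_len(k)])
  }
  cross_x <- function(x0) function(a, b) {
    t <- (x0 - a[1]) / (b[1] - a[1])
    c(x0, a[2] + t * (b[2] - a[2]))
  }
  cross_y <- function(y0) function(a, b) {
    t <- (y0 - a[2]) / (b[2] - a[2])
    c(a[1] + t * (b[1] - a[1]), y0)
  }
  p <- xy
  p <- clip_halfplane(p, function(v) v[1] >= xlim[1], cross_x(xlim[1]))
  p <- clip_halfplane(p, function(v) v[1] <= xlim[2], cross_x(xlim[2]))
  p <- clip_halfplane(p, function(v) v[2] >= ylim[1], cross_y(ylim[1]))
  p <- clip_halfplane(p, function(v) v[2] <= ylim[2], cross_y(ylim[2]))
  p
}

stopifnot_scalar_pos <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(what, " must be a single positive number", call. = FALSE)
  invisible(x)
}
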