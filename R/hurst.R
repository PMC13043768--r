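#' Collect the lag (free-space) distribution of a vessel mask
#'
#' A lag is a maximal run of background pixels bounded by vessel
#' foreground on both ends along a scan line. Every row and every column
#' is scanned; runs touching the raster border are not bounded by vessels
#' and are excluded.
#'
#' @param mask a [binary_mask()].
#' @param direction `"both"` (default) pools horizontal and vertical
#'   scans; `"horizontal"` / `"vertical"` restrict to one direction.
#' @return A `lag_distribution`: list with `lag_px` (ascending integers),
#'   `counts` and `spacing_um`. Empty when the mask has no bounded runs.
#' @examples
#' m <- binary_mask(rbind(c(TRUE, FALSE, FALSE, FALSE, TRUE)), 0.5)
#' collect_lags(m, "horizontal")$lag_px  # one lag of 3
#' @export
collect_lags <- function(mask, direction = c("both", "horizontal",
                                             "vertical")) {
  stopifnot(inherits(mask, "binary_mask"))
  direction <- match.arg(direction)
  M <- mask$pixels
  scan_rows <- function(M) {
    gaps <- lapply(seq_len(nrow(M)), function(r) {
      p <- which(M[r, ])
      if (length(p) < 2L) return(integer(0))
      g <- diff(p) - 1L
      g[g > 0L]
    })
    unlist(gaps)
  }
  all_gaps <- switch(direction,
    horizontal = scan_rows(M),
    vertical = scan_rows(t(M)),
    both = c(scan_rows(M), scan_rows(t(M))))
  if (length(all_gaps) == 0L) {
    return(structure(list(lag_px = integer(0), counts = integer(0),
                          spacing_um = mask$spacing_um),
                     class = "lag_distribution"))
  }
  tab <- table(all_gaps)
  structure(list(lag_px = as.integer(names(tab)),
                 counts = as.integer(tab),
                 spacing_um = mask$spacing_um),
            class = "lag_distribution")
}

#' Fit the Hurst index to a lag distribution
#'
#' Ordinary least squares of `log10(count)` on `log10(lag)` over the lags
#' with positive counts inside a physical window (default 20-200 um, i.e.
#' 40-400 px at 0.5 um/px). The falling histogram has negative slope; by
#' convention the Hurst index is reported as `H = |slope| / 2`, so the
#' anti-persistent regime corresponds to fitted magnitudes `2H` below 1.
#'
#' @param dist a `lag_distribution` from [collect_lags()].
#' @param window_um two-element fit window in micrometres.
#' @param weighted if `TRUE`, weight each lag by its count.
#' @return A `hurst_estimate`: list with `H`, `slope`, `intercept`,
#'   `fit_window_um`, `n_points`, `r_squared`.
#' @examples
#' p <- generate_powerlaw_gap_pattern(0.5, 10, 60, 128, count_at_min = 50)
#' fit_hurst(collect_lags(p, "horizontal"), window_um = c(10, 60))$H
#' @export
fit_hurst <- function(dist, window_um = c(20, 200), weighted = FALSE) {
  stopifnot(inherits(dist, "lag_distribution"), length(window_um) == 2,
            window_um[1] < window_um[2])
  lo <- window_um[1] / dist$spacing_um
  hi <- window_um[2] / dist$spacing_um
  sel <- dist$lag_px >= lo & dist$lag_px <= hi & dist$counts > 0L
  lag <- dist$lag_px[sel]
  cnt <- dist$counts[sel]
  if (length(lag) < 3L)
    stop(sprintf(
      paste0("fewer than 3 usable lags in the fit window [%g, %g] um ",
             "(%g-%g px); available in-window lags: %d"),
      window_um[1], window_um[2], lo, hi, length(lag)), call. = FALSE)
  x <- log10(lag); y <- log10(cnt)
  fit <- if (weighted) stats::lm(y ~ x, weights = cnt) else stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  structure(list(H = abs(slope) / 2,
                 slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 fit_window_um = as.numeric(window_um),
                 n_points = length(lag),
                 r_squared = suppressWarnings(summary(fit)$r.squared)),
            class = "hurst_estimate")
}

#' Pool several lag distributions
#'
#' Sums counts lag-by-lag; used to merge the tiles of one annotated
#' region so the Hurst fit sees enough long lags.
#'
#' @param dists list of `lag_distribution`s sharing one spacing.
#' @return A pooled `lag_distribution`.
#' @export
pool_lag_distributions <- function(dists) {
  stopifnot(length(dists) >= 1,
            all(vapply(dists, inherits, logical(1), "lag_distribution")))
  sp <- unique(vapply(dists, `[[`, numeric(1), "spacing_um"))
  if (length(sp) != 1L) stop("mixed pixel spacings", call. = FALSE)
  lag <- unlist(lapply(dists, `[[`, "lag_px"))
  cnt <- unlist(lapply(dists, `[[`, "counts"))
  if (length(lag) == 0L)
    return(structure(list(lag_px = integer(0), counts = integer(0),
                          spacing_um = sp), class = "lag_distribution"))
  agg <- rowsum(cnt, lag)
  structure(list(lag_px = as.integer(rownames(agg)),
                 counts = as.integer(agg[, 1]),
                 spacing_um = sp),
            class = "lag_distribution")
}

#' @export
print.lag_distribution <- function(x, ...) {
  cat(sprintf("<lag_distribution> %d distinct lags, %d runs @ %g um/px\n",
              length(x$lag_px), sum(x$counts), x$spacing_um))
  invisible(x)
}

#' @export
print.hurst_estimate <- function(x, ...) {
  cat(sprintf(
    "<hurst_estimate> H = %.4f (2H = %.4f), window %g-%g um, n = %d, R2 = %.3f\n",
    x$H, abs(x$slope), x$fit_window_um[1], x$fit_window_um[2],
    x$n_points, x$r_squared))
  invisible(x)
}
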