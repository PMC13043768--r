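REGION_LABELS <- c("tumoral", "peritumoral", "non_tumoral", "necrotic")

#' Region annotation of a slide
#'
#' Polygons in slide pixel coordinates (origin top-left, x = column,
#' y = row) labelled with the histological vocabulary `tumoral`,
#' `peritumoral`, `non_tumoral`, `necrotic`, plus a per-slide vascular
#' invasion status.
#'
#' @param polygons list of `list(label = <chr>, coords = <n x 2 matrix>)`
#'   where `coords` columns are (x, y); the ring closes implicitly.
#' @param vi_status `"VI+"`, `"VI-"` or `"unknown"`.
#' @return A `region_annotation` list.
#' @export
region_annotation <- function(polygons, vi_status = "unknown") {
  stopifnot(is.list(polygons),
            vi_status %in% c("VI+", "VI-", "unknown"))
  for (p in polygons) {
    if (!p$label %in% REGION_LABELS)
      stop("unknown region label: ", p$label, call. = FALSE)
    if (!is.matrix(p$coords) || ncol(p$coords) != 2 || nrow(p$coords) < 3)
      stop("each polygon needs an n x 2 coordinate matrix, n >= 3",
           call. = FALSE)
  }
  structure(list(polygons = polygons, vi_status = vi_status),
            class = "region_annotation")
}

#' Read a GeoJSON region annotation
#'
#' Expects a FeatureCollection of Polygon features in pixel coordinates
#' whose label sits in `properties.classification` (either a string or an
#' object with a `name`, the common digital-pathology convention).
#' An optional top-level or per-feature `vi_status` property carries the
#' vascular-invasion status.
#'
#' @param path GeoJSON file.
#' @return A [region_annotation()].
#' @export
read_region_annotation <- function(path) {
  j <- jsonlite::read_json(path)
  feats <- j$features %||% list()
  polys <- lapply(feats, function(f) {
    cls <- f$properties$classification
    label <- if (is.list(cls)) cls$name else cls
    ring <- f$geometry$coordinates[[1]]
    coords <- do.call(rbind, lapply(ring, function(pt)
      c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))))
    # drop an explicitly closed ring's duplicate last vertex
    if (nrow(coords) > 1 && all(coords[1, ] == coords[nrow(coords), ]))
      coords <- coords[-nrow(coords), , drop = FALSE]
    list(label = label, coords = coords)
  })
  vi <- j$vi_status %||%
    (if (length(feats) > 0) feats[[1]]$properties$vi_status else NULL) %||%
    "unknown"
  region_annotation(polys, vi)
}

#' Cut a slide into non-overlapping tiles
#'
#' Grid anchored at the top-left pixel; partial tiles at the right/bottom
#' edges are dropped.
#'
#' @param slide an [rgb_tile()] (possibly whole-slide sized).
#' @param tile_px tile side in pixels (>= 64).
#' @return List of `list(origin = c(row, col), tile = rgb_tile)` with
#'   0-based pixel origins.
#' @export
tile_image <- function(slide, tile_px = 1024L) {
  stopifnot(inherits(slide, "rgb_tile"), tile_px >= 64)
  d <- dim(slide$pixels)
  nr <- d[1] %/% tile_px
  nc <- d[2] %/% tile_px
  if (nr < 1L || nc < 1L)
    stop("slide smaller than one tile", call. = FALSE)
  out <- vector("list", nr * nc)
  k <- 0L
  for (i in seq_len(nr) - 1L) {
    for (j in seq_len(nc) - 1L) {
      k <- k + 1L
      px <- slide$pixels[(i * tile_px + 1L):((i + 1L) * tile_px),
                         (j * tile_px + 1L):((j + 1L) * tile_px), ,
                         drop = FALSE]
      out[[k]] <- list(origin = c(row = i * tile_px, col = j * tile_px),
                       tile = rgb_tile(px, slide$spacing_um))
    }
  }
  out
}

#' Assign a tile to an annotated region
#'
#' The tile gets the label whose polygons cover at least `min_overlap` of
#' its area. Any positive overlap with a necrotic polygon excludes the
#' tile outright (`necrotic_excluded`); a tile dominated by no single
#' label is excluded as `transition_zone`.
#'
#' @param origin 0-based `c(row, col)` pixel origin of the tile.
#' @param tile_px tile side in pixels.
#' @param annotation a [region_annotation()].
#' @param min_overlap required covered area fraction (default 0.95).
#' @return `list(label = <chr or NA>, qc_flags = <chr vector>)`.
#' @export
assign_region <- function(origin, tile_px, annotation, min_overlap = 0.95) {
  stopifnot(inherits(annotation, "region_annotation"))
  xlim <- c(origin[["col"]], origin[["col"]] + tile_px)
  ylim <- c(origin[["row"]], origin[["row"]] + tile_px)
  tile_area <- as.numeric(tile_px)^2
  cov <- setNames(numeric(length(REGION_LABELS)), REGION_LABELS)
  for (p in annotation$polygons) {
    a <- polygon_area(clip_polygon_rect(p$coords, xlim, ylim))
    cov[p$label] <- cov[p$label] + a / tile_area
  }
  if (cov[["necrotic"]] > 1e-9)
    return(list(label = NA_character_, qc_flags = "necrotic_excluded"))
  cov <- cov[setdiff(REGION_LABELS, "necrotic")]
  best <- which.max(cov)
  if (cov[best] >= min_overlap)
    return(list(label = names(cov)[best], qc_flags = character(0)))
  list(label = NA_character_, qc_flags = "transition_zone")
}

#' Reconstruct the slide-level fractal-dimension map
#'
#' One pixel per tile, valued with the tile's dimension at the requested
#' physical scale; excluded or blank tiles are `NA`.
#'
#' @param records list of tile records as produced by [run_pipeline()]
#'   (each holding `slide_id`, `origin`, `tile_px`, `df_profile`,
#'   `qc_flags`).
#' @param scale_um physical box size passed to [df_at_scale()].
#' @return Numeric matrix (rows x cols of the tile grid).
#' @export
reconstruct_df_map <- function(records, scale_um) {
  if (length(records) == 0L) stop("no records", call. = FALSE)
  sid <- unique(vapply(records, `[[`, character(1), "slide_id"))
  if (length(sid) != 1L)
    stop("records mix slides: ", paste(sid, collapse = ", "), call. = FALSE)
  tp <- unique(vapply(records, `[[`, numeric(1), "tile_px"))
  if (length(tp) != 1L) stop("records mix tile sizes", call. = FALSE)
  rows <- vapply(records, function(r) r$origin[["row"]], numeric(1)) / tp
  cols <- vapply(records, function(r) r$origin[["col"]], numeric(1)) / tp
  m <- matrix(NA_real_, max(rows) + 1L, max(cols) + 1L)
  for (k in seq_along(records)) {
    rec <- records[[k]]
    if (length(rec$qc_flags) > 0L || is.null(rec$df_profile)) next
    m[rows[k] + 1L, cols[k] + 1L] <- df_at_scale(rec$df_profile, scale_um)
  }
  m
}

significance_band <- function(p) {
  if (p < 0.001) "highly_significant"
  else if (p < 0.05) "significant"
  else if (p > 0.1) "not_significant"
  else "indeterminate"
}

#' Mann-Whitney comparison of two tile-metric groups
#'
#' Two-sided Mann-Whitney U test: exact null distribution when the pooled
#' sample size is at most 20 and there are no ties, normal approximation
#' with tie and continuity correction otherwise. The p value is banded
#' into `highly_significant` (p < 0.001), `significant`
#' (0.001 <= p < 0.05), `not_significant` (p > 0.1) or `indeterminate`
#' (0.05 <= p <= 0.1).
#'
#' @param values_a,values_b numeric samples, each of size >= 3.
#' @param group_a,group_b optional group labels carried into the result.
#' @return A `group_comparison`: list with `group_a`, `group_b`, `n_a`,
#'   `n_b`, `u_statistic`, `p_value`, `significance_band`.
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6))$p_value  # exact: 0.1
#' @export
compare_groups <- function(values_a, values_b,
                           group_a = "a", group_b = "b") {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (length(values_a) < 3L || length(values_b) < 3L)
    stop("each group needs at least 3 finite values", call. = FALSE)
  exact <- length(values_a) + length(values_b) <= 20L
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, exact = exact, correct = TRUE))
  structure(list(group_a = group_a, group_b = group_b,
                 n_a = length(values_a), n_b = length(values_b),
                 u_statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 significance_band = significance_band(wt$p.value)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (n=%d) vs %s (n=%d): U = %g, p = %.4g [%s]\n",
              x$group_a, x$n_a, x$group_b, x$n_b, x$u_statistic, x$p_value,
              x$significance_band))
  invisible(x)
}
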