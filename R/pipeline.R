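#' Pipeline configuration
#'
#' Bundles every knob of the slide-level analysis.
#'
#' @param tile_px tile side in pixels.
#' @param spacing_um micrometres per pixel.
#' @param seg_params a [segmentation_params()].
#' @param box_sizes_px box-size schedule; default dyadic up to `tile_px`.
#' @param hurst_window_um Hurst fit window in micrometres.
#' @param min_overlap region-assignment coverage threshold.
#' @param scales_um physical scales reported per tile.
#' @param compare_scale_um scale used for group comparisons.
#' @param min_size_px minimum component size for shape statistics.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(tile_px = 1024L, spacing_um = 0.5,
                            seg_params = segmentation_params(),
                            box_sizes_px = NULL,
                            hurst_window_um = c(20, 200),
                            min_overlap = 0.95,
                            scales_um = c(1, 16, 128),
                            compare_scale_um = 16,
                            min_size_px = 4L) {
  structure(list(
    tile_px = as.integer(tile_px), spacing_um = spacing_um,
    seg_params = seg_params,
    box_sizes_px = box_sizes_px %||% dyadic_box_sizes(tile_px),
    hurst_window_um = hurst_window_um, min_overlap = min_overlap,
    scales_um = scales_um, compare_scale_um = compare_scale_um,
    min_size_px = as.integer(min_size_px)
  ), class = "pipeline_config")
}

#' Run the slide-level vascular-architecture pipeline
#'
#' For every slide: tile, assign each tile to its annotated region,
#' segment vessels, compute the scale-resolved fractal dimension and the
#' per-tile lag distribution, then pool lags per (slide, region) for the
#' Hurst fit and compare regions tile-wise with Mann-Whitney tests at
#' `config$compare_scale_um`. Necrotic-overlapping, transition-zone and
#' blank tiles are flagged and never enter group statistics. Per-tile
#' failures are caught, flagged `error` and logged; the batch never
#' aborts. The run is deterministic: identical inputs and config give
#' identical outputs.
#'
#' @param slides named list of [rgb_tile()]s or image paths (PNG/TIFF).
#' @param annotations named list (same names) of [region_annotation()]s
#'   or GeoJSON paths; `NULL` entries leave tiles `unlabelled`.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; when given, writes
#'   `tiles.csv`, `comparisons.csv`, `hurst.csv`, one
#'   `df_map_<slide>_<scale>um.png` per slide and scale, and `run.log`.
#' @return (Invisibly) a list with `records` (per-tile detail),
#'   `tiles` (data frame), `hurst` (per slide x region), `comparisons`
#'   (data frame) and `df_maps` (nested list of matrices).
#' @export
run_pipeline <- function(slides, annotations = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(names(slides)) || any(names(slides) == ""))
    names(slides) <- paste0("slide", seq_along(slides))
  log_lines <- c("vesselfractal pipeline run",
                 paste0("package version: ",
                        as.character(utils::packageVersion("vesselfractal"))),
                 paste0("tile_px=", config$tile_px,
                        " spacing_um=", config$spacing_um,
                        " min_overlap=", config$min_overlap,
                        " compare_scale_um=", config$compare_scale_um),
                 paste0("box_sizes_px=",
                        paste(config$box_sizes_px, collapse = ",")),
                 paste0("hurst_window_um=",
                        paste(config$hurst_window_um, collapse = "-")))

  records <- list()
  for (sid in names(slides)) {
    slide <- slides[[sid]]
    if (is.character(slide)) slide <- read_tile(slide, config$spacing_um)
    ann <- annotations[[sid]]
    if (is.character(ann)) ann <- read_region_annotation(ann)
    tiles <- tile_image(slide, config$tile_px)
    for (tl in tiles) {
      rec <- list(slide_id = sid, origin = tl$origin,
                  tile_px = config$tile_px,
                  region_label = "unlabelled",
                  vi_status = if (is.null(ann)) "unknown" else ann$vi_status,
                  qc_flags = character(0),
                  df_profile = NULL, lag_dist = NULL,
                  fg_fraction = NA_real_, n_components = NA_integer_)
      if (!is.null(ann)) {
        asg <- assign_region(tl$origin, config$tile_px, ann,
                             config$min_overlap)
        rec$region_label <- if (is.na(asg$label)) "excluded" else asg$label
        rec$qc_flags <- asg$qc_flags
      }
      rec <- tryCatch({
        m <- segment_vessels(tl$tile, config$seg_params)
        rec$fg_fraction <- mean(m$pixels)
        if (!any(m$pixels)) {
          rec$qc_flags <- union(rec$qc_flags, "blank")
        } else {
          rec$df_profile <- local_dimension(box_count(m, config$box_sizes_px))
          rec$lag_dist <- collect_lags(m)
          rec$n_components <- nrow(extract_components(m, config$min_size_px))
        }
        rec
      }, error = function(e) {
        rec$qc_flags <- union(rec$qc_flags, "error")
        log_lines <<- c(log_lines,
                        sprintf("tile %s (%d,%d) failed: %s", sid,
                                tl$origin[["row"]], tl$origin[["col"]],
                                conditionMessage(e)))
        rec
      })
      records[[length(records) + 1L]] <- rec
    }
  }

  ok <- vapply(records, function(r) length(r$qc_flags) == 0L &&
                 !is.null(r$df_profile), logical(1))

  # per-tile table
  tiles_df <- do.call(rbind, lapply(seq_along(records), function(k) {
    r <- records[[k]]
    row <- data.frame(slide = r$slide_id, tile_row = r$origin[["row"]],
                      tile_col = r$origin[["col"]],
                      region = r$region_label, vi_status = r$vi_status,
                      qc_flags = paste(r$qc_flags, collapse = ";"),
                      fg_fraction = r$fg_fraction,
                      n_components = r$n_components)
    for (sc in config$scales_um) {
      row[[sprintf("df_%gum", sc)]] <- if (ok[k])
        df_at_scale(r$df_profile, sc) else NA_real_
    }
    row
  }))

  # Hurst per slide x region on pooled lags
  hurst_rows <- list()
  keys <- unique(lapply(records[ok], function(r)
    c(r$slide_id, r$region_label)))
  for (key in keys) {
    sel <- records[ok]
    sel <- sel[vapply(sel, function(r)
      r$slide_id == key[1] && r$region_label == key[2], logical(1))]
    pooled <- pool_lag_distributions(lapply(sel, `[[`, "lag_dist"))
    hres <- tryCatch(fit_hurst(pooled, config$hurst_window_um),
                     error = function(e) NULL)
    hurst_rows[[length(hurst_rows) + 1L]] <- data.frame(
      slide = key[1], region = key[2], n_tiles = length(sel),
      H = if (is.null(hres)) NA_real_ else hres$H,
      slope = if (is.null(hres)) NA_real_ else hres$slope,
      r_squared = if (is.null(hres)) NA_real_ else hres$r_squared)
  }
  hurst_df <- if (length(hurst_rows)) do.call(rbind, hurst_rows) else NULL

  # group comparisons on df at the comparison scale
  metric <- vapply(seq_along(records), function(k) {
    if (ok[k]) df_at_scale(records[[k]]$df_profile, config$compare_scale_um)
    else NA_real_
  }, numeric(1))
  region <- vapply(records, `[[`, character(1), "region_label")
  vi <- vapply(records, `[[`, character(1), "vi_status")
  cmp_rows <- list()
  add_cmp <- function(va, vb, la, lb) {
    if (sum(is.finite(va)) >= 3L && sum(is.finite(vb)) >= 3L) {
      gc <- compare_groups(va, vb, la, lb)
      cmp_rows[[length(cmp_rows) + 1L]] <<- data.frame(
        group_a = la, group_b = lb, n_a = gc$n_a, n_b = gc$n_b,
        u_statistic = gc$u_statistic, p_value = gc$p_value,
        significance_band = gc$significance_band)
    }
  }
  present <- intersect(c("non_tumoral", "peritumoral", "tumoral"),
                       unique(region[ok]))
  if (length(present) >= 2L) {
    prs <- utils::combn(present, 2L)
    for (j in seq_len(ncol(prs))) {
      a <- prs[1, j]; b <- prs[2, j]
      add_cmp(metric[ok & region == a], metric[ok & region == b], a, b)
    }
  }
  for (zone in c("tumoral", "peritumoral")) {
    add_cmp(metric[ok & region == zone & vi == "VI+"],
            metric[ok & region == zone & vi == "VI-"],
            paste0(zone, "_VI+"), paste0(zone, "_VI-"))
  }
  cmp_df <- if (length(cmp_rows)) do.call(rbind, cmp_rows) else NULL

  # df maps
  df_maps <- lapply(split(records, vapply(records, `[[`, character(1),
                                          "slide_id")),
                    function(rs) {
    lapply(setNames(config$scales_um, sprintf("%gum", config$scales_um)),
           function(sc) reconstruct_df_map(rs, sc))
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tiles_df, file.path(out_dir, "tiles.csv"),
                     row.names = FALSE)
    if (!is.null(cmp_df))
      utils::write.csv(cmp_df, file.path(out_dir, "comparisons.csv"),
                       row.names = FALSE)
    if (!is.null(hurst_df))
      utils::write.csv(hurst_df, file.path(out_dir, "hurst.csv"),
                       row.names = FALSE)
    for (sid in names(df_maps)) {
      for (sc in names(df_maps[[sid]])) {
        m <- df_maps[[sid]][[sc]]
        img <- m / 2          # dimension in [0,2] -> grey in [0,1]
        img[!is.finite(img)] <- 0
        png::writePNG(clamp(img, 0, 1),
                      file.path(out_dir,
                                sprintf("df_map_%s_%s.png", sid, sc)))
      }
    }
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }

  invisible(list(records = records, tiles = tiles_df, hurst = hurst_df,
                 comparisons = cmp_df, df_maps = df_maps))
}
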