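#' Specify a synthetic vessel population
#'
#' Describes the vessel content, colours and noise of one synthetic
#' DAB-like histology tile. The defaults emulate CD31/DAB staining with a
#' hematoxylin-counterstained pale-blue background: vessels are rendered
#' in DAB brown (hue 20-40 degrees), small vessels are round lumina,
#' large vessels are elongated and optionally tortuous tubes, and debris
#' specks reproduce chromogen noise. Vessel centres can be drawn from a
#' multiplicative-cascade density (`clustering` > 0) so that free space
#' between vessels spans many scales, as in lobular liver parenchyma.
#'
#' @param n_small_round number of small round vessels.
#' @param small_radius_range radius interval of small vessels, um.
#' @param n_large number of large vessels.
#' @param large_axis_range major-axis interval of large vessels, um.
#' @param elongation_range major/minor axis ratio interval (>= 1).
#' @param tortuosity >= 0; 0 renders straight ellipses, larger values bend
#'   the centreline of large vessels by a random walk.
#' @param clustering 0-1; 0 places vessel centres uniformly, larger values
#'   concentrate them on a hierarchical (quadtree cascade) density.
#' @param brown_color_mean mean vessel RGB (0-255).
#' @param brown_color_jitter per-channel jitter SD.
#' @param background_color background RGB (0-255).
#' @param debris_density brown specks per mm^2 (not part of ground truth).
#' @param diffuse_brown_level 0-1 blend of the background towards brown,
#'   mimicking diffusely stained necrotic tissue.
#' @param seed integer RNG seed; same spec + seed gives bit-identical tiles.
#' @return A `vessel_population_spec` list.
#' @seealso [generate_vessel_tile()]
#' @export
vessel_population_spec <- function(n_small_round = 80,
                                   small_radius_range = c(2, 6),
                                   n_large = 3,
                                   large_axis_range = c(40, 120),
                                   elongation_range = c(2, 5),
                                   tortuosity = 0.3,
                                   clustering = 0.5,
                                   brown_color_mean = c(140, 95, 55),
                                   brown_color_jitter = c(10, 10, 10),
                                   background_color = c(200, 205, 235),
                                   debris_density = 20,
                                   diffuse_brown_level = 0,
                                   seed = 1L) {
  stopifnot(
    n_small_round >= 0, n_large >= 0,
    length(small_radius_range) == 2, all(small_radius_range > 0),
    diff(small_radius_range) >= 0,
    length(large_axis_range) == 2, all(large_axis_range > 0),
    diff(large_axis_range) >= 0,
    all(elongation_range >= 1), diff(elongation_range) >= 0,
    tortuosity >= 0, clustering >= 0, clustering <= 1,
    all(brown_color_mean >= 0 & brown_color_mean <= 255),
    all(background_color >= 0 & background_color <= 255),
    debris_density >= 0,
    diffuse_brown_level >= 0, diffuse_brown_level <= 1
  )
  structure(list(
    n_small_round = as.integer(n_small_round),
    small_radius_range = as.numeric(small_radius_range),
    n_large = as.integer(n_large),
    large_axis_range = as.numeric(large_axis_range),
    elongation_range = as.numeric(elongation_range),
    tortuosity = tortuosity, clustering = clustering,
    brown_color_mean = brown_color_mean,
    brown_color_jitter = brown_color_jitter,
    background_color = background_color,
    debris_density = debris_density,
    diffuse_brown_level = diffuse_brown_level,
    seed = as.integer(seed)
  ), class = "vessel_population_spec")
}

#' Preset population specs for the architectural phenotypes
#'
#' `non_tumoral_like_spec()` emulates normal parenchyma: a dense
#' population of small round open lumina (sinusoids) on a clustered
#' lobular layout, with a few larger vessels. `tumoral_like_spec()`
#' emulates tumour tissue: fewer round vessels and many thin, elongated,
#' slit-like channels laid out homogeneously (weak hierarchy).
#' `peritumoral_like_spec()` sits between the two. The presets are
#' ordered in small-round-vessel enrichment (non-tumoral > peritumoral >
#' tumoral), which orders their fractal dimension at mesoscopic scales
#' the same way.
#'
#' @param seed RNG seed.
#' @param ... overrides passed to [vessel_population_spec()].
#' @return A `vessel_population_spec`.
#' @export
non_tumoral_like_spec <- function(seed = 1L, ...) {
  args <- list(n_small_round = 350, small_radius_range = c(3, 7),
               n_large = 2, large_axis_range = c(60, 140),
               elongation_range = c(2, 4), tortuosity = 0.3,
               clustering = 0.6, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(vessel_population_spec, args)
}

#' @rdname non_tumoral_like_spec
#' @export
tumoral_like_spec <- function(seed = 1L, ...) {
  args <- list(n_small_round = 40, small_radius_range = c(2, 5),
               n_large = 60, large_axis_range = c(40, 100),
               elongation_range = c(15, 30), tortuosity = 0.5,
               clustering = 0.15, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(vessel_population_spec, args)
}

#' @rdname non_tumoral_like_spec
#' @export
peritumoral_like_spec <- function(seed = 1L, ...) {
  args <- list(n_small_round = 180, small_radius_range = c(2.5, 6),
               n_large = 28, large_axis_range = c(50, 120),
               elongation_range = c(8, 16), tortuosity = 0.4,
               clustering = 0.4, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(vessel_population_spec, args)
}

# ---- rasterization helpers (exact, no anti-aliasing) ----

# linear (column-major) indices of a disk clipped to the raster
raster_disk <- function(cy, cx, r, H, W) {
  r0 <- max(1L, floor(cy - r)); r1 <- min(H, ceiling(cy + r))
  c0 <- max(1L, floor(cx - r)); c1 <- min(W, ceiling(cx + r))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rows <- r0:r1; cols <- c0:c1
  dr2 <- (rows - cy)^2
  dc2 <- (cols - cx)^2
  inside <- outer(dr2, dc2, "+") <= r^2
  idx <- which(inside)
  ((cols[(idx - 1L) %/% length(rows) + 1L] - 1L) * H +
     rows[(idx - 1L) %% length(rows) + 1L])
}

raster_ellipse <- function(cy, cx, a, b, theta, H, W) {
  r0 <- max(1L, floor(cy - a)); r1 <- min(H, ceiling(cy + a))
  c0 <- max(1L, floor(cx - a)); c1 <- min(W, ceiling(cx + a))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rows <- r0:r1; cols <- c0:c1
  dy <- matrix(rows - cy, length(rows), length(cols))
  dx <- matrix(cols - cx, length(rows), length(cols), byrow = TRUE)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  idx <- which(inside)
  ((cols[(idx - 1L) %/% length(rows) + 1L] - 1L) * H +
     rows[(idx - 1L) %% length(rows) + 1L])
}

# tortuous tube: random-walk centreline stamped with disks
raster_tube <- function(cy, cx, length_px, radius, tortuosity, H, W) {
  n_step <- max(2L, ceiling(length_px))
  theta <- runif(1, 0, 2 * pi) + cumsum(rnorm(n_step, 0, tortuosity * 0.25))
  py <- cy + cumsum(sin(theta)) - sum(sin(theta)) / 2
  px <- cx + cumsum(cos(theta)) - sum(cos(theta)) / 2
  keep <- seq(1L, n_step, by = max(1L, floor(radius / 2)))
  keep <- union(keep, n_step)
  idx <- unlist(lapply(keep, function(i) raster_disk(py[i], px[i], radius, H, W)))
  unique(idx)
}

# quadtree multiplicative-cascade sampler for vessel centres; depth grows
# with tile size so the coarsest void scale tracks the field of view
sample_centers <- function(n, size_px, clustering,
                           depth = max(4L, floor(log2(size_px / 64)))) {
  if (n == 0L) return(cbind(row = numeric(0), col = numeric(0)))
  if (clustering <= 0) {
    return(cbind(row = runif(n, 1, size_px), col = runif(n, 1, size_px)))
  }
  alpha <- max(0.05, (1 - clustering) / clustering)
  P <- matrix(1, 1, 1)
  for (d in seq_len(depth)) {
    k <- nrow(P)
    W4 <- array(stats::rgamma(4 * k * k, shape = alpha) + 1e-12, c(k, k, 4))
    Ws <- W4[, , 1] + W4[, , 2] + W4[, , 3] + W4[, , 4]
    Q <- matrix(0, 2 * k, 2 * k)
    Q[seq(1, 2 * k, 2), seq(1, 2 * k, 2)] <- P * W4[, , 1] / Ws
    Q[seq(2, 2 * k, 2), seq(1, 2 * k, 2)] <- P * W4[, , 2] / Ws
    Q[seq(1, 2 * k, 2), seq(2, 2 * k, 2)] <- P * W4[, , 3] / Ws
    Q[seq(2, 2 * k, 2), seq(2, 2 * k, 2)] <- P * W4[, , 4] / Ws
    P <- Q
  }
  nc <- nrow(P)
  cs <- size_px / nc
  cell <- sample.int(length(P), n, replace = TRUE, prob = as.vector(P))
  ri <- (cell - 1L) %% nc
  ci <- (cell - 1L) %/% nc
  cbind(row = ri * cs + runif(n, 1, cs), col = ci * cs + runif(n, 1, cs))
}

# vectorized HSV -> RGB for hue restricted to [0, 60) degrees
hsv_band_to_rgb <- function(h_deg, s, v255) {
  C <- v255 * s
  X <- C * (h_deg / 60)
  m <- v255 - C
  rbind(v255, X + m, m)
}

#' Render a synthetic DAB histology tile with ground truth
#'
#' Draws the vessel population of `spec` onto a `size_px` x `size_px`
#' canvas. The returned mask is the exact union of the rasterized vessel
#' interiors (no anti-aliasing); debris specks and diffuse brown appear in
#' the RGB tile only. Vessel pixel colours are jittered around
#' `brown_color_mean` and then constrained to the DAB hue band
#' (20-40 degrees, value 90-180) so the colour gate of
#' [segment_vessels()] applies. Placement avoids overlaps by bounded
#' retry; if a vessel cannot be placed after 40 attempts it is skipped and
#' the result carries `attr(, "placement_incomplete") = TRUE`.
#'
#' @param spec a [vessel_population_spec()].
#' @param size_px tile side in pixels (>= 64).
#' @param spacing_um micrometres per pixel.
#' @return A list with elements `tile` ([rgb_tile()]) and `mask`
#'   ([binary_mask()]).
#' @examples
#' out <- generate_vessel_tile(vessel_population_spec(n_small_round = 10,
#'   n_large = 0, debris_density = 0, seed = 7), size_px = 128)
#' mean(out$mask$pixels)
#' @export
generate_vessel_tile <- function(spec, size_px, spacing_um = 0.5) {
  stopifnot(inherits(spec, "vessel_population_spec"), size_px >= 64)
  stopifnot_scalar_pos(spacing_um, "spacing_um")
  H <- W <- as.integer(size_px)
  with_seed(spec$seed, {
    mask <- matrix(FALSE, H, W)
    incomplete <- FALSE

    # shape inventory: large vessels first so they find room
    shapes <- list()
    if (spec$n_large > 0) {
      for (i in seq_len(spec$n_large)) {
        major <- runif(1, spec$large_axis_range[1], spec$large_axis_range[2]) /
          spacing_um
        elong <- runif(1, spec$elongation_range[1], spec$elongation_range[2])
        shapes[[length(shapes) + 1L]] <-
          list(kind = "large", major = major, minor = major / elong)
      }
    }
    if (spec$n_small_round > 0) {
      for (i in seq_len(spec$n_small_round)) {
        r <- runif(1, spec$small_radius_range[1], spec$small_radius_range[2]) /
          spacing_um
        shapes[[length(shapes) + 1L]] <- list(kind = "small", r = r)
      }
    }

    n_sh <- length(shapes)
    if (n_sh > 0) {
      centers <- sample_centers(n_sh, size_px, spec$clustering)
      for (i in seq_len(n_sh)) {
        sh <- shapes[[i]]
        placed <- FALSE
        cy <- centers[i, 1]; cx <- centers[i, 2]
        for (try in 1:40) {
          idx <- if (sh$kind == "small") {
            raster_disk(cy, cx, sh$r, H, W)
          } else if (spec$tortuosity > 0) {
            raster_tube(cy, cx, sh$major, sh$minor / 2, spec$tortuosity, H, W)
          } else {
            raster_ellipse(cy, cx, sh$major / 2, sh$minor / 2,
                           runif(1, 0, pi), H, W)
          }
          if (length(idx) > 0 && !any(mask[idx])) {
            mask[idx] <- TRUE
            placed <- TRUE
            break
          }
          nxt <- sample_centers(1L, size_px, spec$clustering)
          cy <- nxt[1, 1]; cx <- nxt[1, 2]
        }
        if (!placed) incomplete <- TRUE
      }
    }

    # ---- RGB rendering ----
    bg <- spec$background_color * (1 - spec$diffuse_brown_level) +
      spec$brown_color_mean * spec$diffuse_brown_level
    px <- array(0, dim = c(H, W, 3))
    for (ch in 1:3) px[, , ch] <- bg[ch] + rnorm(H * W, 0, 2)

    paint_brown <- function(px, idx) {
      n <- length(idx)
      if (n == 0) return(px)
      raw <- rbind(rnorm(n, spec$brown_color_mean[1], spec$brown_color_jitter[1]),
                   rnorm(n, spec$brown_color_mean[2], spec$brown_color_jitter[2]),
                   rnorm(n, spec$brown_color_mean[3], spec$brown_color_jitter[3]))
      raw <- clamp(raw, 1, 254)
      hsv <- grDevices::rgb2hsv(raw, maxColorValue = 255)
      h <- clamp(hsv[1, ] * 360, 21, 39)
      s <- clamp(hsv[2, ], 0.4, 0.85)
      v <- clamp(hsv[3, ] * 255, 90, 180)
      rgb <- hsv_band_to_rgb(h, s, v)
      HW <- dim(px)[1] * dim(px)[2]
      px[idx] <- rgb[1, ]
      px[idx + HW] <- rgb[2, ]
      px[idx + 2 * HW] <- rgb[3, ]
      px
    }
    px <- paint_brown(px, which(mask))

    # debris: 1-3 px brown specks, RGB only, never in the ground truth
    area_mm2 <- (H * spacing_um / 1000) * (W * spacing_um / 1000)
    n_deb <- stats::rpois(1, spec$debris_density * area_mm2)
    if (n_deb > 0) {
      didx <- integer(0)
      dy <- runif(n_deb, 1, H); dx <- runif(n_deb, 1, W)
      sz <- sample(1:3, n_deb, replace = TRUE)
      for (i in seq_len(n_deb))
        didx <- c(didx, raster_disk(dy[i], dx[i], sz[i] / 2, H, W))
      px <- paint_brown(px, unique(didx))
    }

    tile <- rgb_tile(px, spacing_um)
    out <- list(tile = tile, mask = binary_mask(mask, spacing_um))
    attr(out, "placement_incomplete") <- incomplete
    if (incomplete)
      warning("some vessels could not be placed without overlap; ",
              "tile rendered with partial population", call. = FALSE)
    out
  })
}

#' Specify an ideal test fractal
#'
#' @param family one of `"sierpinski_carpet"`, `"vicsek"`,
#'   `"filled_square"`, `"line"`, `"single_pixel"`.
#' @param level recursion level (>= 0, capped at 8). The two self-similar
#'   families are rendered on a `3^level` raster; the degenerate families
#'   use `size_px` (default `3^level`).
#' @param size_px optional raster side for the non-self-similar families.
#' @return An `ideal_fractal_spec` list.
#' @export
ideal_fractal_spec <- function(family = c("sierpinski_carpet", "vicsek",
                                          "filled_square", "line",
                                          "single_pixel"),
                               level = 1L, size_px = NULL) {
  family <- match.arg(family)
  level <- as.integer(level)
  if (level < 0L || level > 8L)
    stop("level must be between 0 and 8", call. = FALSE)
  structure(list(family = family, level = level, size_px = size_px),
            class = "ideal_fractal_spec")
}

#' Generate an ideal fractal raster of known dimension
#'
#' Self-similar constructions for box-counting oracles: the Sierpinski
#' carpet (dimension log 8 / log 3) and the Vicsek cross fractal
#' (log 5 / log 3), plus degenerate references (filled square, 1-px line,
#' single pixel) with dimensions 2, 1 and 0.
#'
#' @param spec an [ideal_fractal_spec()].
#' @param spacing_um nominal pixel spacing attached to the mask.
#' @return A [binary_mask()]; the carpet at level L has exactly `8^L`
#'   foreground pixels, the Vicsek fractal `5^L`.
#' @examples
#' m <- generate_ideal_fractal(ideal_fractal_spec("sierpinski_carpet", 2))
#' sum(m$pixels) # 64
#' @export
generate_ideal_fractal <- function(spec, spacing_um = 1) {
  stopifnot(inherits(spec, "ideal_fractal_spec"))
  side_default <- 3L^spec$level
  m <- switch(spec$family,
    sierpinski_carpet = {
      base <- matrix(1L, 3, 3); base[2, 2] <- 0L
      Reduce(kronecker, rep(list(base), spec$level), matrix(1L, 1, 1))
    },
    vicsek = {
      base <- matrix(0L, 3, 3)
      base[2, ] <- 1L; base[, 2] <- 1L; base[c(1, 3), c(1, 3)] <- 0L
      Reduce(kronecker, rep(list(base), spec$level), matrix(1L, 1, 1))
    },
    filled_square = {
      side <- as.integer(spec$size_px %||% side_default)
      matrix(1L, side, side)
    },
    line = {
      side <- as.integer(spec$size_px %||% side_default)
      m <- matrix(0L, side, side)
      m[(side + 1L) %/% 2L, ] <- 1L
      m
    },
    single_pixel = {
      side <- as.integer(spec$size_px %||% side_default)
      m <- matrix(0L, side, side)
      m[(side + 1L) %/% 2L, (side + 1L) %/% 2L] <- 1L
      m
    }
  )
  binary_mask(m > 0L, spacing_um)
}

#' Construct a gap pattern with a prescribed power-law lag histogram
#'
#' Deterministically lays down, for each integer lag L in
#' `[lag_min_px, lag_max_px]`, `round(count_at_min * (L/lag_min_px)^-alpha)`
#' horizontal background runs of exact length L, each bounded by single
#' foreground pixels. Runs are packed first-fit (longest first) into rows of
#' width `row_length_px`, rows are padded with foreground, and every
#' pattern row is sandwiched between full-foreground separator rows. The
#' horizontal lag histogram of the result therefore equals the prescribed
#' counts exactly; the vertical scan direction only contributes lags of
#' length 1 (every interior background pixel sits between two separator
#' rows), far below any physically sensible fit window.
#'
#' @param alpha power-law exponent (>= 0) of the lag histogram.
#' @param lag_min_px,lag_max_px integer lag range, `1 <= min < max`.
#' @param row_length_px row width; must exceed `lag_max_px + 2`.
#' @param count_at_min number of runs at the smallest lag.
#' @param spacing_um pixel spacing attached to the mask.
#' @return A [binary_mask()] with attribute `lag_counts`, a data frame
#'   `(lag_px, count)` of the constructed horizontal histogram.
#' @examples
#' p <- generate_powerlaw_gap_pattern(0, 2, 4, 32, count_at_min = 3)
#' attr(p, "lag_counts")
#' @export
generate_powerlaw_gap_pattern <- function(alpha, lag_min_px, lag_max_px,
                                          row_length_px, count_at_min = 100,
                                          spacing_um = 1) {
  stopifnot(alpha >= 0, lag_min_px >= 1, lag_min_px < lag_max_px,
            count_at_min >= 1)
  if (lag_max_px + 2 > row_length_px)
    stop("row_length_px too small to host the longest run plus its bounds",
         call. = FALSE)
  lags <- lag_min_px:lag_max_px
  counts <- as.integer(round(count_at_min * (lags / lag_min_px)^(-alpha)))
  runs <- rep(lags, counts)
  runs <- sort(runs, decreasing = TRUE)

  rows <- list()
  cur <- rep(TRUE, row_length_px)
  pos <- 2L
  for (l in runs) {
    if (pos + l > row_length_px) {
      rows[[length(rows) + 1L]] <- cur
      cur <- rep(TRUE, row_length_px)
      pos <- 2L
    }
    cur[pos:(pos + l - 1L)] <- FALSE
    pos <- pos + l + 1L
  }
  if (pos > 2L) rows[[length(rows) + 1L]] <- cur

  n <- length(rows)
  sep <- rep(TRUE, row_length_px)
  M <- matrix(TRUE, 2L * n + 1L, row_length_px)
  for (i in seq_len(n)) M[2L * i, ] <- rows[[i]]
  out <- binary_mask(M, spacing_um)
  attr(out, "lag_counts") <- data.frame(lag_px = lags, count = counts)
  out
}

#' Deterministic toy vessel layouts with equal total area
#'
#' Builds the two didactic configurations that explain why the vessel-size
#' distribution changes the measured fractal dimension: a
#' "non-tumoral-like" layout (one large vessel plus many small round ones)
#' and a "tumoral-like" layout (a few medium vessels, homogeneous in
#' size). Both masks have exactly the same foreground area up to
#' rasterization of the analytically matched radii, so box-count
#' differences come from organization alone.
#'
#' @param size_px canvas side in pixels.
#' @param spacing_um pixel spacing.
#' @return Named list of two [binary_mask()]s: `non_tumoral`, `tumoral`.
#' @export
toy_vessel_masks <- function(size_px = 512, spacing_um = 0.5) {
  H <- W <- as.integer(size_px)
  s <- size_px / 512
  big_r <- 48 * s
  small_r <- 9 * s
  n_small <- 14L
  m1 <- matrix(FALSE, H, W)
  m1[raster_disk(0.3 * H, 0.32 * W, big_r, H, W)] <- TRUE
  ang <- 2 * pi * (seq_len(n_small) - 1) / n_small
  rad <- rep(c(0.33, 0.2), length.out = n_small) * H
  cys <- 0.55 * H + rad * sin(ang)
  cxs <- 0.58 * W + rad * cos(ang)
  for (i in seq_len(n_small))
    m1[raster_disk(cys[i], cxs[i], small_r, H, W)] <- TRUE

  # tumoral: 4 equal disks matching the total area analytically
  med_r <- sqrt((big_r^2 + n_small * small_r^2) / 4)
  m2 <- matrix(FALSE, H, W)
  pos <- rbind(c(0.28, 0.3), c(0.3, 0.72), c(0.7, 0.32), c(0.72, 0.7))
  for (i in 1:4)
    m2[raster_disk(pos[i, 1] * H, pos[i, 2] * W, med_r, H, W)] <- TRUE

  list(non_tumoral = binary_mask(m1, spacing_um),
       tumoral = binary_mask(m2, spacing_um))
}
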