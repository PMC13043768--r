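# Independent brute-force oracles, deliberately naive.

# double-loop box counter over an explicit grid
brute_box_count <- function(M, s) {
  H <- nrow(M); W <- ncol(M)
  n <- 0L
  for (i in seq(1L, H, by = s)) {
    for (j in seq(1L, W, by = s)) {
      blk <- M[i:min(i + s - 1L, H), j:min(j + s - 1L, W), drop = FALSE]
      if (any(blk)) n <- n + 1L
    }
  }
  n
}

# character-by-character scan for bounded background runs along one vector
brute_line_gaps <- function(v) {
  gaps <- integer(0)
  run <- 0L
  seen_fg <- FALSE
  for (x in v) {
    if (x) {
      if (seen_fg && run > 0L) gaps <- c(gaps, run)
      seen_fg <- TRUE
      run <- 0L
    } else if (seen_fg) {
      run <- run + 1L
    }
  }
  gaps
}

brute_collect_lags <- function(M) {
  out <- integer(0)
  for (r in seq_len(nrow(M))) out <- c(out, brute_line_gaps(M[r, ]))
  for (cc in seq_len(ncol(M))) out <- c(out, brute_line_gaps(M[, cc]))
  sort(out)
}

lag_table <- function(dist) {
  stats::setNames(dist$counts, dist$lag_px)
}

# exact disk raster for ground-truth pixel counts
disk_mask <- function(r, pad = 10, spacing = 1) {
  H <- 2L * ceiling(r) + 2L * pad
  cy <- cx <- H / 2
  xy <- expand.grid(row = 1:H, col = 1:H)
  binary_mask(matrix((xy$row - cy)^2 + (xy$col - cx)^2 <= r^2, H, H), spacing)
}

random_blob_mask <- function(seed, side = 96, p_shapes = 6) {
  set.seed(seed)
  M <- matrix(FALSE, side, side)
  for (k in seq_len(p_shapes)) {
    r <- runif(1, 2, 10)
    cy <- runif(1, 1, side); cx <- runif(1, 1, side)
    xy <- expand.grid(row = 1:side, col = 1:side)
    M <- M | matrix((xy$row - cy)^2 + (xy$col - cx)^2 <= r^2, side, side)
  }
  binary_mask(M, 1)
}

# the slit-like <-> lobular-chunky architecture family used for the
# scale-consistency validation (sparse regime; see the methods vignette)
consistency_axis_spec <- function(f, seed) {
  vessel_population_spec(
    n_small_round = round(80 * (1 - f) + 230 * f),
    small_radius_range = c(1 + 2.5 * f, 2.5 + 5 * f),
    n_large = round(260 * (1 - f)^2 + 2 * f),
    large_axis_range = c(40 + 40 * f, 100 + 60 * f),
    elongation_range = c(30 - 28 * f, 60 - 56 * f),
    tortuosity = 0.5 - 0.2 * f,
    clustering = min(0.95, 0.15 + 2.2 * f),
    debris_density = 0, seed = seed)
}
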