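test_that("empty population renders a background-only tile and mask", {
  sp <- vessel_population_spec(n_small_round = 0, n_large = 0,
                               debris_density = 0, seed = 1)
  out <- generate_vessel_tile(sp, 64)
  expect_false(any(out$mask$pixels))
  # background stays near the configured colour, never in the brown band
  expect_gt(mean(out$tile$pixels[, , 3]), 220)
})

test_that("a single 10-um circle rasterizes to the expected pixel area", {
  sp <- vessel_population_spec(n_small_round = 1,
                               small_radius_range = c(10, 10),
                               n_large = 0, debris_density = 0,
                               clustering = 0, seed = 2)
  out <- generate_vessel_tile(sp, 128, spacing_um = 0.5)
  # seed chosen so the vessel lands fully inside the raster
  idx <- which(out$mask$pixels, arr.ind = TRUE)
  expect_true(min(idx) > 1 && max(idx) < 128)
  expect_lt(abs(sum(out$mask$pixels) - pi * 20^2) / (pi * 20^2), 0.05)
})

test_that("generation is a pure function of spec and seed", {
  sp <- vessel_population_spec(n_small_round = 15, n_large = 0, seed = 42)
  a <- generate_vessel_tile(sp, 128)
  b <- generate_vessel_tile(sp, 128)
  expect_identical(a$tile$pixels, b$tile$pixels)
  expect_identical(a$mask$pixels, b$mask$pixels)
  # and it restores the caller's RNG stream
  set.seed(99); x <- runif(1)
  set.seed(99)
  invisible(suppressWarnings(generate_vessel_tile(sp, 64)))
  y <- runif(1)
  expect_identical(x, y)
})

test_that("vessel pixels fall inside the DAB hue gate, background outside", {
  sp <- vessel_population_spec(n_small_round = 20, debris_density = 0,
                               seed = 3)
  out <- generate_vessel_tile(sp, 256)
  px <- out$tile$pixels
  r <- px[, , 1]; g <- px[, , 2]; b <- px[, , 3]
  hue <- matrix(grDevices::rgb2hsv(rbind(as.vector(r), as.vector(g),
                                         as.vector(b)),
                                   maxColorValue = 255)[1, ] * 360,
                nrow(r))
  fg <- out$mask$pixels
  expect_true(all(hue[fg] >= 20 & hue[fg] <= 40))
  expect_true(all(r[fg] > g[fg] & g[fg] > b[fg]))  # DAB brown ordering
  expect_true(all(b[!fg] > 220 | b[!fg] > r[!fg])) # background is gated out
})

test_that("self-similar fractal rasters have exact analytic counts", {
  c1 <- generate_ideal_fractal(ideal_fractal_spec("sierpinski_carpet", 1))
  expect_identical(dim(c1$pixels), c(3L, 3L))
  expect_identical(sum(c1$pixels), 8L)
  expect_false(c1$pixels[2, 2])
  c4 <- generate_ideal_fractal(ideal_fractal_spec("sierpinski_carpet", 4))
  expect_identical(sum(c4$pixels), 4096L)
  v2 <- generate_ideal_fractal(ideal_fractal_spec("vicsek", 2))
  expect_identical(sum(v2$pixels), 25L)
  expect_identical(dim(v2$pixels), c(9L, 9L))
  expect_error(ideal_fractal_spec("carpet"), "arg")
  expect_error(ideal_fractal_spec("vicsek", 9), "level")
})

test_that("degenerate fractal families match their definitions", {
  fs <- generate_ideal_fractal(ideal_fractal_spec("filled_square", 2))
  expect_true(all(fs$pixels))
  ln <- generate_ideal_fractal(ideal_fractal_spec("line", 2))
  expect_identical(sum(ln$pixels), 9L)
  expect_identical(sum(rowSums(ln$pixels) > 0), 1L)
  px1 <- generate_ideal_fractal(ideal_fractal_spec("single_pixel", 2))
  expect_identical(sum(px1$pixels), 1L)
})

test_that("constructed gap pattern carries its exact prescribed histogram", {
  p <- generate_powerlaw_gap_pattern(0, 2, 4, 32, count_at_min = 3)
  want <- data.frame(lag_px = 2:4, count = c(3L, 3L, 3L))
  expect_identical(attr(p, "lag_counts"), want)
  got <- collect_lags(p, "horizontal")
  expect_identical(got$lag_px, 2:4)
  expect_identical(got$counts, c(3L, 3L, 3L))
  # vertical direction only ever contributes unit lags
  v <- collect_lags(p, "vertical")
  expect_identical(v$lag_px, 1L)
})

test_that("gap pattern round-trips through the lag extractor for alpha > 0", {
  p <- generate_powerlaw_gap_pattern(0.8, 5, 40, 128, count_at_min = 60)
  got <- collect_lags(p, "horizontal")
  want <- attr(p, "lag_counts")
  want <- want[want$count > 0, ]
  expect_identical(got$lag_px, want$lag_px)
  expect_identical(got$counts, want$count)
  expect_error(generate_powerlaw_gap_pattern(1, 5, 40, 30), "row_length")
})

test_that("regression on the constructed counts recovers the exponent", {
  p <- generate_powerlaw_gap_pattern(0.735, 40, 400, 2048,
                                     count_at_min = 1000)
  lc <- attr(p, "lag_counts")
  fit <- stats::lm(log10(count) ~ log10(lag_px), data = lc[lc$count > 0, ])
  expect_lt(abs(unname(stats::coef(fit)[2]) + 0.735), 0.01)
})

test_that("toy layouts have matched areas and the expected Df ordering", {
  toys <- toy_vessel_masks(512)
  a1 <- sum(toys$non_tumoral$pixels)
  a2 <- sum(toys$tumoral$pixels)
  expect_lt(abs(a1 - a2) / a1, 0.02)
  sizes <- c(2, 4, 8, 16, 32, 64, 128)
  d1 <- local_dimension(box_count(toys$non_tumoral, sizes))
  d2 <- local_dimension(box_count(toys$tumoral, sizes))
  # at box sizes comparable to the large vessel, the layout rich in small
  # vessels keeps needing many boxes -> higher local dimension
  expect_gt(d1$df[sizes == 64], d2$df[sizes == 64])
  expect_gt(d1$df[sizes == 128], d2$df[sizes == 128])
})

test_that("unplaceable populations terminate with a partial-placement warning", {
  sp <- vessel_population_spec(n_small_round = 400,
                               small_radius_range = c(10, 14),
                               n_large = 0, debris_density = 0, seed = 1)
  expect_warning(out <- generate_vessel_tile(sp, 64),
                 "partial population")
  expect_true(attr(out, "placement_incomplete"))
})
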