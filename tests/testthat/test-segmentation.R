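one_px_tile <- function(rgb) {
  rgb_tile(array(rep(rgb, each = 1), c(1, 1, 3)), 0.5)
}

test_that("non-brown suppression follows the channel and hue gates", {
  p <- segmentation_params()
  # blue-dominant pixel -> white
  out <- suppress_non_brown(one_px_tile(c(40, 90, 150)), p)
  expect_equal(as.vector(out$pixels), c(255, 255, 255))
  # red-dominant, hue 60*(90-40)/(150-40) = 27.3 degrees -> kept
  out <- suppress_non_brown(one_px_tile(c(150, 90, 40)), p)
  expect_equal(as.vector(out$pixels), c(150, 90, 40))
  # pure red, hue 0 outside [20, 40] -> white
  out <- suppress_non_brown(one_px_tile(c(255, 0, 0)), p)
  expect_equal(as.vector(out$pixels), c(255, 255, 255))
})

test_that("suppression is idempotent on random tiles", {
  set.seed(11)
  px <- array(sample(0:255, 32 * 32 * 3, TRUE), c(32, 32, 3))
  t1 <- suppress_non_brown(rgb_tile(px, 0.5))
  t2 <- suppress_non_brown(t1)
  expect_identical(t1$pixels, t2$pixels)
})

test_that("blue binarization thresholds at strictly-greater-than 220", {
  p <- segmentation_params()
  # three pixels with blue 100, 230, 220
  px <- array(100, c(1, 3, 3))
  px[1, 1, 3] <- 100; px[1, 2, 3] <- 230; px[1, 3, 3] <- 220
  m <- binarize_blue(rgb_tile(px, 0.5), p)
  expect_identical(as.vector(m$pixels), c(TRUE, FALSE, TRUE))
  # all-white tile -> empty mask
  white <- rgb_tile(array(255, c(4, 4, 3)), 0.5)
  expect_false(any(binarize_blue(white, p)$pixels))
})

test_that("raising the blue threshold never shrinks the foreground", {
  set.seed(5)
  px <- array(sample(0:255, 24 * 24 * 3, TRUE), c(24, 24, 3))
  tl <- rgb_tile(px, 0.5)
  for (th in c(100, 180, 254)) {
    lo <- binarize_blue(tl, segmentation_params(blue_threshold = th))
    hi <- binarize_blue(tl, segmentation_params(blue_threshold = th + 1))
    expect_true(all(hi$pixels >= lo$pixels))
  }
})

test_that("noise assessment selects the documented median aperture", {
  p <- segmentation_params()
  mk_src <- function(frac_bright, n = 40) {
    px <- array(0, c(n, n, 3))
    nb <- round(frac_bright * n * n)
    red <- c(rep(250, nb), rep(100, n * n - nb))
    px[, , 1] <- matrix(red, n, n)
    rgb_tile(px, 0.5)
  }
  m <- binary_mask(matrix(TRUE, 40, 40), 0.5)
  strong <- adaptive_denoise(m, mk_src(0.6), p)
  expect_identical(attr(strong, "aperture_used"), 15L)
  weak <- adaptive_denoise(m, mk_src(0.1), p)
  expect_identical(attr(weak, "aperture_used"), 5L)
  # median of a constant mask is the mask itself
  expect_identical(strong$pixels, m$pixels)
  expect_identical(weak$pixels, m$pixels)
  expect_error(adaptive_denoise(binary_mask(matrix(TRUE, 2, 2), 0.5),
                                mk_src(0.5)), "shape")
})

test_that("vessel completion fills an annulus into a solid disk", {
  n <- 31
  xy <- expand.grid(1:n, 1:n)
  d <- sqrt((xy[, 1] - 16)^2 + (xy[, 2] - 16)^2)
  annulus <- binary_mask(matrix(d >= 9 & d <= 10, n, n), 0.5)
  disk <- matrix(d <= 10, n, n)
  done <- complete_vessels(annulus)
  # result contains the full disk and little else
  expect_true(all(done$pixels[disk]))
  expect_lt(sum(done$pixels & !disk), 0.1 * sum(disk))
})

test_that("completion preserves solid shapes and isolated pixels", {
  m <- matrix(FALSE, 40, 40); m[10:29, 10:29] <- TRUE
  expect_identical(complete_vessels(binary_mask(m, 0.5))$pixels, m)
  s <- matrix(FALSE, 21, 21); s[11, 11] <- TRUE
  expect_identical(complete_vessels(binary_mask(s, 0.5))$pixels, s)
})

test_that("dice and ppv follow their definitions", {
  m <- function(ix, n = 20) {
    M <- matrix(FALSE, n, n); M[ix] <- TRUE; binary_mask(M, 0.5)
  }
  a <- m(1:100); expect_equal(dice_ppv(a, a), list(dice = 1, ppv = 1))
  expect_equal(dice_ppv(m(1:100), m(101:200)), list(dice = 0, ppv = 0))
  q <- dice_ppv(m(1:100), m(21:120))
  expect_equal(q$dice, 0.8); expect_equal(q$ppv, 0.8)
  empty <- m(integer(0))
  expect_equal(dice_ppv(empty, empty), list(dice = 1, ppv = 1))
  expect_equal(dice_ppv(empty, a)$dice, 0)
})

test_that("full segmentation recovers synthetic vessels and their absence", {
  blank <- generate_vessel_tile(vessel_population_spec(
    n_small_round = 0, n_large = 0, debris_density = 0, seed = 2), 128)
  expect_false(any(segment_vessels(blank$tile)$pixels))

  out <- generate_vessel_tile(vessel_population_spec(
    n_small_round = 30, n_large = 0, small_radius_range = c(3, 6),
    clustering = 0, seed = 8), 512)
  q <- dice_ppv(segment_vessels(out$tile), out$mask)
  expect_gt(q$dice, 0.9)
})

test_that("a uniform diffusely brown field segments as one vessel-like mass", {
  nec <- generate_vessel_tile(vessel_population_spec(
    n_small_round = 0, n_large = 0, debris_density = 0,
    diffuse_brown_level = 1, seed = 4), 128)
  expect_gt(mean(segment_vessels(nec$tile)$pixels), 0.95)
})

test_that("median denoising removes debris specks without vessels lost", {
  out <- generate_vessel_tile(vessel_population_spec(
    n_small_round = 0, n_large = 0, debris_density = 3000, seed = 9), 256)
  seg <- segment_vessels(out$tile)
  # debris is 1-3 px; a 5x5 median wipes it out almost entirely
  expect_lt(mean(seg$pixels), 0.002)
})
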