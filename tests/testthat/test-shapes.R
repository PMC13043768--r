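test_that("components are measured with 8-connectivity and size filter", {
  M <- matrix(FALSE, 40, 40)
  M[2:11, 2:11] <- TRUE
  M[25:34, 20:29] <- TRUE
  comp <- extract_components(binary_mask(M, 1))
  expect_identical(nrow(comp), 2L)
  expect_identical(comp$area_px, c(100L, 100L))
  # diagonal touch joins components under 8-connectivity
  D <- matrix(FALSE, 10, 10); D[2:4, 2:4] <- TRUE; D[5:7, 5:7] <- TRUE
  expect_identical(nrow(extract_components(binary_mask(D, 1))), 1L)
  # min-size filter removes specks
  S <- matrix(FALSE, 10, 10); S[2, 2] <- TRUE; S[5:8, 5:8] <- TRUE
  expect_identical(nrow(extract_components(binary_mask(S, 1))), 1L)
})

test_that("square and circle geometry match the Crofton oracle values", {
  M <- matrix(FALSE, 20, 20); M[5:14, 5:14] <- TRUE
  comp <- extract_components(binary_mask(M, 1))
  # value cross-checked against skimage.measure.perimeter_crofton
  expect_equal(comp$perimeter_um, 36.8117, tolerance = 1e-4)
  expect_equal(comp$equiv_circle_perimeter_um, 2 * sqrt(100 * pi),
               tolerance = 1e-12)
  expect_gt(comp$perimeter_um, comp$equiv_circle_perimeter_um)

  disk <- disk_mask(20)
  cd <- extract_components(disk)
  expect_lt(abs(cd$perimeter_um - 2 * pi * 20) / (2 * pi * 20), 0.05)
  ratio <- cd$perimeter_um / cd$equiv_circle_perimeter_um
  expect_gte(ratio, 0.98); expect_lte(ratio, 1.08)
})

test_that("equivalent circle perimeter is 2*sqrt(pi*A)", {
  expect_equal(equivalent_circle_perimeter(pi), 2 * pi)
  expect_equal(equivalent_circle_perimeter(100), 35.44908, tolerance = 1e-5)
  expect_identical(equivalent_circle_perimeter(0), 0)
  expect_error(equivalent_circle_perimeter(-1), "non-negative")
})

test_that("isoperimetric inequality holds across generated populations", {
  # vessels >= 5 um radius (10 px): below that, digitization of
  # near-circular blobs can push the Crofton estimate under 0.98 P*
  worst <- Inf
  for (seed in 1:4) {
    out <- suppressWarnings(generate_vessel_tile(vessel_population_spec(
      n_small_round = 40, small_radius_range = c(5, 10),
      n_large = 4, elongation_range = c(2, 6), debris_density = 0,
      seed = seed), 512))
    comp <- extract_components(out$mask)
    worst <- min(worst, comp$perimeter_um / comp$equiv_circle_perimeter_um)
  }
  expect_gte(worst, 0.98)
})

test_that("areas are conserved and scale with spacing equivariantly", {
  m <- random_blob_mask(3, side = 80)
  comp <- extract_components(m, min_size_px = 4)
  kept <- sum(comp$area_px)
  # conservation against a size-filtered mask
  all_comp <- extract_components(m, min_size_px = 1)
  expect_identical(sum(all_comp$area_px), sum(m$pixels))
  expect_lte(kept, sum(m$pixels))

  m2 <- binary_mask(m$pixels, 2)   # double the spacing
  comp2 <- extract_components(m2, min_size_px = 4)
  expect_equal(comp2$perimeter_um, 2 * comp$perimeter_um)
  expect_equal(comp2$equiv_circle_perimeter_um,
               2 * comp$equiv_circle_perimeter_um)
  expect_equal(comp2$area_um2, 4 * comp$area_um2)
})

test_that("perimeter-plane density is a unit-mass histogram on the diagonal", {
  # N identical circles -> single occupied bin, on the identity line
  M <- matrix(FALSE, 60, 180)
  xy <- expand.grid(1:60, 1:60)
  sub <- matrix((xy[, 1] - 30)^2 + (xy[, 2] - 30)^2 <= 8^2, 60, 60)
  for (k in 0:2) M[1:60, (k * 60 + 1):(k * 60 + 60)] <- sub
  comp <- extract_components(binary_mask(M, 1))
  expect_identical(nrow(comp), 3L)
  d <- perimeter_plane_density(comp, n_bins = 10)
  expect_equal(sum(d$density), 1, tolerance = 1e-9)
  expect_identical(sum(d$density > 0), 1L)
  expect_identical(d$n_components, 3L)

  # circles plus one long tube -> bimodal, tube off the small-P cluster
  M2 <- matrix(FALSE, 120, 180)
  M2[1:60, 1:180] <- M
  M2[90:95, 10:170] <- TRUE
  comp2 <- extract_components(binary_mask(M2, 1))
  d2 <- perimeter_plane_density(comp2, n_bins = 8)
  expect_identical(sum(d2$density > 0), 2L)
  # the tube has larger P and sits further above the diagonal
  tube <- comp2[which.max(comp2$area_px), ]
  expect_gt(tube$perimeter_um / tube$equiv_circle_perimeter_um, 1.5)
})

test_that("small-round enrichment separates the two architecture presets", {
  frac_small_diag <- function(spec) {
    out <- suppressWarnings(generate_vessel_tile(spec, 512))
    comp <- extract_components(out$mask)
    med <- stats::median(comp$equiv_circle_perimeter_um)
    near_round <- comp$perimeter_um / comp$equiv_circle_perimeter_um < 1.15
    mean(near_round & comp$equiv_circle_perimeter_um <= med)
  }
  nt <- frac_small_diag(non_tumoral_like_spec(seed = 5))
  tu <- frac_small_diag(tumoral_like_spec(seed = 5))
  expect_gt(nt, tu)
})
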