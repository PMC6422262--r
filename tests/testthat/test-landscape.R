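test_that("landscape constructor validates its inputs", {
  expect_error(landscape(matrix(1, 1, 5)), "2 x 2")
  expect_error(landscape(matrix(c(1, NA, 2, 3), 2, 2)), "finite")
  expect_error(landscape(matrix(1:4, 2, 2), mask = matrix(TRUE, 3, 3)),
               "same shape")
  L <- landscape(matrix(1:4, 2, 2), mask = matrix(c(TRUE, FALSE), 2, 2))
  expect_s3_class(L, "landscape")
  expect_identical(sum(reporting_mask(L)), 2L)
})

test_that("pyramid has apex at center, base at zero, 4-fold symmetry", {
  L <- make_pyramid(101, 3000)
  z <- elevations(L)
  expect_equal(z[51, 51], 3000)
  expect_equal(z[1, 1], 0)
  expect_equal(z[1, 101], 0)
  expect_equal(z[101, 1], 0)
  expect_equal(z[101, 101], 0)
  expect_equal(z, t(z))                     # diagonal reflection
  expect_equal(z, z[101:1, ])               # vertical flip
  expect_equal(z, z[, 101:1])               # horizontal flip
  expect_error(make_pyramid(2), "n must be")
  expect_error(make_pyramid(10, -5), "z_max")
})

test_that("pyramid hypsography decreases strictly with elevation", {
  # even n: no ring elevation falls exactly on a bin edge
  L <- make_pyramid(100, 3000)
  counts <- brute_bin_counts(as.numeric(elevations(L)), 10)
  expect_true(all(diff(counts) < 0))
  h <- hypsographic_curve(L, 10)
  expect_equal(h$area_fraction, counts / sum(counts))
  # oracle and implementation agree on the tie-prone odd grid as well
  L2 <- make_pyramid(101, 3000)
  expect_equal(hypsographic_curve(L2, 10)$area_fraction,
               brute_bin_counts(as.numeric(elevations(L2)), 10) / 101^2)
})

test_that("cone has apex at center, zero corners, hump-shaped hypsography", {
  L <- make_cone(101, 3000)
  z <- elevations(L)
  expect_equal(z[51, 51], 3000)
  expect_equal(z[1, 1], 0)
  expect_equal(z, t(z))
  expect_equal(z, z[101:1, ])
  counts <- brute_bin_counts(as.numeric(z), 10)
  pyramid_counts <- brute_bin_counts(as.numeric(elevations(make_pyramid(101))),
                                     10)
  expect_identical(which.max(pyramid_counts), 1L)
  expect_gt(which.max(counts), 1L)  # modal bin strictly above the lowest
})

test_that("roof is planar (row-only), ridge at z_max, uniform hypsography", {
  L <- make_roof(101, 3000)
  z <- elevations(L)
  expect_true(all(z[51, ] == 3000))
  expect_true(all(apply(z, 1, function(r) length(unique(r)) == 1)))
  expect_equal(z, z[101:1, ])  # reflection across the ridge

  # even grid: equal-width bins get the same number of rows up to quantization
  L2 <- make_roof(100, 3000)
  counts <- brute_bin_counts(as.numeric(elevations(L2)), 10)
  rows_per_bin <- 100 / 10
  expect_lte(max(counts) / min(counts), (rows_per_bin + 1) / rows_per_bin)
})

test_that("hypsographic fractions sum to one and ignore unmasked buffer", {
  L <- make_cone(40)
  h <- hypsographic_curve(L, 13)
  expect_equal(sum(h$area_fraction), 1, tolerance = 1e-12)
  expect_length(h$area_fraction, 13)
  expect_length(h$bin_edges, 14)
  expect_equal(hypsographic_curve(L, 1)$area_fraction, 1)

  # masking off a buffer ring of constant cells leaves the masked histogram
  # of the interior unchanged
  z <- elevations(L)
  mask <- matrix(FALSE, 40, 40)
  mask[6:35, 6:35] <- TRUE
  Lm <- landscape(z, mask = mask)
  hm <- hypsographic_curve(Lm, 13)
  inner <- landscape(z[6:35, 6:35])
  expect_equal(hm$area_fraction, hypsographic_curve(inner, 13)$area_fraction)
  expect_error(hypsographic_curve(landscape(z, mask = matrix(FALSE, 40, 40))),
               "empty")
})

test_that("rescaling maps extremes exactly and is idempotent", {
  set.seed(42)
  z <- matrix(runif(100, 100, 700), 10, 10)
  L <- landscape(z)
  L2 <- rescale_elevations(L, 0, 3000)
  expect_equal(min(elevations(L2)), 0)
  expect_equal(max(elevations(L2)), 3000)
  L3 <- rescale_elevations(L2, 0, 3000)
  expect_lt(max(abs(elevations(L3) - elevations(L2))), 1e-9)
  expect_error(rescale_elevations(landscape(matrix(5, 3, 3))), "constant")
})

test_that("DEM round-trips through ESRI ASCII bit-exactly", {
  set.seed(7)
  z <- matrix(runif(25, 0, 1), 5, 5)
  path <- file.path(tempdir(), "dem5.asc")
  spomscape:::write_esri_ascii(z, path)
  L <- load_dem(path, rescale_to = NULL)
  expect_identical(elevations(L), z)

  # affine endpoints after rescale
  L2 <- load_dem(path, rescale_to = c(0, 3000))
  expect_equal(min(elevations(L2)), 0)
  expect_equal(max(elevations(L2)), 3000)

  # no-data inside the simulation square is rejected
  z2 <- z
  z2[2, 2] <- NA
  path2 <- file.path(tempdir(), "dem5_na.asc")
  spomscape:::write_esri_ascii(z2, path2)
  expect_error(load_dem(path2), "no-data")
})

test_that("GeoJSON polygon masks select the right cells", {
  z <- matrix(seq_len(100), 10, 10)
  path <- file.path(tempdir(), "dem10.asc")
  spomscape:::write_esri_ascii(z, path)
  gj <- list(type = "Polygon",
             coordinates = list(list(list(2, 2), list(8, 2), list(8, 8),
                                     list(2, 8), list(2, 2))))
  gj_path <- file.path(tempdir(), "mask.geojson")
  jsonlite::write_json(gj, gj_path, auto_unbox = TRUE)
  L <- load_dem(path, rescale_to = NULL, mask = gj_path)
  m <- reporting_mask(L)
  expect_equal(sum(m), 36)  # cell centers at 2.5..7.5 in both axes
  expect_true(m[5, 5])
  expect_false(m[1, 1])
})

test_that("landscape export and import round-trip all fields", {
  L <- make_cone(12)
  L$mask <- elevations(L) > 500
  prefix <- file.path(tempdir(), "cone12")
  write_landscape(L, prefix)
  L2 <- read_landscape(prefix)
  expect_identical(elevations(L2), elevations(L))
  expect_identical(L2$mask, L$mask)
  expect_identical(L2$boundary, L$boundary)
  expect_identical(L2$name, L$name)
})
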