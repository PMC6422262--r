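test_that("initial drainage is a valid, reproducible spanning forest", {
  cfg <- init_drainage(16, seed = 1)
  expect_invisible(validate_drainage(cfg))
  expect_identical(sum(cfg$area[cfg$flow_dir == -1L]), 256L)  # mass conservation
  expect_true(all(cfg$area >= 1L & cfg$area <= 256L))
  cfg2 <- init_drainage(16, seed = 1)
  expect_identical(cfg$flow_dir, cfg2$flow_dir)
  cfg3 <- init_drainage(16, seed = 2)
  expect_false(identical(cfg$flow_dir, cfg3$flow_dir))

  multi <- init_drainage(16, seed = 1, n_outlets = 4)
  validate_drainage(multi)
  expect_identical(sum(multi$flow_dir == -1L), 4L)
  expect_identical(sum(multi$area[multi$flow_dir == -1L]), 256L)
})

test_that("greedy optimization monotonically decreases energy", {
  cfg <- init_drainage(16, seed = 1)
  opt <- optimize_ocn(cfg, n_iters = 10000, seed = 2, trace_every = 10)
  expect_lte(opt$energy, cfg$energy)
  tr <- c(cfg$energy, attr(opt, "energy_trace"))
  expect_true(all(diff(tr) <= 1e-9))
  validate_drainage(opt)
  expect_equal(opt$energy, sum(opt$area^0.5), tolerance = 1e-9)
  expect_error(optimize_ocn(cfg, gamma = 1.2), "gamma")
  expect_error(optimize_ocn(cfg, gamma = 0), "gamma")
})

test_that("annealing at zero temperature reduces to greedy acceptance", {
  cfg <- init_drainage(12, seed = 3)
  ann <- optimize_ocn(cfg, n_iters = 4000, schedule = "annealing", seed = 4,
                      T0 = 1e-12, trace_every = 10)
  tr <- c(cfg$energy, attr(ann, "energy_trace"))
  expect_true(all(diff(tr) <= 1e-9))
  validate_drainage(ann)
})

test_that("elevations increase upstream from outlets at level zero", {
  res <- shared_ocn()
  opt <- res$opt
  z_raw <- spomscape:::cpp_elevations_from_areas(as.integer(opt$flow_dir),
                                                 as.integer(opt$area), 0.5)
  z_raw <- matrix(z_raw, opt$n, opt$n)
  expect_equal(min(z_raw), 0)
  expect_true(all(z_raw[opt$flow_dir == -1L] == 0))
  # every cell lies strictly above its receiver
  n <- opt$n
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  for (cell in which(opt$flow_dir >= 0L)) {
    d <- opt$flow_dir[cell]
    r <- (cell - 1L) %% n + 1L
    cc <- (cell - 1L) %/% n + 1L
    r2 <- (r - 1L + dr[d + 1L]) %% n + 1L
    c2 <- (cc - 1L + dc[d + 1L]) %% n + 1L
    expect_gt(z_raw[r, cc], z_raw[r2, c2])
  }
  L <- res$L
  expect_identical(L$boundary, "periodic")
  expect_equal(range(elevations(L)), c(0, 3000))
})

test_that("elevations are equivariant under lattice translation", {
  res <- shared_ocn()
  opt <- res$opt
  roll <- function(m, k1, k2) {
    n <- nrow(m)
    m[((seq_len(n) - 1 - k1) %% n) + 1, ((seq_len(n) - 1 - k2) %% n) + 1]
  }
  shifted <- opt
  shifted$flow_dir <- roll(opt$flow_dir, 5, 9)
  shifted$area <- roll(opt$area, 5, 9)
  z1 <- elevations(elevations_from_areas(opt))
  z2 <- elevations(elevations_from_areas(shifted))
  expect_equal(z2, roll(z1, 5, 9), tolerance = 1e-12)
})

test_that("OCN landscapes have a hump-shaped hypsographic curve", {
  res <- shared_ocn()
  counts <- brute_bin_counts(as.numeric(elevations(res$L)), 10)
  expect_gt(which.max(counts), 1L)
})
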