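test_that("extinction rates are inversely proportional to fitness", {
  expect_equal(extinction_rates(1, e = 0.02), 0.02)
  expect_equal(extinction_rates(0.2, e = 0.02), 0.1)
  f <- matrix(runif(20, 0.1, 1), 4, 5)
  expect_equal(extinction_rates(2 * f), extinction_rates(f) / 2)
})

test_that("colonization rates match the printed kernel on a single source", {
  p <- matrix(0L, 5, 5)
  p[3, 3] <- 1L
  f <- matrix(1, 5, 5)
  cr <- colonization_rates(p, f, D = 2, c = 15)
  expect_equal(cr[3, 4], 15 * exp(-0.5) / (2 * pi * 4), tolerance = 1e-12)
  expect_equal(cr[3, 2], cr[3, 4])  # isotropy
  expect_equal(cr[2, 2], 15 * exp(-sqrt(2) / 2) / (2 * pi * 4),
               tolerance = 1e-12)
  # empty landscape: no colonization pressure anywhere
  expect_true(all(colonization_rates(p * 0L, f, D = 2) == 0))
})

test_that("direct and FFT colonization agree with the naive double loop", {
  set.seed(20)
  p <- matrix(rbinom(400, 1, 0.3), 20, 20)
  f <- matrix(runif(400, 0.05, 1), 20, 20)
  for (bnd in c("absorbing", "periodic")) {
    for (D in c(0.7, 2.1)) {
      oracle <- naive_colonization(p, f, D, 15, boundary = bnd)
      for (m in c("direct", "fft")) {
        got <- colonization_rates(p, f, D, c = 15, boundary = bnd, method = m)
        expect_lt(max(abs(got - oracle)), 1e-10)
      }
    }
  }
  # unnormalized variant agrees too
  oracle_u <- naive_colonization(p, f, 1.5, 15, kernel_norm = FALSE)
  got_u <- colonization_rates(p, f, 1.5, c = 15, kernel_norm = FALSE)
  expect_lt(max(abs(got_u - oracle_u)), 1e-9)
})

test_that("adding an occupied cell never decreases colonization rates", {
  set.seed(21)
  p <- matrix(rbinom(225, 1, 0.2), 15, 15)
  f <- matrix(runif(225, 0.1, 1), 15, 15)
  base <- colonization_rates(p, f, D = 1.5)
  empty_cells <- which(p == 0)
  for (cell in sample(empty_cells, 5)) {
    p2 <- p
    p2[cell] <- 1L
    grown <- colonization_rates(p2, f, D = 1.5)
    expect_true(all(grown >= base - 1e-12))
  }
})

test_that("kernel truncation error is bounded by exp(-10) of source mass", {
  set.seed(22)
  p <- matrix(rbinom(1600, 1, 0.05), 40, 40)
  f <- matrix(runif(1600, 0.2, 1), 40, 40)
  D <- 1.2
  c10 <- colonization_rates(p, f, D, c = 15, cutoff = 10)
  cinf <- colonization_rates(p, f, D, c = 15, cutoff = 1000)
  bound <- exp(-10) * 15 * sum(f[p == 1]) / (2 * pi * D^2)
  expect_lt(max(abs(cinf - c10)), bound)
  expect_lt(max(abs(cinf - c10)) / max(cinf), 1e-3)
})

test_that("a fully empty state is absorbing and zero-horizon is identity", {
  f <- matrix(0.5, 6, 6)
  res <- run_occupancy(matrix(0L, 6, 6), f, D = 1, horizon = 50, seed = 1)
  expect_true(res$extinct)
  expect_identical(res$final_total, 0L)
  expect_true(all(res$occupied == 0L))

  L <- make_cone(10)
  sp <- species_params(1500, 200, 1)
  s0 <- matrix(rbinom(100, 1, 0.5), 10, 10)
  res0 <- run_spom(L, sp, state0 = s0, horizon = 0, seed = 1)
  expect_identical(res0$final, matrix(as.integer(s0), 10, 10))
  expect_length(res0$times, 0)
})

test_that("seeded runs are exactly reproducible", {
  L <- make_cone(30)
  sp <- species_params(900, 150, 1)
  a <- run_spom(L, sp, horizon = 40, seed = 99)
  b <- run_spom(L, sp, horizon = 40, seed = 99)
  expect_identical(a$occupied, b$occupied)
  expect_identical(a$final, b$final)
  c3 <- run_spom(L, sp, horizon = 40, seed = 100)
  expect_false(identical(a$final, c3$final))
})

test_that("single-step transition frequencies match the Bernoulli model", {
  # two cells in a row; exact per-cell probabilities from the rate model
  f <- matrix(c(1, 0.6), 1, 2)
  D <- 1.5; e <- 0.3; cc <- 8; dt <- 0.5
  p0 <- matrix(c(1L, 0L), 1, 2)
  C2 <- cc * 1 * exp(-1 / D) / (2 * pi * D^2)  # pressure on the empty cell
  p_ext1 <- 1 - exp(-(e / 1) * dt)
  p_col2 <- 1 - exp(-C2 * dt)
  n <- 20000
  set.seed(123)
  ext <- logical(n)
  col <- logical(n)
  for (i in seq_len(n)) {
    s1 <- spom_step(p0, f, D = D, e = e, c = cc, dt = dt)
    ext[i] <- s1[1, 1] == 0L
    col[i] <- s1[1, 2] == 1L
  }
  se_ext <- sqrt(p_ext1 * (1 - p_ext1) / n)
  se_col <- sqrt(p_col2 * (1 - p_col2) / n)
  expect_lt(abs(mean(ext) - p_ext1), 3 * se_ext)
  expect_lt(abs(mean(col) - p_col2), 3 * se_col)
})

test_that("halving the time step barely changes long-run occupancy", {
  # flat landscape at the species optimum: f = 1 everywhere
  L <- landscape(matrix(1500, 50, 50), name = "flat")
  sp <- species_params(1500, 100, 3, f_max = 1)
  occ <- vapply(c(0.5, 0.25), function(dt) {
    res <- run_spom(L, sp, horizon = 200, dt = dt, record_every = 1,
                    seed = 31)
    mean(res$occupied[res$times > 100]) / 2500
  }, numeric(1))
  expect_lt(abs(occ[1] - occ[2]) / occ[2], 0.01)
})
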