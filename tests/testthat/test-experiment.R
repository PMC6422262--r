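test_that("warming schedule derives the shift rate exactly", {
  ws <- warming_schedule()
  expect_identical(ws$shift_rate, 4 / ((1 / 150) * 100))
  expect_identical(warming_schedule(delta_T = 0)$shift_rate, 0)
  expect_error(warming_schedule(lapse_rate = 0), "positive")
  sp <- species_params(800, 100, 1)
  expect_equal(warmed_z_opt(sp, 0, ws), 800)
  expect_equal(warmed_z_opt(sp, 100, ws), 1400)
  expect_equal(warmed_z_opt(sp, 50, ws), 1100)
  expect_error(warmed_z_opt(sp, 101, ws), "warming period")
})

test_that("fate classification is modal with a worst-first tie break", {
  expect_identical(classify_fate(rep("survivor_increase", 10)),
                   "survivor_increase")
  out <- c(rep("extinct_suited", 60), rep("survivor_decrease", 40))
  expect_identical(classify_fate(out), "extinct_suited")
  tie <- c(rep("extinction_debt", 5), rep("survivor_increase", 5))
  expect_identical(classify_fate(tie), "extinction_debt")
  tie2 <- c(rep("extinct_unsuited", 3), rep("extinct_suited", 3))
  expect_identical(classify_fate(tie2), "extinct_unsuited")
  expect_error(classify_fate(c("survivor_increase", "wanders_off")),
               "unknown outcome")
})

test_that("relative occupancy trajectories are anchored at the initial median", {
  traj <- rbind(c(10, 8, 6, 0), c(10, 12, 6, 0), c(10, 10, 8, 0))
  rel <- occupancy_relative_trajectory(traj, 10)
  expect_equal(rel[1], 100)
  expect_equal(rel[4], 0)
  expect_equal(rel[3], 60)
  expect_error(occupancy_relative_trajectory(traj, 0), "positive")
})

test_that("experiment config validates thresholds and horizons", {
  expect_error(experiment_config(n_replicates = 10, regional_threshold = 11),
               "exceed")
  expect_error(experiment_config(equilibration_horizon = 0), "positive")
  cfg <- experiment_config(n_replicates = 10)
  expect_identical(cfg$regional_threshold, 5L)
})

test_that("a species with no reachable habitat is filtered as not regional", {
  L <- make_cone(12)
  # niche entirely above the summit: fitness < 1e-12 everywhere
  sp <- species_params(30000, 50, 2)
  cfg <- experiment_config(n_replicates = 4, regional_threshold = 2,
                           equilibration_horizon = 30, debt_horizon = 30,
                           base_seed = 3)
  rec <- run_fate_experiment(L, sp, cfg)
  expect_false(rec$is_regional)
  expect_identical(rec$fate, "not_regional")
  expect_identical(rec$n_survived[["step1"]], 0L)
})

test_that("the five-step protocol produces a consistent fate record", {
  L <- make_cone(30)
  sp <- species_params(900, 150, 1)  # a robustly viable mid-elevation species
  cfg <- experiment_config(n_replicates = 6, regional_threshold = 3,
                           equilibration_horizon = 120, debt_horizon = 120,
                           base_seed = 21)
  rec <- run_fate_experiment(L, sp, cfg, species_id = 5L,
                             record_trajectories = TRUE)
  expect_s3_class(rec, "fate_record")
  expect_true(rec$is_regional)
  expect_identical(length(rec$outcomes), 6L)
  expect_true(rec$fate %in% c("survivor_increase", "survivor_decrease",
                              "extinction_debt", "extinct_suited",
                              "extinct_unsuited"))
  # nesting within the record: step-3 survivors are step-2 survivors
  expect_lte(rec$n_survived[["step3"]], rec$n_survived[["step2"]])
  # trajectories: one row per replicate, warming (100 yr) + debt records
  expect_identical(dim(rec$trajectories), c(6L, 100L + 120L))
  # reruns with the same id reproduce exactly
  rec2 <- run_fate_experiment(L, sp, cfg, species_id = 5L)
  expect_identical(rec2$outcomes, rec$outcomes)
  expect_identical(rec2$occupancy, rec$occupancy)
})

test_that("zero debt horizon lets every warming survivor through step 3", {
  L <- make_cone(30)
  sp <- species_params(900, 150, 1)
  cfg <- experiment_config(n_replicates = 4, regional_threshold = 2,
                           equilibration_horizon = 80, debt_horizon = 0,
                           base_seed = 13)
  rec <- run_fate_experiment(L, sp, cfg)
  expect_true(rec$is_regional)
  expect_identical(rec$n_survived[["step3"]], rec$n_survived[["step2"]])
})

test_that("parameter sweeps are order-independent and tabulate every species", {
  L <- make_cone(15)
  pool <- sample_species_pool(4, method = "random", seed = 5)
  cfg <- experiment_config(n_replicates = 4, regional_threshold = 2,
                           equilibration_horizon = 40, debt_horizon = 40,
                           base_seed = 17)
  sw <- run_parameter_sweep(L, pool, cfg)
  expect_identical(nrow(sw), 4L)
  expect_true(all(!is.na(sw$fate)))
  sw2 <- run_parameter_sweep(L, pool[rev(seq_len(nrow(pool))), ], cfg)
  sw2 <- sw2[order(sw2$species_id), ]
  rownames(sw2) <- NULL
  expect_equal(sw2, sw[order(sw$species_id), ], ignore_attr = TRUE)
})
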