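#' Warming schedule
#'
#' Converts a temperature scenario into an upward drift of species optima: a
#' warming of `delta_T` degrees over `duration` years with an atmospheric
#' lapse rate `lapse_rate` (degrees lost per meter climbed) displaces
#' isotherms -- and with them each species' optimal elevation -- at
#' `shift_rate = delta_T / (lapse_rate * duration)` meters per year. The
#' defaults (4 degrees C over 100 yr, lapse rate 1/150 degrees C/m; the
#' worst-case warming scenario) give exactly 6 m/yr.
#'
#' @param delta_T temperature increase over the warming period (degrees C),
#'   `>= 0` (0 gives a null-warming control).
#' @param lapse_rate temperature decrease per meter of elevation
#'   (degrees C/m), positive.
#' @param duration warming period length (yr), positive.
#' @return object of class `warming_schedule` with the derived `shift_rate`
#'   (m/yr).
#' @export
warming_schedule <- function(delta_T = 4, lapse_rate = 1 / 150,
                             duration = 100) {
  if (delta_T < 0) stop("delta_T must be non-negative")
  if (lapse_rate <= 0 || duration <= 0)
    stop("lapse_rate and duration must be positive")
  structure(list(delta_T = delta_T, lapse_rate = lapse_rate,
                 duration = duration,
                 shift_rate = delta_T / (lapse_rate * duration)),
            class = "warming_schedule")
}

#' @export
print.warming_schedule <- function(x, ...) {
  cat(sprintf(
    "warming: %+.1f degC over %g yr, lapse rate %.4g degC/m -> %.3g m/yr\n",
    x$delta_T, x$duration, x$lapse_rate, x$shift_rate))
  invisible(x)
}

#' Optimal elevation under warming
#'
#' `z_opt(t) = z_opt(0) + shift_rate * t`. The optimum may be driven above the
#' highest elevation of the landscape -- that is how warming extirpates summit
#' species.
#'
#' @param sp a [species_params()].
#' @param t years since warming onset, `0 <= t <= ws$duration`.
#' @param ws a [warming_schedule()].
#' @return optimal elevation (m) at time `t`.
#' @export
warmed_z_opt <- function(sp, t, ws) {
  stopifnot(inherits(sp, "species_params"), inherits(ws, "warming_schedule"))
  if (any(t < 0) || any(t > ws$duration))
    stop("t must lie within the warming period")
  sp$z_opt + ws$shift_rate * t
}

#' Experiment configuration
#'
#' Bundles the rate constants, replicate ensemble settings, phase horizons,
#' simulation options and warming schedule of the five-step fate experiment.
#'
#' @param e,c extinction and colonization constants (1/yr; defaults 0.02 and
#'   15).
#' @param n_replicates stochastic replicates per species (default 100).
#' @param regional_threshold minimum number of replicates that must persist
#'   through step 1 for the species to count as regional (default half,
#'   rounded up; the criterion is `>=`).
#' @param equilibration_horizon constant-climate equilibration length (yr) for
#'   steps 1 and 5 (default 500).
#' @param debt_horizon post-warming horizon (yr) over which extinction debt is
#'   paid off in step 3 (default 500).
#' @param dt time step (yr, default 1: the optimum shifts by exactly
#'   `shift_rate` meters per step).
#' @param cutoff kernel truncation (multiples of `D`).
#' @param kernel_norm logical; see [colonization_rates()].
#' @param warming a [warming_schedule()].
#' @param survivor_tolerance relative dead zone around zero when classifying
#'   survivor occupancy change (default 0: any change in the ensemble median
#'   counts).
#' @param base_seed integer; every replicate of every species derives its own
#'   seed from (`base_seed`, species id, replicate, phase), so sweeps are
#'   reproducible and independent of pool ordering.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(e = 0.02, c = 15, n_replicates = 100,
                              regional_threshold = ceiling(n_replicates / 2),
                              equilibration_horizon = 500,
                              debt_horizon = 500, dt = 1, cutoff = 10,
                              kernel_norm = TRUE,
                              warming = warming_schedule(),
                              survivor_tolerance = 0, base_seed = 1L) {
  if (regional_threshold > n_replicates)
    stop("regional_threshold cannot exceed n_replicates")
  if (equilibration_horizon <= 0 || debt_horizon < 0)
    stop("horizons must be positive (debt_horizon may be 0)")
  stopifnot(inherits(warming, "warming_schedule"))
  structure(list(e = e, c = c, n_replicates = as.integer(n_replicates),
                 regional_threshold = as.integer(regional_threshold),
                 equilibration_horizon = equilibration_horizon,
                 debt_horizon = debt_horizon, dt = dt, cutoff = cutoff,
                 kernel_norm = kernel_norm, warming = warming,
                 survivor_tolerance = survivor_tolerance,
                 base_seed = as.integer(base_seed)),
            class = "experiment_config")
}

# deterministic per-(species, replicate, phase) seed; stays under 2^31
phase_seed <- function(base, species_id, replicate, phase) {
  as.integer((as.numeric(base) * 48271 + as.numeric(species_id) * 2654435761 +
                as.numeric(replicate) * 9973 + phase * 101 + 17) %% 2147483562) + 1L
}

FATE_LEVELS <- c("extinct_unsuited", "extinct_suited", "extinction_debt",
                 "survivor_decrease", "survivor_increase")

#' Classify the fate of a species from its per-replicate outcomes
#'
#' The fate is the modal outcome over the replicate ensemble. Ties are broken
#' by a fixed precedence order, worst first: `extinct_unsuited` >
#' `extinct_suited` > `extinction_debt` > `survivor_decrease` >
#' `survivor_increase`.
#'
#' @param outcomes character vector of per-replicate outcomes (values among
#'   the five fate levels).
#' @return the modal fate (character scalar).
#' @export
classify_fate <- function(outcomes) {
  tab <- table(factor(outcomes, levels = FATE_LEVELS))
  if (sum(tab) != length(outcomes))
    stop("unknown outcome label(s): ",
         paste(setdiff(outcomes, FATE_LEVELS), collapse = ", "))
  names(tab)[which.max(tab)]
}

#' Run the five-step warming experiment for one species
#'
#' Step 1 (regional filter): `n_replicates` constant-climate runs from full
#' occupancy over the equilibration horizon; the species is *regional* if at
#' least `regional_threshold` replicates end non-extinct. Replicates that died
#' are re-seeded with an equilibrium configuration drawn at random from the
#' surviving ones (so the warming phase starts from a full ensemble). Step 2
#' (warming): each replicate runs for the warming duration with the optimum
#' drifting upward every step. Step 3 (extinction debt): climate is frozen at
#' the post-warming optimum and surviving replicates run for the debt horizon.
#' Steps 4-5 (suitability): if any replicate died during warming, the step-1
#' procedure is repeated with the post-warming optimum to decide whether the
#' new conditions would have been suitable at all.
#'
#' Per-replicate outcomes: replicates extinct during warming are
#' `extinct_suited` or `extinct_unsuited` depending on the species-level
#' suitability verdict; replicates extinct during step 3 carry `extinction_debt`;
#' survivors are `survivor_increase`/`survivor_decrease` according to the sign
#' of the change in ensemble median occupancy (end of step 3 vs end of step 1).
#' The species fate is the mode (see [classify_fate()]).
#'
#' @param L a [landscape()].
#' @param sp a [species_params()].
#' @param cfg an [experiment_config()].
#' @param species_id integer id used for seeding (default 1).
#' @param record_trajectories keep the per-replicate yearly occupancy
#'   trajectories for steps 2-3 (default `FALSE`; they are a replicate x time
#'   matrix and can be large).
#' @return an object of class `fate_record`: list with `species_id`, `params`,
#'   `is_regional`, `suited`, `fate`, `outcomes`, `n_survived`
#'   (per step), `occupancy` (median masked counts: `initial`, `post_warming`,
#'   `final`), and optionally `trajectories` (with `times` attribute).
#' @export
run_fate_experiment <- function(L, sp, cfg, species_id = 1L,
                                record_trajectories = FALSE) {
  stopifnot(inherits(L, "landscape"), inherits(sp, "species_params"),
            inherits(cfg, "experiment_config"))
  R <- cfg$n_replicates
  base <- cfg$base_seed
  run1 <- function(r, species, state0, horizon, warming, phase)
    run_spom(L, species, state0 = state0, horizon = horizon, e = cfg$e,
             c = cfg$c, dt = cfg$dt, record_every = cfg$dt,
             cutoff = cfg$cutoff, kernel_norm = cfg$kernel_norm,
             warming = warming, seed = phase_seed(base, species_id, r, phase))

  rec <- list(species_id = species_id,
              params = sp, is_regional = FALSE, suited = NA, fate =
                "not_regional", outcomes = rep(NA_character_, R),
              n_survived = c(step1 = 0L, step2 = 0L, step3 = 0L),
              occupancy = c(initial = NA_real_, post_warming = NA_real_,
                            final = NA_real_))
  class(rec) <- "fate_record"

  # --- step 1: regional filter ------------------------------------------
  finals <- vector("list", R)
  surv1 <- logical(R)
  counts1 <- numeric(R)
  for (r in seq_len(R)) {
    res <- run1(r, sp, NULL, cfg$equilibration_horizon, NULL, 1L)
    surv1[r] <- res$final_total > 0
    finals[[r]] <- res$final
    counts1[r] <- res$final_masked
  }
  rec$n_survived["step1"] <- sum(surv1)
  rec$is_regional <- sum(surv1) >= cfg$regional_threshold
  if (!rec$is_regional) return(rec)
  for (r in which(!surv1)) {  # replacement rule, seeded per replicate
    set.seed(phase_seed(base, species_id, r, 7L))
    pick <- sample(which(surv1), 1L)
    finals[[r]] <- finals[[pick]]
    counts1[r] <- counts1[pick]
  }
  rec$occupancy["initial"] <- median(counts1)

  # --- step 2: warming ---------------------------------------------------
  dur <- cfg$warming$duration
  surv2 <- logical(R)
  counts2 <- numeric(R)
  finals2 <- vector("list", R)
  n_rec2 <- floor(dur / cfg$dt)
  traj <- if (record_trajectories)
    matrix(NA_real_, R, n_rec2 + floor(cfg$debt_horizon / cfg$dt)) else NULL
  for (r in seq_len(R)) {
    res <- run1(r, sp, finals[[r]], dur, cfg$warming, 2L)
    surv2[r] <- res$final_total > 0
    finals2[[r]] <- res$final
    counts2[r] <- res$final_masked
    if (record_trajectories) traj[r, seq_len(n_rec2)] <- res$occupied
  }
  rec$n_survived["step2"] <- sum(surv2)
  rec$occupancy["post_warming"] <- median(counts2)

  # --- step 3: extinction debt payoff -----------------------------------
  sp_w <- species_params(sp$z_opt + cfg$warming$shift_rate * dur, sp$sigma,
                         sp$D, f_max = sp$f_max)
  surv3 <- logical(R)
  counts3 <- numeric(R)
  for (r in which(surv2)) {
    res <- run1(r, sp_w, finals2[[r]], cfg$debt_horizon, NULL, 3L)
    surv3[r] <- res$final_total > 0
    counts3[r] <- res$final_masked
    if (record_trajectories && length(res$occupied))
      traj[r, n_rec2 + seq_along(res$occupied)] <- res$occupied
  }
  if (record_trajectories) {
    traj[is.na(traj)] <- 0
    attr(traj, "times") <- cfg$dt * seq_len(ncol(traj))
    rec$trajectories <- traj
  }
  rec$n_survived["step3"] <- sum(surv3)
  rec$occupancy["final"] <- median(counts3)

  # --- steps 4-5: suitability of the post-warming conditions ------------
  if (any(!surv2)) {
    surv5 <- logical(R)
    for (r in seq_len(R)) {
      res <- run1(r, sp_w, NULL, cfg$equilibration_horizon, NULL, 5L)
      surv5[r] <- res$final_total > 0
    }
    rec$suited <- sum(surv5) >= cfg$regional_threshold
  }

  # --- per-replicate outcomes and modal fate -----------------------------
  med1 <- median(counts1)
  med3 <- median(counts3)  # ensemble median, extinct replicates count as 0
  delta <- (med3 - med1) / med1
  survivor_label <- if (delta > cfg$survivor_tolerance) "survivor_increase"
    else "survivor_decrease"
  out <- character(R)
  for (r in seq_len(R)) {
    out[r] <- if (!surv2[r]) {
      if (isTRUE(rec$suited)) "extinct_suited" else "extinct_unsuited"
    } else if (!surv3[r]) "extinction_debt" else survivor_label
  }
  rec$outcomes <- out
  rec$fate <- classify_fate(out)
  rec
}

#' @export
print.fate_record <- function(x, ...) {
  cat(sprintf("species %d: %s\n", x$species_id, x$fate))
  if (x$is_regional)
    cat(sprintf(
      "  survived replicates: step1 %d, step2 %d, step3 %d; occupancy %s -> %s\n",
      x$n_survived["step1"], x$n_survived["step2"], x$n_survived["step3"],
      format(x$occupancy["initial"]), format(x$occupancy["final"])))
  invisible(x)
}

#' Median occupancy trajectory relative to the initial median
#'
#' Per time point, the across-replicate median of masked occupied-cell counts,
#' expressed as a percentage of the initial (step 1) median occupancy. This is
#' the quantity used to describe range contraction during and after warming.
#'
#' @param trajectories replicate x time matrix of occupied-cell counts (e.g.
#'   the `trajectories` element of a [run_fate_experiment()] record).
#' @param initial_median the step-1 ensemble median occupancy (> 0).
#' @return numeric vector (percent of initial median per time point).
#' @export
occupancy_relative_trajectory <- function(trajectories, initial_median) {
  trajectories <- as.matrix(trajectories)
  if (nrow(trajectories) < 1L) stop("need at least one replicate")
  if (!is.finite(initial_median) || initial_median <= 0)
    stop("initial median occupancy must be positive")
  100 * apply(trajectories, 2, median) / initial_median
}

#' Run the fate experiment over a species pool
#'
#' Executes the full five-step protocol for every species of the pool and
#' tabulates the results. Seeding is keyed by `species_id`, so the table does
#' not depend on pool ordering. A species whose run fails is marked
#' `"error"` in the fate column (with a warning) rather than aborting the
#' sweep.
#'
#' @param L a [landscape()].
#' @param pool species pool data.frame (see [sample_species_pool()]).
#' @param cfg an [experiment_config()].
#' @param verbose print one line per species.
#' @return data.frame with one row per species: parameters, `regional`,
#'   `suited`, `fate`, per-step replicate survival counts, and the median
#'   masked occupancies (`occ_initial`, `occ_post_warming`, `occ_final`) plus
#'   `occ_change_pct` (final vs initial, -100 for species that lost all
#'   replicates).
#' @export
run_parameter_sweep <- function(L, pool, cfg, verbose = FALSE) {
  stopifnot(is.data.frame(pool), nrow(pool) >= 1L)
  rows <- vector("list", nrow(pool))
  for (i in seq_len(nrow(pool))) {
    id <- pool$species_id[i]
    sp <- pool_species(pool, i)
    rec <- tryCatch(run_fate_experiment(L, sp, cfg, species_id = id),
                    error = function(e) {
                      warning("species ", id, " failed: ",
                              conditionMessage(e))
                      NULL
                    })
    if (is.null(rec)) {
      rows[[i]] <- data.frame(species_id = id, z_opt = sp$z_opt,
                              sigma = sp$sigma, D = sp$D, f_max = sp$f_max,
                              regional = NA, suited = NA, fate = "error",
                              n_surv1 = NA_integer_, n_surv2 = NA_integer_,
                              n_surv3 = NA_integer_, occ_initial = NA_real_,
                              occ_post_warming = NA_real_,
                              occ_final = NA_real_, occ_change_pct = NA_real_)
    } else {
      chg <- if (!rec$is_regional || !is.finite(rec$occupancy["initial"]) ||
                 rec$occupancy["initial"] <= 0) NA_real_
        else 100 * (rec$occupancy["final"] - rec$occupancy["initial"]) /
          rec$occupancy["initial"]
      rows[[i]] <- data.frame(
        species_id = id, z_opt = sp$z_opt, sigma = sp$sigma, D = sp$D,
        f_max = sp$f_max, regional = rec$is_regional, suited = rec$suited,
        fate = rec$fate, n_surv1 = rec$n_survived[["step1"]],
        n_surv2 = rec$n_survived[["step2"]],
        n_surv3 = rec$n_survived[["step3"]],
        occ_initial = rec$occupancy[["initial"]],
        occ_post_warming = rec$occupancy[["post_warming"]],
        occ_final = rec$occupancy[["final"]], occ_change_pct = chg)
    }
    if (verbose)
      message(sprintf("species %d/%d (id %d): %s", i, nrow(pool), id,
                      rows[[i]]$fate))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
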