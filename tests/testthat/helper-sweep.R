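# Shared reduced-scale warming experiment, computed once per test session and
# reused by the protocol-nesting and range-shift tests. Problem sizes: 50 x 50
# cone, 150-species uniform random pool (large enough that both elevation
# groups of the range-shift comparison are represented), 20 replicates,
# 500-yr equilibration and debt horizons.

sweep_cache <- new.env(parent = emptyenv())

cone_sweep <- function() {
  if (!is.null(sweep_cache$main)) return(sweep_cache$main)
  L <- make_cone(50)
  pool <- sample_species_pool(150, method = "random", seed = 101)
  cfg <- experiment_config(n_replicates = 20, regional_threshold = 10,
                           base_seed = 7)
  sweep_cache$main <- list(L = L, pool = pool, cfg = cfg,
                           fates = run_parameter_sweep(L, pool, cfg))
  sweep_cache$main
}

null_warming_sweep <- function() {
  if (!is.null(sweep_cache$null)) return(sweep_cache$null)
  L <- make_cone(50)
  pool <- sample_species_pool(24, method = "random", seed = 202)
  cfg <- experiment_config(n_replicates = 10, regional_threshold = 5,
                           warming = warming_schedule(delta_T = 0),
                           base_seed = 11)
  sweep_cache$null <- list(L = L, pool = pool, cfg = cfg,
                           fates = run_parameter_sweep(L, pool, cfg))
  sweep_cache$null
}

ocn_cache <- new.env(parent = emptyenv())

shared_ocn <- function() {
  if (is.null(ocn_cache$res)) {
    cfg0 <- init_drainage(64, seed = 3)
    cfg <- optimize_ocn(cfg0, n_iters = 50 * 64^2, seed = 4)
    ocn_cache$res <- list(init = cfg0, opt = cfg,
                          L = elevations_from_areas(cfg))
  }
  ocn_cache$res
}
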