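#' Initialize a random drainage configuration
#'
#' Builds a loop-free spanning drainage forest on an `n` x `n` periodic
#' lattice: outlet cells are drawn at random and every other cell drains to
#' one of its eight neighbors, attached by a randomized spanning-tree growth,
#' so mass conservation and acyclicity hold by construction. This is the
#' starting point for the energy-dissipation minimization of [optimize_ocn()].
#'
#' @param n lattice side (>= 8).
#' @param seed integer seed (the configuration is reproducible from it).
#' @param n_outlets number of outlet cells (default 1).
#' @return an object of class `drainage_config`: list with `flow_dir`
#'   (integer matrix; 0-7 neighbor codes, -1 marks outlets), `area` (drainage
#'   area in cells, each cell counting itself), `energy`
#'   (`sum(area^gamma)` with the `gamma` used so far, initially 0.5), `gamma`,
#'   and `n`.
#' @export
init_drainage <- function(n, seed = 1L, n_outlets = 1L) {
  if (!is.numeric(n) || n < 8 || n != round(n)) stop("n must be an integer >= 8")
  if (n_outlets < 1 || n_outlets > n * n) stop("invalid n_outlets")
  set.seed(seed)
  outlets <- sample.int(n * n, n_outlets) - 1L
  res <- cpp_init_drainage(as.integer(n), as.integer(outlets))
  cfg <- list(flow_dir = matrix(res$flow_dir, n, n),
              area = matrix(res$area, n, n), gamma = 0.5, n = as.integer(n))
  cfg$energy <- sum(cfg$area^cfg$gamma)
  class(cfg) <- "drainage_config"
  cfg
}

#' @export
print.drainage_config <- function(x, ...) {
  cat(sprintf("drainage configuration: %d x %d periodic lattice, %d outlet(s)\n",
              x$n, x$n, sum(x$flow_dir == -1L)))
  cat(sprintf("  energy sum(A^%.2f) = %.2f, max drainage area = %d cells\n",
              x$gamma, x$energy, max(x$area)))
  invisible(x)
}

#' Optimize a drainage network by minimizing total energy dissipation
#'
#' The Optimal Channel Network metaheuristic: at each iteration one randomly
#' chosen cell's drainage direction is reassigned to a random neighbor;
#' proposals that would create a loop are rejected; the change in total energy
#' dissipation `E = sum_i A_i^gamma` is computed incrementally along the old
#' and new downstream paths. Greedy acceptance takes any non-increasing move;
#' simulated annealing accepts increases with probability `exp(-dE/T)` under
#' geometric cooling `T_k = T0 * alpha^k`. Greedy is the default and is what
#' the landscape generator uses.
#'
#' @param cfg a `drainage_config` from [init_drainage()].
#' @param gamma energy exponent, `0 < gamma < 1` (default 0.5; values outside
#'   the open interval are rejected because the slope-area reconstruction in
#'   [elevations_from_areas()] requires them).
#' @param n_iters number of proposals (default `50 * n^2`).
#' @param schedule `"greedy"` or `"annealing"`.
#' @param seed integer seed.
#' @param T0 initial annealing temperature; default is the median `|dE|` of
#'   100 random proposals from `cfg`.
#' @param alpha geometric cooling factor (default 0.999).
#' @param trace_every record the energy every this many iterations (for
#'   monotonicity diagnostics); 0 disables the trace.
#' @return an optimized `drainage_config` with an `energy_trace` attribute.
#' @export
optimize_ocn <- function(cfg, gamma = 0.5, n_iters = 50 * cfg$n^2,
                         schedule = c("greedy", "annealing"), seed = 1L,
                         T0 = NULL, alpha = 0.999, trace_every = 100L) {
  stopifnot(inherits(cfg, "drainage_config"))
  schedule <- match.arg(schedule)
  if (gamma <= 0 || gamma >= 1) stop("gamma must lie strictly in (0, 1)")
  set.seed(seed)
  annealing <- schedule == "annealing"
  if (annealing && is.null(T0)) T0 <- median_proposal_energy(cfg, gamma)
  if (!annealing) T0 <- 0
  res <- cpp_optimize_ocn(as.integer(cfg$flow_dir), as.integer(cfg$area),
                          gamma, as.integer(n_iters), annealing, T0, alpha,
                          as.integer(trace_every))
  out <- list(flow_dir = matrix(res$flow_dir, cfg$n, cfg$n),
              area = matrix(res$area, cfg$n, cfg$n), gamma = gamma,
              n = cfg$n, energy = res$energy)
  attr(out, "energy_trace") <- res$energy_trace
  attr(out, "n_accept") <- res$n_accept
  class(out) <- "drainage_config"
  out
}

# median |dE| over random single-cell redirections, used to set T0
median_proposal_energy <- function(cfg, gamma, n_probe = 100L) {
  probe <- cpp_optimize_ocn(as.integer(cfg$flow_dir), as.integer(cfg$area),
                            gamma, as.integer(n_probe), FALSE, 0, 1,
                            as.integer(1))
  tr <- c(cfg$energy, probe$energy_trace)
  d <- abs(diff(tr))
  m <- median(d[d > 0])
  if (!is.finite(m) || m <= 0) 1 else m
}

#' Reconstruct elevations from drainage areas (slope-area relation)
#'
#' Along each flow link the local slope is proportional to
#' `A^(gamma - 1)` (the constant of proportionality is immaterial because the
#' relief is rescaled afterwards). Elevations are accumulated upstream from
#' outlet level 0 -- so elevation strictly increases along every upstream path
#' -- and then affinely rescaled to the target relief.
#'
#' @param cfg an optimized `drainage_config`.
#' @param gamma energy exponent used for the slope-area relation (defaults to
#'   the one stored in `cfg`).
#' @param relief numeric `c(z_min, z_max)` target relief (default 0-3000 m).
#' @return a [landscape()] with periodic boundary.
#' @export
elevations_from_areas <- function(cfg, gamma = cfg$gamma,
                                  relief = c(0, 3000)) {
  stopifnot(inherits(cfg, "drainage_config"))
  if (gamma <= 0 || gamma >= 1) stop("gamma must lie strictly in (0, 1)")
  z <- cpp_elevations_from_areas(as.integer(cfg$flow_dir),
                                 as.integer(cfg$area), gamma)
  if (anyNA(z)) stop("disconnected flow graph: some cells reach no outlet")
  z <- matrix(z, cfg$n, cfg$n)
  z <- rescale_elevations(z, relief[1], relief[2])
  landscape(z, boundary = "periodic", name = sprintf("ocn_%d", cfg$n))
}

#' Generate an Optimal Channel Network landscape
#'
#' Convenience chain: [init_drainage()] then greedy [optimize_ocn()] then
#' [elevations_from_areas()]. OCN landscapes are "statistically realistic"
#' virtual topographies: they reproduce the hump-shaped hypsographic curve of
#' fluvially carved mountain ranges, with periodic boundary conditions.
#'
#' @inheritParams init_drainage
#' @inheritParams optimize_ocn
#' @param relief target relief (default 0-3000 m).
#' @return a [landscape()] with periodic boundary. The optimized
#'   `drainage_config` is attached as attribute `"drainage"`.
#' @export
make_ocn <- function(n = 100, seed = 1L, gamma = 0.5, n_iters = 50 * n^2,
                     n_outlets = 1L, relief = c(0, 3000)) {
  cfg <- init_drainage(n, seed = seed, n_outlets = n_outlets)
  cfg <- optimize_ocn(cfg, gamma = gamma, n_iters = n_iters, seed = seed + 1L)
  L <- elevations_from_areas(cfg, relief = relief)
  attr(L, "drainage") <- cfg
  L
}

#' Validate a drainage configuration
#'
#' Checks loop-freeness (every cell reaches an outlet in at most `N` steps)
#' and mass conservation (recomputed drainage areas match; outlet areas sum to
#' `N`).
#'
#' @param cfg a `drainage_config`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_drainage <- function(cfg) {
  stopifnot(inherits(cfg, "drainage_config"))
  pl <- cpp_path_lengths(as.integer(cfg$flow_dir))
  if (any(pl < 0)) stop("flow graph contains a loop")
  n <- cfg$n
  area <- matrix(1L, n, n)
  ord <- order(pl, decreasing = TRUE)
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  for (cell in ord) {
    d <- cfg$flow_dir[cell]
    if (d >= 0) {
      r <- (cell - 1L) %% n + 1L
      cc <- (cell - 1L) %/% n + 1L
      r2 <- (r - 1L + dr[d + 1L]) %% n + 1L
      c2 <- (cc - 1L + dc[d + 1L]) %% n + 1L
      area[r2, c2] <- area[r2, c2] + area[cell]
    }
  }
  if (!identical(as.integer(area), as.integer(cfg$area)))
    stop("stored drainage areas are inconsistent with the flow directions")
  if (sum(cfg$area[cfg$flow_dir == -1L]) != n * n)
    stop("outlet drainage areas do not sum to the lattice size")
  invisible(TRUE)
}
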