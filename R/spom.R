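#' Local extinction rates
#'
#' The extinction rate of an occupied cell is inversely proportional to its
#' fitness, `E_i = e / f_i`. Cells with fitness below `1e-12` are treated as
#' instantly extinct (their per-step extinction probability is 1) to avoid
#' overflow; this matters only when a niche has shifted entirely off the
#' landscape.
#'
#' @param f fitness field (matrix or vector), positive.
#' @param e extinction constant (1/yr), default 0.02.
#' @return rate field (1/yr) shaped like `f`; may contain `Inf` for
#'   zero-fitness cells.
#' @export
extinction_rates <- function(f, e = 0.02) {
  if (e <= 0) stop("e must be positive")
  e / f
}

#' Colonization rates from an occupancy state
#'
#' The colonization rate of a cell sums the contributions of all occupied
#' cells, weighted by an isotropic exponential dispersal kernel and the
#' fitness of the source: `C_i = c sum_{j != i} p_j f_j exp(-d_ij / D) / (2
#' pi D^2)`. Distances are Euclidean in cell units (minimal-image on periodic
#' landscapes); the kernel is truncated at `cutoff * D`. `kernel_norm = FALSE`
#' drops the `1 / (2 pi D^2)` normalization (a diagnostic variant in which the
#' colonization constant absorbs the kernel mass).
#'
#' Rates are computed for every cell (values at occupied cells are unused by
#' the stepping rule). Two computation paths give identical results: a direct
#' sum over occupied sources and an FFT grid convolution; `method = "auto"`
#' picks by operation count.
#'
#' @param state binary occupancy matrix (0/1 or logical).
#' @param f fitness matrix, same shape.
#' @param D dispersal distance (cell units).
#' @param c colonization constant (1/yr), default 15.
#' @param boundary `"absorbing"` or `"periodic"`.
#' @param cutoff kernel truncation radius in multiples of `D` (default 10;
#'   must be >= 3). Contributions beyond it are below `exp(-10)` relative.
#' @param kernel_norm logical; divide the kernel by `2 pi D^2` (default TRUE).
#' @param method `"auto"`, `"direct"` or `"fft"`.
#' @return matrix of colonization rates (1/yr).
#' @export
colonization_rates <- function(state, f, D, c = 15,
                               boundary = c("absorbing", "periodic"),
                               cutoff = 10, kernel_norm = TRUE,
                               method = c("auto", "direct", "fft")) {
  boundary <- match.arg(boundary)
  method <- match.arg(method)
  state <- as.matrix(state)
  storage.mode(state) <- "integer"
  f <- as.matrix(f)
  if (!identical(dim(state), dim(f)))
    stop("state and f must have the same shape")
  if (D <= 0 || c <= 0) stop("D and c must be positive")
  if (cutoff < 3) stop("cutoff must be at least 3 dispersal distances")
  cpp_colonization_rates(state, f, D, c, cutoff, boundary == "periodic",
                         kernel_norm, method)
}

#' One synchronous SPOM step
#'
#' All transition probabilities are evaluated from the state at time `t`, then
#' every cell performs one independent Bernoulli draw: an empty cell becomes
#' occupied with probability `1 - exp(-C_i dt)`, an occupied cell goes extinct
#' with probability `1 - exp(-E_i dt)`.
#'
#' @inheritParams colonization_rates
#' @param e extinction constant (1/yr).
#' @param dt time step (yr).
#' @return binary occupancy matrix at `t + dt`.
#' @export
spom_step <- function(state, f, D, e = 0.02, c = 15, dt = 1,
                      boundary = c("absorbing", "periodic"), cutoff = 10,
                      kernel_norm = TRUE) {
  boundary <- match.arg(boundary)
  state <- as.matrix(state)
  storage.mode(state) <- "integer"
  C <- colonization_rates(state, f, D, c = c, boundary = boundary,
                          cutoff = cutoff, kernel_norm = kernel_norm)
  E <- extinction_rates(f, e = e)
  p_col <- 1 - exp(-C * dt)
  p_ext <- ifelse(f < 1e-12, 1, 1 - exp(-E * dt))
  u <- matrix(runif(length(state)), nrow(state), ncol(state))
  new_state <- ifelse(state == 1L, (u >= p_ext) * 1L, (u < p_col) * 1L)
  storage.mode(new_state) <- "integer"
  new_state
}

#' Run the SPOM on a raw fitness field
#'
#' Low-level constant-climate run loop operating directly on a fitness matrix
#' of any shape (no [landscape()] object required). This is the entry point
#' for fitness fields that do not come from an elevation grid -- e.g.
#' externally supplied habitat-suitability layers -- and for exact small-system
#' analyses (the fitness field is the model's only coupling to the
#' environment).
#'
#' @inheritParams spom_step
#' @param state0 initial binary occupancy matrix.
#' @param horizon run length (yr).
#' @param record_every trajectory recording interval (yr), a multiple of `dt`.
#' @param mask optional logical matrix: cells counted in occupancy reports.
#' @param seed optional integer seed.
#' @return a `spom_run` object (see [run_spom()]).
#' @export
run_occupancy <- function(state0, f, D, e = 0.02, c = 15, dt = 1, horizon,
                          record_every = dt,
                          boundary = c("absorbing", "periodic"), cutoff = 10,
                          kernel_norm = TRUE, mask = NULL, seed = NULL) {
  boundary <- match.arg(boundary)
  state0 <- as.matrix(state0)
  storage.mode(state0) <- "integer"
  f <- as.matrix(f)
  if (!identical(dim(state0), dim(f)))
    stop("state0 and f must have the same shape")
  rec_steps <- record_every / dt
  if (abs(rec_steps - round(rec_steps)) > 1e-9)
    stop("record_every must be a multiple of dt")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(f), ncol(f))
  mask <- as.matrix(mask)
  storage.mode(mask) <- "integer"
  if (!is.null(seed)) set.seed(seed)
  n_steps <- floor(round(horizon / dt, 9))
  res <- cpp_run_spom(state0, f, f * 0, 0, 1, 1, D, e, c, dt,
                      as.integer(n_steps), 0, cutoff,
                      boundary == "periodic", kernel_norm,
                      as.integer(round(rec_steps)), mask)
  res$initial_masked <- sum(state0 == 1L & mask == 1L)
  res$dt <- dt
  class(res) <- "spom_run"
  res
}

#' Run the SPOM over a horizon
#'
#' Iterates synchronous steps, optionally under a warming schedule that shifts
#' the species' optimal elevation by `shift_rate * dt` after every step (the
#' fitness field is recomputed each step). The run early-exits once occupancy
#' hits zero (the empty state is absorbing) and the remaining trajectory
#' records are zero. Occupied-cell counts are reported within the landscape's
#' reporting mask.
#'
#' @param L a [landscape()].
#' @param sp a [species_params()].
#' @param state0 initial occupancy matrix; default fully occupied.
#' @param horizon run length (yr), `>= dt`.
#' @param e,c rate constants (1/yr).
#' @param dt time step (yr), default 1.
#' @param record_every trajectory recording interval (yr); must be a multiple
#'   of `dt`. Default `dt`.
#' @param cutoff kernel truncation (multiples of `D`).
#' @param kernel_norm logical; see [colonization_rates()].
#' @param warming optional [warming_schedule()]; its `shift_rate` drives the
#'   upward drift of `z_opt` starting from `sp$z_opt`.
#' @param seed optional integer seed set before the run (the trajectory is
#'   fully reproducible from it).
#' @return an object of class `spom_run`: list with `times`, `occupied`
#'   (masked counts at the recorded times), `final` (occupancy matrix),
#'   `extinct`, `final_total`, `final_masked`, and `initial_masked`.
#' @export
run_spom <- function(L, sp, state0 = NULL, horizon, e = 0.02, c = 15, dt = 1,
                     record_every = dt, cutoff = 10, kernel_norm = TRUE,
                     warming = NULL, seed = NULL) {
  stopifnot(inherits(L, "landscape"), inherits(sp, "species_params"))
  z <- L$elevations
  if (is.null(state0)) state0 <- matrix(1L, nrow(z), ncol(z))
  state0 <- as.matrix(state0)
  storage.mode(state0) <- "integer"
  if (!identical(dim(state0), dim(z)))
    stop("state0 must match the landscape shape")
  if (horizon < 0) stop("horizon must be non-negative")
  rec_steps <- record_every / dt
  if (abs(rec_steps - round(rec_steps)) > 1e-9)
    stop("record_every must be a multiple of dt")
  mask <- reporting_mask(L)
  storage.mode(mask) <- "integer"
  if (!is.null(seed)) set.seed(seed)
  shift_rate <- if (is.null(warming)) 0 else warming$shift_rate
  f0 <- fitness_field(L, sp)
  n_steps <- floor(round(horizon / dt, 9))
  if (n_steps == 0L) {
    occ <- sum(state0 == 1L & mask == 1L)
    return(structure(list(times = numeric(0), occupied = integer(0),
                          final = state0, extinct = all(state0 == 0L),
                          final_total = sum(state0), final_masked = occ,
                          initial_masked = occ, dt = dt),
                     class = "spom_run"))
  }
  res <- cpp_run_spom(state0, f0, z, sp$z_opt, sp$sigma, sp$f_max, sp$D, e, c,
                      dt, as.integer(n_steps), shift_rate, cutoff,
                      L$boundary == "periodic", kernel_norm,
                      as.integer(round(rec_steps)), mask)
  res$initial_masked <- sum(state0 == 1L & mask == 1L)
  res$dt <- dt
  class(res) <- "spom_run"
  res
}

#' @export
print.spom_run <- function(x, ...) {
  cat(sprintf("SPOM run: %d records, final occupancy %d (masked %d)%s\n",
              length(x$times), x$final_total, x$final_masked,
              if (x$extinct) " [extinct]" else ""))
  invisible(x)
}
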