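#' Virtual species parameters
#'
#' A virtual species is defined by its optimal elevation `z_opt` (m), niche
#' width `sigma` (m), dispersal distance `D` (cell units) and maximum fitness
#' `f_max`. Under the equal-viability calibration (the default),
#' `f_max = 1 / sqrt(sigma)`, which makes the Perron-Frobenius row-sum bound
#' on the metapopulation capacity identical across niche widths on an unbiased
#' constant-slope landscape: wide-niche species are correspondingly low-fitness
#' everywhere, narrow-niche species high-fitness near their optimum.
#'
#' @param z_opt optimal elevation (m); may lie outside the landscape range.
#' @param sigma niche width (m), positive.
#' @param D dispersal distance (cell units), positive.
#' @param f_max maximum fitness; defaults to the equal-viability value
#'   [fmax_for_sigma()], `1/sqrt(sigma)`. Supplying any positive value lifts
#'   the constraint (e.g. "super-species" with both wide niche and high
#'   fitness).
#' @return an object of class `species_params`.
#' @export
species_params <- function(z_opt, sigma, D, f_max = NULL) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
  if (!is.numeric(D) || D <= 0) stop("D must be positive")
  if (is.null(f_max)) f_max <- fmax_for_sigma(sigma)
  if (!is.numeric(f_max) || f_max <= 0) stop("f_max must be positive")
  structure(list(z_opt = as.numeric(z_opt), sigma = as.numeric(sigma),
                 D = as.numeric(D), f_max = as.numeric(f_max)),
            class = "species_params")
}

#' @export
print.species_params <- function(x, ...) {
  cat(sprintf(
    "species: z_opt = %.1f m, sigma = %.1f m, D = %.2f cells, f_max = %.4g\n",
    x$z_opt, x$sigma, x$D, x$f_max))
  invisible(x)
}

#' Equal-viability maximum fitness
#'
#' The maximum fitness that gives every niche width the same Perron row-sum
#' bound on the metapopulation capacity over an unbiased constant-slope
#' landscape: the bound converges to `f_max^2 sigma sqrt(2 pi)` (the Gaussian
#' integral of the optimal row of the landscape matrix), so holding it fixed
#' at `sqrt(2 pi)` across `sigma` requires `f_max^2 sigma = 1`, i.e.
#' `f_max = 1 / sqrt(sigma)`.
#'
#' @param sigma niche width (m), positive.
#' @return `1 / sqrt(sigma)`.
#' @export
fmax_for_sigma <- function(sigma) {
  if (any(!is.numeric(sigma)) || any(sigma <= 0))
    stop("sigma must be positive")
  1 / sqrt(sigma)
}

#' Gaussian elevational fitness field
#'
#' `f_i = f_max exp(-(z_i - z_opt)^2 / (2 sigma^2))` evaluated on every cell
#' (or element, for a numeric elevation vector such as the 1D calibration
#' profile).
#'
#' @param x a [landscape()], or a numeric vector/matrix of elevations (m).
#' @param sp a [species_params()].
#' @return numeric object shaped like the input elevations.
#' @export
fitness_field <- function(x, sp) {
  stopifnot(inherits(sp, "species_params"))
  z <- if (inherits(x, "landscape")) x$elevations else x
  sp$f_max * exp(-(z - sp$z_opt)^2 / (2 * sp$sigma^2))
}

balanced_triple <- function(n) {
  best <- c(1, 1, n)
  best_spread <- n
  for (a in seq_len(floor(n^(1 / 3)) + 1)) {
    if (n %% a != 0) next
    m <- n / a
    for (b in a:floor(sqrt(m))) {
      if (m %% b != 0) next
      d3 <- m / b
      spread <- d3 / a
      if (spread < best_spread) {
        best <- c(a, b, d3)
        best_spread <- spread
      }
    }
  }
  sort(best, decreasing = TRUE)
}

#' Sample a pool of virtual species
#'
#' Generates `n` parameter triples covering the box of optimal elevations,
#' niche widths and dispersal distances, with the equal-viability `f_max`
#' attached. The default scheme is a regular grid over the box (the most
#' balanced three-factor factorization of `n` sets the grid dimensions, with
#' the largest dimension given to `z_opt`); `method = "random"` draws uniform
#' samples instead.
#'
#' @param n pool size (default 4000, the full study pool).
#' @param z_opt_range,sigma_range,D_range parameter ranges
#'   (defaults 0-3000 m, 25-600 m, 0.1-12 cells).
#' @param method `"grid"` or `"random"`.
#' @param seed integer seed (used by `"random"`; kept for reproducibility
#'   bookkeeping either way).
#' @param equal_viability apply `f_max = 1/sigma` (default). `FALSE` sets
#'   `f_max = 1` for every species.
#' @return data.frame with columns `species_id`, `z_opt`, `sigma`, `D`,
#'   `f_max`.
#' @export
sample_species_pool <- function(n = 4000, z_opt_range = c(0, 3000),
                                sigma_range = c(25, 600), D_range = c(0.1, 12),
                                method = c("grid", "random"), seed = 1L,
                                equal_viability = TRUE) {
  method <- match.arg(method)
  for (rg in list(z_opt_range, sigma_range, D_range))
    if (length(rg) != 2L || rg[2] < rg[1]) stop("invalid parameter range")
  if (n < 1) stop("n must be positive")
  if (method == "grid") {
    dims <- balanced_triple(n)
    lev <- function(rg, k) if (k == 1) mean(rg) else
      seq(rg[1], rg[2], length.out = k)
    g <- expand.grid(z_opt = lev(z_opt_range, dims[1]),
                     sigma = lev(sigma_range, dims[2]),
                     D = lev(D_range, dims[3]))
  } else {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    g <- data.frame(z_opt = runif(n, z_opt_range[1], z_opt_range[2]),
                    sigma = runif(n, sigma_range[1], sigma_range[2]),
                    D = runif(n, D_range[1], D_range[2]))
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  data.frame(species_id = seq_len(nrow(g)), z_opt = g$z_opt, sigma = g$sigma,
             D = g$D,
             f_max = if (equal_viability) fmax_for_sigma(g$sigma) else 1)
}

#' Read / write a species pool as CSV
#'
#' @param pool data.frame as returned by [sample_species_pool()].
#' @param path CSV file path.
#' @return `read_species_pool` returns the pool data.frame.
#' @export
write_species_pool <- function(pool, path) {
  write.csv(pool[, c("species_id", "z_opt", "sigma", "D", "f_max")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_species_pool
#' @export
read_species_pool <- function(path) {
  pool <- read.csv(path)
  req <- c("species_id", "z_opt", "sigma", "D", "f_max")
  if (!all(req %in% names(pool)))
    stop("species pool CSV must have columns: ", paste(req, collapse = ", "))
  pool[, req]
}

pool_species <- function(pool, i) {
  species_params(pool$z_opt[i], pool$sigma[i], pool$D[i], f_max = pool$f_max[i])
}
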