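#' Metapopulation capacity (leading eigenvalue of the landscape matrix)
#'
#' The mean-field landscape matrix has entries `m_ij = f_i f_j` off the
#' diagonal and zero on it, i.e. `M = f f' - diag(f^2)`. Its leading eigenvalue
#' is the metapopulation capacity `lambda_M`: the species persists if and only
#' if `lambda_M > e/c`. The matrix is never materialized: power iteration uses
#' the rank-one structure, `M v = f (f . v) - f^2 * v`, with a diagonal shift
#' `max(f^2)` so the leading eigenvalue strictly dominates in magnitude (for
#' `N = 2` the spectrum is symmetric and unshifted power iteration stalls).
#'
#' @param f positive fitness vector (any shape; flattened), length >= 2.
#' @param tol relative convergence tolerance on the eigenvalue (default 1e-10).
#' @param max_iter iteration cap; exceeding it is an error.
#' @return the leading eigenvalue (numeric scalar).
#' @seealso [perron_bound()], [persists()]
#' @export
metapop_capacity <- function(f, tol = 1e-10, max_iter = 100000L) {
  f <- as.numeric(f)
  if (length(f) < 2L) stop("need at least two cells")
  if (any(!is.finite(f)) || any(f <= 0)) stop("f must be positive and finite")
  f2 <- f * f
  shift <- max(f2)
  v <- f / sqrt(sum(f2))
  lam <- 0
  for (it in seq_len(max_iter)) {
    w <- f * sum(f * v) - f2 * v + shift * v
    nw <- sqrt(sum(w * w))
    if (nw == 0) return(-shift)
    v_new <- w / nw
    lam_new <- sum(v_new * (f * sum(f * v_new) - f2 * v_new))
    if (it > 1 && abs(lam_new - lam) <= tol * max(abs(lam_new), 1e-300))
      return(lam_new)
    lam <- lam_new
    v <- v_new
  }
  stop("power iteration did not converge in ", max_iter, " iterations")
}

#' Perron-Frobenius row-sum bound on the metapopulation capacity
#'
#' For the non-negative mean-field landscape matrix the leading eigenvalue is
#' bounded by the maximum row sum, `max_i f_i (sum_j f_j - f_i) dx`. On an
#' unbiased constant-slope landscape with the equal-viability constraint
#' `f_max = 1/sigma` the bound converges to `sqrt(2 pi)` for every niche
#' width, which is what makes the species pool comparable.
#'
#' @inheritParams metapop_capacity
#' @param dx spacing between elements (default 1).
#' @return the row-sum bound (numeric scalar).
#' @export
perron_bound <- function(f, dx = 1) {
  f <- as.numeric(f)
  if (length(f) < 2L) stop("need at least two cells")
  if (any(!is.finite(f)) || any(f < 0)) stop("f must be non-negative")
  max(f * (sum(f) - f)) * dx
}

#' Persistence criterion
#'
#' A species persists in the domain if and only if its metapopulation capacity
#' strictly exceeds the extinction-to-colonization ratio `e/c`.
#'
#' @param lambda_M metapopulation capacity, `>= 0`.
#' @param e extinction constant (1/yr), default 0.02.
#' @param c colonization constant (1/yr), default 15.
#' @return logical.
#' @export
persists <- function(lambda_M, e = 0.02, c = 15) {
  if (e <= 0 || c <= 0) stop("e and c must be positive")
  lambda_M > e / c
}

#' Unbiased 1D constant-slope calibration profile
#'
#' Elevations `0, dx, 2 dx, ..., L` of the geomorphologically unbiased
#' landscape used to calibrate equal-viability species: a constant slope long
#' enough that the niche of any pool species fits inside with negligible
#' truncation. Center a species (`z_opt = L/2`) on it to evaluate
#' [perron_bound()].
#'
#' @param L profile length (m), default 6000.
#' @param dx spacing (m), default 1.
#' @return numeric vector of elevations.
#' @export
slope_profile <- function(L = 6000, dx = 1) seq(0, L, by = dx)

#' Kernel-weighted metapopulation capacity (diagnostic)
#'
#' Leading eigenvalue of the dispersal-weighted landscape matrix
#' `m_ij = f_i f_j exp(-d_ij/D) / (2 pi D^2)` (zero diagonal). This is *not*
#' the mean-field capacity used for the equal-viability calibration; it is a
#' diagnostic of how dispersal limitation degrades effective capacity. The
#' dense matrix is built explicitly, so this is restricted to small grids.
#'
#' @param L a [landscape()].
#' @param sp a [species_params()].
#' @param normalized divide the kernel by `2 pi D^2` (default `TRUE`).
#' @return the leading eigenvalue (numeric scalar).
#' @export
metapop_capacity_kernel <- function(L, sp, normalized = TRUE) {
  stopifnot(inherits(L, "landscape"), inherits(sp, "species_params"))
  z <- L$elevations
  if (length(z) > 4096)
    stop("kernel capacity builds a dense matrix; grid too large (> 4096 cells)")
  f <- as.numeric(fitness_field(L, sp))
  nr <- nrow(z); nc <- ncol(z)
  ij <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  dr <- abs(outer(ij$r, ij$r, `-`))
  dc <- abs(outer(ij$c, ij$c, `-`))
  if (L$boundary == "periodic") {
    dr <- pmin(dr, nr - dr)
    dc <- pmin(dc, nc - dc)
  }
  d <- sqrt(dr^2 + dc^2) * L$cell_size
  k <- exp(-d / sp$D)
  if (normalized) k <- k / (2 * pi * sp$D^2)
  M <- outer(f, f) * k
  diag(M) <- 0
  max(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
}
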