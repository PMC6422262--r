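#' Construct a landscape object
#'
#' A landscape is a rectangular grid of cell elevations (meters) plus a cell
#' size, a boundary mode, and an optional reporting mask. The mask marks the
#' cells that are counted when occupancy is reported (e.g. an administrative
#' boundary inside a buffered simulation square); all cells always take part
#' in the dynamics.
#'
#' @param elevations numeric matrix of elevations in meters; at least 2 x 2,
#'   all values finite.
#' @param cell_size cell side length in dispersal distance units (default 1;
#'   dispersal distances `D` are interpreted in these units).
#' @param boundary `"absorbing"` (no neighbors beyond the grid edge) or
#'   `"periodic"` (torus with minimal-image distances). Periodic boundaries
#'   are used by the Optimal Channel Network landscapes.
#' @param mask optional logical matrix of the same shape; `TRUE` cells are
#'   counted in occupancy reports. `NULL` means all cells count.
#' @param name text label carried through summaries and exports.
#' @return an object of class `landscape`.
#' @seealso [make_pyramid()], [make_cone()], [make_roof()], [make_ocn()],
#'   [load_dem()], [hypsographic_curve()]
#' @export
landscape <- function(elevations, cell_size = 1,
                      boundary = c("absorbing", "periodic"), mask = NULL,
                      name = "landscape") {
  boundary <- match.arg(boundary)
  elevations <- as.matrix(elevations)
  storage.mode(elevations) <- "double"
  if (nrow(elevations) < 2L || ncol(elevations) < 2L)
    stop("landscape must be at least 2 x 2 cells")
  if (!all(is.finite(elevations)))
    stop("elevations must all be finite (no missing cells inside the grid)")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a positive number")
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    if (!identical(dim(mask), dim(elevations)))
      stop("mask must have the same shape as elevations")
    storage.mode(mask) <- "logical"
    if (anyNA(mask)) stop("mask must not contain NA")
  }
  structure(list(elevations = elevations, cell_size = cell_size,
                 boundary = boundary, mask = mask, name = name),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  d <- dim(x$elevations)
  cat(sprintf("landscape '%s': %d x %d cells, %s boundary\n", x$name, d[1],
              d[2], x$boundary))
  cat(sprintf("  elevation range: %.1f - %.1f m, cell size %g\n",
              min(x$elevations), max(x$elevations), x$cell_size))
  if (!is.null(x$mask))
    cat(sprintf("  reporting mask: %d of %d cells\n", sum(x$mask),
                length(x$mask)))
  invisible(x)
}

#' @export
dim.landscape <- function(x) dim(x$elevations)

#' Grid of cell elevations
#' @param L a [landscape()]
#' @return the numeric elevation matrix.
#' @export
elevations <- function(L) {
  stopifnot(inherits(L, "landscape"))
  L$elevations
}

#' Reporting mask of a landscape
#' @param L a [landscape()]
#' @return logical matrix of cells counted in occupancy reports.
#' @export
reporting_mask <- function(L) {
  stopifnot(inherits(L, "landscape"))
  if (is.null(L$mask)) matrix(TRUE, nrow(L$elevations), ncol(L$elevations))
  else L$mask
}

check_geometry_args <- function(n, z_max) {
  if (!is.numeric(n) || length(n) != 1L || n != round(n) || n < 3)
    stop("n must be an integer >= 3")
  if (!is.numeric(z_max) || length(z_max) != 1L || z_max <= 0)
    stop("z_max must be positive")
}

#' Pyramid landscape
#'
#' A square pyramid: elevation decreases linearly with the Chebyshev
#' (L-infinity) distance from the grid center, from `z_max` at the apex to 0
#' on the grid edge. Its hypsographic curve decreases monotonically with
#' elevation (cross-section perimeter shrinks towards the apex).
#'
#' @param n cells per side (>= 3).
#' @param z_max apex elevation in meters.
#' @return a [landscape()] with absorbing boundary.
#' @export
make_pyramid <- function(n, z_max = 3000) {
  check_geometry_args(n, z_max)
  ctr <- (n + 1) / 2
  d <- abs(seq_len(n) - ctr)
  dmax <- (n - 1) / 2
  elev <- z_max * (1 - outer(d, d, pmax) / dmax)
  landscape(elev, boundary = "absorbing", name = sprintf("pyramid_%d", n))
}

#' Cone-in-a-square landscape
#'
#' A circular cone centered in the square grid. The default base radius is the
#' circumscribed radius (the distance from the center to the corner cells), so
#' the corner cells sit exactly at elevation 0 and the area-elevation
#' distribution is hump-shaped: near the base only the four corner sectors
#' remain (area vanishes), the full ring of largest circumference is reached
#' where the cone's cross-section circle is inscribed in the square (at about
#' 0.29 `z_max`), and ring circumference decreases towards the apex.
#'
#' @inheritParams make_pyramid
#' @param radius base radius in cells; defaults to the circumscribed radius
#'   `sqrt(2) * (n - 1) / 2`. Use `n / 2` for an inscribed cone with flat
#'   corners (monotone decreasing hypsography).
#' @return a [landscape()] with absorbing boundary.
#' @export
make_cone <- function(n, z_max = 3000, radius = sqrt(2) * (n - 1) / 2) {
  check_geometry_args(n, z_max)
  ctr <- (n + 1) / 2
  d2 <- (seq_len(n) - ctr)^2
  r <- sqrt(outer(d2, d2, `+`))
  elev <- z_max * pmax(1 - r / radius, 0)
  landscape(elev, boundary = "absorbing", name = sprintf("cone_%d", n))
}

#' Roof landscape
#'
#' Two planes rising linearly from two opposite edges to a central ridge line,
#' so elevation depends only on the row index. Every elevation band holds the
#' same area (up to row quantization): the hypsographic curve is uniform.
#'
#' @inheritParams make_pyramid
#' @return a [landscape()] with absorbing boundary.
#' @export
make_roof <- function(n, z_max = 3000) {
  check_geometry_args(n, z_max)
  ctr <- (n + 1) / 2
  prof <- z_max * (1 - abs(seq_len(n) - ctr) / ((n - 1) / 2))
  elev <- matrix(prof, nrow = n, ncol = n)
  landscape(elev, boundary = "absorbing", name = sprintf("roof_%d", n))
}

#' Affinely rescale elevations to a target relief
#'
#' Maps the elevation field linearly so its minimum and maximum match
#' `z_min` and `z_max` (default 0-3000 m, the relief all study landscapes are
#' normalized to). Rescaling an already matching field is the identity.
#'
#' @param L a [landscape()] or numeric matrix.
#' @param z_min,z_max target minimum and maximum elevation (m).
#' @return object of the same type with rescaled elevations.
#' @export
rescale_elevations <- function(L, z_min = 0, z_max = 3000) {
  if (z_max <= z_min) stop("z_max must exceed z_min")
  z <- if (inherits(L, "landscape")) L$elevations else L
  rng <- range(z)
  if (rng[2] - rng[1] <= 0)
    stop("cannot rescale a constant elevation field")
  z2 <- z_min + (z - rng[1]) / (rng[2] - rng[1]) * (z_max - z_min)
  if (inherits(L, "landscape")) {
    L$elevations <- z2
    L
  } else z2
}

#' Hypsographic curve (area distribution across elevations)
#'
#' Histogram of the elevations of the masked cells over `n_bins` equal-width
#' bins spanning the observed range, normalized to sum to one. Bins are
#' right-open except the last, which is closed so the maximum cell is counted.
#'
#' @param L a [landscape()].
#' @param n_bins number of elevation bins (>= 1).
#' @return an object of class `hypsographic_curve`: a list with `bin_edges`
#'   (length `n_bins + 1`), `mids` and `area_fraction` (length `n_bins`,
#'   summing to 1).
#' @export
hypsographic_curve <- function(L, n_bins = 10) {
  stopifnot(inherits(L, "landscape"))
  if (!is.numeric(n_bins) || length(n_bins) != 1L || n_bins < 1 ||
      n_bins != round(n_bins))
    stop("n_bins must be a positive integer")
  zs <- L$elevations[reporting_mask(L)]
  if (length(zs) == 0L) stop("reporting mask is empty")
  rng <- range(zs)
  if (rng[1] == rng[2]) {
    counts <- c(length(zs), rep(0, n_bins - 1))
    edges <- seq(rng[1], rng[1] + 1, length.out = n_bins + 1)
  } else {
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
    idx <- findInterval(zs, edges, rightmost.closed = TRUE)
    counts <- tabulate(idx, nbins = n_bins)
  }
  structure(list(bin_edges = edges,
                 mids = (edges[-1] + edges[-length(edges)]) / 2,
                 area_fraction = counts / sum(counts)),
            class = "hypsographic_curve")
}

#' @export
print.hypsographic_curve <- function(x, ...) {
  cat(sprintf("hypsographic curve: %d bins over %.1f - %.1f m\n",
              length(x$area_fraction), min(x$bin_edges), max(x$bin_edges)))
  print(round(setNames(x$area_fraction, sprintf("%.0f", x$mids)), 4))
  invisible(x)
}

#' Elevation of the hypsographic mode
#'
#' Midpoint elevation of the elevation bin holding the largest area fraction.
#' Species with optimal elevations below this value face increasing habitat
#' area as their niche shifts upslope; species above it face shrinking area.
#'
#' @inheritParams hypsographic_curve
#' @return elevation (m) of the modal bin midpoint.
#' @export
hypsographic_peak <- function(L, n_bins = 10) {
  h <- hypsographic_curve(L, n_bins)
  h$mids[which.max(h$area_fraction)]
}
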