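# DEM import/export. Supported text raster format is the ESRI ASCII grid
# (parsed here; no geospatial raster package is required); single-band TIFF
# rasters are read through the tiff package with values taken as stored.
# Projection metadata is passed through untouched.

read_esri_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-0-9.eE+]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  for (key in c("ncols", "nrows"))
    if (is.null(hdr[[key]])) stop("missing '", key, "' in ESRI ASCII header")
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$nrows * hdr$ncols)
    stop("ESRI ASCII grid: expected ", hdr$nrows * hdr$ncols,
         " values, found ", length(vals))
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  list(values = m, header = hdr)
}

write_esri_ascii <- function(m, path, xllcorner = 0, yllcorner = 0,
                             cellsize = 1, nodata = -9999) {
  m[is.na(m)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(m)), sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %.10g", xllcorner),
           sprintf("yllcorner %.10g", yllcorner),
           sprintf("cellsize %.10g", cellsize),
           sprintf("NODATA_value %.10g", nodata))
  rows <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

read_raster_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    v <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(v)) == 3L) {
      if (dim(v)[3] != 1L) stop("only single-band rasters are supported")
      v <- v[, , 1]
    }
    list(values = v, header = list(ncols = ncol(v), nrows = nrow(v),
                                   xllcorner = 0, yllcorner = 0, cellsize = 1))
  } else {
    read_esri_ascii(path)
  }
}

mask_from_geojson <- function(path, header, dims) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  geom <- gj
  if (identical(geom$type, "FeatureCollection")) {
    if (length(geom$features) != 1L)
      stop("mask GeoJSON must contain exactly one feature")
    geom <- geom$features[[1]]
  }
  if (identical(geom$type, "Feature")) geom <- geom$geometry
  if (!identical(geom$type, "Polygon"))
    stop("mask GeoJSON must contain a single Polygon geometry")
  ring <- geom$coordinates[[1]]  # outer ring; holes are ignored
  xy <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
  xs <- header$xllcorner + (seq_len(dims[2]) - 0.5) * header$cellsize
  ys <- header$yllcorner + (dims[1] - seq_len(dims[1]) + 0.5) * header$cellsize
  pts <- expand.grid(row = seq_len(dims[1]), col = seq_len(dims[2]))
  inside <- pracma::inpolygon(xs[pts$col], ys[pts$row],
                              xy[, 1], xy[, 2], boundary = TRUE)
  matrix(inside, nrow = dims[1], ncol = dims[2])
}

#' Load a digital elevation model as a landscape
#'
#' Reads a single-band raster (ESRI ASCII grid or TIFF), optionally rescales
#' the relief to a target range (the study convention is 0-3000 m so real
#' landscapes are comparable with the synthetic ones), and optionally restricts
#' occupancy reporting to a polygon or 0/1 raster mask. The full raster is
#' treated as the (buffered) simulation square with absorbing boundary; cells
#' with no-data values anywhere in it are rejected rather than imputed.
#'
#' @param path raster file (`.asc`/`.txt` ESRI ASCII grid, or `.tif`).
#' @param rescale_to numeric `c(z_min, z_max)` target relief in meters, or
#'   `NULL` to keep elevations unchanged.
#' @param mask optional reporting mask: a logical matrix, a path to a 0/1
#'   raster of identical shape, or a path to a GeoJSON Polygon (interpreted in
#'   the grid's coordinate system using the ASCII-grid geotransform; for TIFF
#'   input, in cell coordinates).
#' @param name label for the landscape (defaults to the file name).
#' @return a [landscape()] with absorbing boundary.
#' @export
load_dem <- function(path, rescale_to = c(0, 3000), mask = NULL,
                     name = basename(path)) {
  r <- read_raster_file(path)
  z <- r$values
  if (anyNA(z))
    stop("raster contains no-data cells inside the simulation square; ",
         "crop or fill it before loading")
  mask_m <- NULL
  if (!is.null(mask)) {
    if (is.matrix(mask)) {
      mask_m <- mask
    } else if (is.character(mask) &&
               tolower(tools::file_ext(mask)) %in% c("json", "geojson")) {
      mask_m <- mask_from_geojson(mask, r$header, dim(z))
    } else if (is.character(mask)) {
      mm <- read_raster_file(mask)$values
      mask_m <- !is.na(mm) & mm != 0
    } else stop("unsupported mask specification")
  }
  if (!is.null(rescale_to)) {
    stopifnot(length(rescale_to) == 2L)
    z <- rescale_elevations(z, rescale_to[1], rescale_to[2])
  }
  landscape(z, boundary = "absorbing", mask = mask_m, name = name)
}

#' Export / import a landscape as plain-text files
#'
#' Writes `<prefix>.asc` (ESRI ASCII elevations, full double precision, so a
#' round-trip is bit-exact), `<prefix>_mask.asc` when a mask is present, and
#' `<prefix>.json` with the remaining fields (cell size, boundary, name).
#'
#' @param L a [landscape()].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_landscape <- function(L, prefix) {
  stopifnot(inherits(L, "landscape"))
  write_esri_ascii(L$elevations, paste0(prefix, ".asc"),
                   cellsize = L$cell_size)
  if (!is.null(L$mask))
    write_esri_ascii(L$mask * 1, paste0(prefix, "_mask.asc"),
                     cellsize = L$cell_size)
  jsonlite::write_json(list(cell_size = L$cell_size, boundary = L$boundary,
                            name = L$name, has_mask = !is.null(L$mask)),
                       paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  z <- read_esri_ascii(paste0(prefix, ".asc"))$values
  mask <- NULL
  if (isTRUE(meta$has_mask))
    mask <- read_esri_ascii(paste0(prefix, "_mask.asc"))$values != 0
  landscape(z, cell_size = meta$cell_size, boundary = meta$boundary,
            mask = mask, name = meta$name)
}
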