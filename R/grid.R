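# Grid geometry, cell areas, masks and area-weighted reductions.
#
# Conventions follow NASA L3 ocean-color products: cell-center registration,
# latitude edges spanning -90..90 (south to north), longitude edges
# -180..180. Areas are spherical-zone areas on a sphere of radius
# `EARTH_RADIUS_M`; the sum over a full global grid equals 4*pi*R^2 to
# rounding error.

#' Construct an equal-angle geographic grid
#'
#' @param lat_edges strictly monotone latitude cell edges, degrees, within
#'   \[-90, 90\]
#' @param lon_edges strictly monotone longitude cell edges, degrees, within
#'   \[-180, 180\]
#' @return an object of class `geo_grid`
#' @export
geo_grid <- function(lat_edges, lon_edges) {
  lat_edges <- as.numeric(lat_edges)
  lon_edges <- as.numeric(lon_edges)
  if (length(lat_edges) < 2 || length(lon_edges) < 2)
    stopf("invalid grid: need at least 2 edges per axis")
  if (any(diff(lat_edges) <= 0) || any(diff(lon_edges) <= 0))
    stopf("invalid grid: edges must be strictly increasing")
  if (min(lat_edges) < -90 - 1e-9 || max(lat_edges) > 90 + 1e-9)
    stopf("invalid grid: latitude edges outside [-90, 90]")
  structure(
    list(lat_edges = lat_edges, lon_edges = lon_edges,
         registration = "cell-center"),
    class = "geo_grid")
}

#' Regular global grid at a given resolution
#'
#' @param res_deg cell size in degrees (e.g. `1/12` for standard L3 products,
#'   `2` for the desk-scale synthetic default)
#' @return a global `geo_grid`
#' @export
grid_regular <- function(res_deg) {
  if (res_deg <= 0) stopf("resolution must be positive")
  geo_grid(seq(-90, 90, by = res_deg), seq(-180, 180, by = res_deg))
}

#' @export
print.geo_grid <- function(x, ...) {
  cat(sprintf("geo_grid: %d x %d cells (lat x lon), %s registration\n",
              n_lat(x), n_lon(x), x$registration))
  invisible(x)
}

n_lat <- function(grid) length(grid$lat_edges) - 1L
n_lon <- function(grid) length(grid$lon_edges) - 1L

#' Cell-center coordinates of a grid
#'
#' @param grid a `geo_grid`
#' @return list with numeric vectors `lat` and `lon`
#' @export
grid_centers <- function(grid) {
  list(lat = (grid$lat_edges[-1] + grid$lat_edges[-length(grid$lat_edges)]) / 2,
       lon = (grid$lon_edges[-1] + grid$lon_edges[-length(grid$lon_edges)]) / 2)
}

#' Spherical cell areas
#'
#' Exact spherical-zone areas, `R^2 * dlambda * (sin(phi2) - sin(phi1))`
#' with angles in radians.
#'
#' @param grid a `geo_grid`
#' @param radius sphere radius in meters (default: mean Earth radius 6371 km)
#' @return matrix `[n_lat, n_lon]` of areas in square meters
#' @export
cell_areas <- function(grid, radius = EARTH_RADIUS_M) {
  if (!inherits(grid, "geo_grid")) stopf("`grid` must be a geo_grid")
  phi <- grid$lat_edges * pi / 180
  lam <- grid$lon_edges * pi / 180
  zone <- radius^2 * diff(sin(phi)) # per latitude row, per radian of lon
  outer(zone, diff(lam))
}

#' Area-weighted mean of a gridded field
#'
#' @param field numeric matrix `[n_lat, n_lon]` (NA = missing)
#' @param areas cell-area matrix from [cell_areas()]
#' @param mask optional logical matrix, `TRUE` = include (e.g. ocean mask)
#' @return scalar area-weighted mean over valid, unmasked cells
#' @export
area_weighted_mean <- function(field, areas, mask = NULL) {
  stopifnot(identical(dim(field), dim(areas)))
  keep <- !is.na(field)
  if (!is.null(mask)) keep <- keep & mask
  if (!any(keep)) stopf("empty domain: no valid unmasked cells")
  sum(field[keep] * areas[keep]) / sum(areas[keep])
}

weighted_quantile <- function(x, w, probs) {
  # Weighted empirical quantile by inverting the weight CDF (left-continuous).
  ok <- !is.na(x) & w > 0
  x <- x[ok]; w <- w[ok]
  if (!length(x)) return(rep(NA_real_, length(probs)))
  o <- order(x)
  x <- x[o]; cw <- cumsum(w[o]) / sum(w[o])
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

# ---- equal-area grid -------------------------------------------------------

#' Quasi-equal-area global grid
#'
#' Latitude bands of equal height ~`target_km`, each split into
#' `round(circumference / target_km)` longitude cells, so every cell is close
#' to `target_km` x `target_km`. Used to keep EOF decompositions free of
#' meridian-convergence bias.
#'
#' @param target_km nominal cell edge length in kilometers
#' @param radius sphere radius in meters
#' @return an object of class `ea_grid` with per-cell band index, longitude
#'   bounds and center coordinates
#' @export
equal_area_grid <- function(target_km = 50, radius = EARTH_RADIUS_M) {
  if (target_km <= 0) stopf("target cell size must be positive")
  n_bands <- max(2L, round(pi * radius / (target_km * 1000)))
  lat_edges <- seq(-90, 90, length.out = n_bands + 1)
  lat_c <- (lat_edges[-1] + lat_edges[-(n_bands + 1)]) / 2
  n_lon_band <- pmax(1L, as.integer(round(
    2 * pi * radius * cos(lat_c * pi / 180) / (target_km * 1000))))
  band_of_cell <- rep(seq_len(n_bands), n_lon_band)
  lon_idx <- unlist(lapply(n_lon_band, seq_len), use.names = FALSE)
  lon_width <- 360 / n_lon_band[band_of_cell]
  structure(
    list(n_bands = n_bands, lat_edges = lat_edges, n_lon_band = n_lon_band,
         band = band_of_cell,
         lat = lat_c[band_of_cell],
         lon = -180 + (lon_idx - 0.5) * lon_width,
         n_cells = length(band_of_cell), target_km = target_km),
    class = "ea_grid")
}

#' @export
print.ea_grid <- function(x, ...) {
  cat(sprintf("ea_grid: %d cells in %d latitude bands (~%g km)\n",
              x$n_cells, x$n_bands, x$target_km))
  invisible(x)
}

# Map source-cell centers to equal-area cell indices (whole-cell assignment;
# at typical source/target ratios sub-cell splitting is negligible).
ea_cell_index <- function(ea, lat, lon) {
  band <- findInterval(lat, ea$lat_edges, rightmost.closed = TRUE)
  band <- pmin(pmax(band, 1L), ea$n_bands)
  first <- cumsum(c(0L, ea$n_lon_band))[band]
  li <- pmin(floor((lon + 180) / (360 / ea$n_lon_band[band])), ea$n_lon_band[band] - 1L)
  as.integer(first + li + 1L)
}

#' Downsample a field series to a quasi-equal-area grid
#'
#' Each target cell value is the area-weighted mean of the source cells whose
#' centers fall inside it; missing where all contributors are missing. Target
#' cell weights are the summed contributing source areas, so for fully valid
#' fields the global area-weighted mean is conserved exactly.
#'
#' @param fs a [field_series()]
#' @param target_km nominal equal-area cell size in km (default 50)
#' @param mask optional logical ocean mask on the source grid; target cells
#'   with no unmasked contributors are dropped
#' @return an object of class `ea_field_series`: `values` matrix
#'   `[n_cells, n_time]`, `areas`, cell `lat`/`lon`, `time`, `units`
#' @export
downsample_equal_area <- function(fs, target_km = 50, mask = NULL) {
  stopifnot(inherits(fs, "field_series"))
  grid <- fs$grid
  ea <- equal_area_grid(target_km)
  areas <- cell_areas(grid)
  cc <- grid_centers(grid)
  latm <- matrix(cc$lat, n_lat(grid), n_lon(grid))
  lonm <- matrix(cc$lon, n_lat(grid), n_lon(grid), byrow = TRUE)
  keep_src <- if (is.null(mask)) rep(TRUE, length(latm)) else as.vector(mask)
  idx_all <- ea_cell_index(ea, as.vector(latm), as.vector(lonm))
  src <- which(keep_src)
  idx <- idx_all[src]
  a_src <- as.vector(areas)[src]
  # target cells with at least one contributor, in index order
  tgt <- sort(unique(idx))
  pos <- match(idx, tgt)
  n_t <- dim(fs$values)[3]
  vals <- matrix(NA_real_, length(tgt), n_t)
  a_tot <- as.vector(tapply(a_src, pos, sum))
  for (t in seq_len(n_t)) {
    x <- as.vector(fs$values[, , t])[src]
    ok <- !is.na(x)
    if (!any(ok)) next
    num <- rowsum(x[ok] * a_src[ok], pos[ok])
    den <- rowsum(a_src[ok], pos[ok])
    vals[as.integer(rownames(num)), t] <- num / den
  }
  structure(
    list(values = vals, areas = a_tot,
         lat = ea$lat[tgt], lon = ea$lon[tgt],
         cell_index = tgt, ea = ea,
         time = fs$time, units = fs$units, name = fs$name),
    class = "ea_field_series")
}
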