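# netCDF writers for derived map products (trend maps, blend adjustments).

nc_grid_dims <- function(grid) {
  cc <- grid_centers(grid)
  list(lon = ncdf4::ncdim_def("lon", "degrees_east", cc$lon),
       lat = ncdf4::ncdim_def("lat", "degrees_north", cc$lat))
}

#' Write a trend map as a multi-variable netCDF file
#'
#' Layers: slope, standard error, residual lag-1 autocorrelation, effective
#' sample size, significance flag (0/1), and — when present — the
#' reference-period mean and the normalized slope in percent per decade.
#'
#' @param tr a [trend_map()] result
#' @param path output path
#' @return `path`, invisibly
#' @export
write_trend_map <- function(tr, path) {
  stopifnot(inherits(tr, "trend_result"))
  d <- nc_grid_dims(tr$grid)
  fill <- -9.96921e36
  per_dec <- paste0(tr$units, " decade-1")
  layers <- list(
    slope = per_dec, se_adj = per_dec, rho = "1", n_eff = "1",
    significant = "1")
  if (!is.null(tr$normalized_slope)) {
    layers$mean_ref <- tr$units
    layers$normalized_slope <- "percent decade-1"
  }
  vars <- lapply(names(layers), function(nm)
    ncdf4::ncvar_def(nm, layers[[nm]], list(d$lon, d$lat),
                     missval = fill, prec = "double"))
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))
  for (i in seq_along(vars)) {
    nm <- names(layers)[i]
    v <- tr[[nm]]
    if (is.logical(v)) v <- v * 1.0
    ncdf4::ncvar_put(nc, vars[[i]], t(v))
  }
  invisible(path)
}

#' Write a blend adjustment as a 12-layer netCDF file
#'
#' @param adj a [fit_adjustment()] result
#' @param path output path
#' @return `path`, invisibly
#' @export
write_adjustment <- function(adj, path) {
  stopifnot(inherits(adj, "blend_adjustment"))
  d <- nc_grid_dims(adj$grid)
  dm <- ncdf4::ncdim_def("month", "calendar month", 1:12)
  fill <- -9.96921e36
  var <- ncdf4::ncvar_def("adjustment", adj$units, list(d$lon, d$lat, dm),
                          missval = fill, prec = "double")
  cnt <- ncdf4::ncvar_def("n_overlap", "1", list(d$lon, d$lat, dm),
                          missval = fill, prec = "double")
  nc <- ncdf4::nc_create(path, list(var, cnt))
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, var, aperm(adj$diff, c(2, 1, 3)))
  ncdf4::ncvar_put(nc, cnt, aperm(adj$counts * 1.0, c(2, 1, 3)))
  invisible(path)
}

#' Read a blend adjustment written by [write_adjustment()]
#'
#' @param path netCDF path
#' @param grid the [geo_grid()] the adjustment is defined on
#' @return a `blend_adjustment`
#' @export
read_adjustment <- function(path, grid) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  diff <- aperm(ncdf4::ncvar_get(nc, "adjustment", collapse_degen = FALSE),
                c(2, 1, 3))
  counts <- aperm(ncdf4::ncvar_get(nc, "n_overlap", collapse_degen = FALSE),
                  c(2, 1, 3))
  units <- ncdf4::ncatt_get(nc, "adjustment", "units")$value
  structure(list(diff = diff, counts = counts, units = units, grid = grid,
                 min_obs = NA), class = "blend_adjustment")
}
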