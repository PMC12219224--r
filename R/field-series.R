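# FieldSeries: the pipeline currency — a time-stamped stack of 2-D gridded
# geophysical fields with units and a missing-data mask (NA).

#' Construct a FieldSeries
#'
#' @param values numeric array `[n_lat, n_lon, n_time]`; `NA` marks missing
#' @param grid a [geo_grid()] shared by all fields
#' @param time `Date` vector of first-of-month stamps, strictly increasing,
#'   no duplicate months
#' @param units units string (required; e.g. `"mg C m-2 d-1"`)
#' @param name optional variable name
#' @return object of class `field_series`
#' @export
field_series <- function(values, grid, time, units, name = "field") {
  stopifnot(inherits(grid, "geo_grid"))
  if (length(dim(values)) == 2) dim(values) <- c(dim(values), 1L)
  if (length(dim(values)) != 3)
    stopf("`values` must be a [lat, lon, time] array")
  if (dim(values)[1] != n_lat(grid) || dim(values)[2] != n_lon(grid))
    stopf("values dimensions do not match the grid (%d x %d)",
          n_lat(grid), n_lon(grid))
  time <- as.Date(time)
  if (dim(values)[3] != length(time))
    stopf("time axis length (%d) does not match values (%d)",
          length(time), dim(values)[3])
  if (anyDuplicated(format(time, "%Y-%m")))
    stopf("duplicate months in time axis")
  if (is.unsorted(time, strictly = TRUE))
    stopf("time axis must be strictly increasing")
  if (missing(units) || is.null(units) || !nzchar(units))
    stopf("units metadata is required")
  structure(list(values = values, grid = grid, time = time,
                 units = units, name = name),
            class = "field_series")
}

#' @export
print.field_series <- function(x, ...) {
  cat(sprintf("field_series '%s' [%s]: %d x %d cells, %d months (%s to %s), %.1f%% missing\n",
              x$name, x$units, dim(x$values)[1], dim(x$values)[2],
              length(x$time), format(x$time[1], "%Y-%m"),
              format(x$time[length(x$time)], "%Y-%m"),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Subset a FieldSeries in time
#'
#' @param fs a `field_series`
#' @param from,to inclusive `"YYYY-MM"` bounds (either may be `NULL`)
#' @return a `field_series` restricted to the requested months
#' @export
fs_window <- function(fs, from = NULL, to = NULL) {
  keep <- rep(TRUE, length(fs$time))
  if (!is.null(from)) keep <- keep & fs$time >= as.Date(paste0(from, "-01"))
  if (!is.null(to)) keep <- keep & fs$time <= as.Date(paste0(to, "-01"))
  if (!any(keep)) stopf("empty time window")
  field_series(fs$values[, , keep, drop = FALSE], fs$grid, fs$time[keep],
               fs$units, fs$name)
}

#' Time-mean field of a FieldSeries
#'
#' @param fs a `field_series`
#' @param from,to optional inclusive `"YYYY-MM"` bounds
#' @return matrix `[n_lat, n_lon]` of per-cell temporal means (NA where no
#'   valid months)
#' @export
fs_time_mean <- function(fs, from = NULL, to = NULL) {
  fs <- fs_window(fs, from, to)
  m <- apply(fs$values, c(1, 2), mean, na.rm = TRUE)
  m[!is.finite(m)] <- NA_real_
  m
}

# ---- netCDF I/O (CF-style: lat, lon, time coordinates; units attrs) --------

#' Write a FieldSeries to a CF-style netCDF file
#'
#' @param fs a [field_series()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_fields <- function(fs, path) {
  stopifnot(inherits(fs, "field_series"))
  cc <- grid_centers(fs$grid)
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", cc$lon)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", cc$lat)
  dim_time <- ncdf4::ncdim_def("time", "days since 1970-01-01",
                               as.numeric(fs$time), unlim = TRUE)
  fill <- -9.96921e36
  var <- ncdf4::ncvar_def(fs$name, fs$units, list(dim_lon, dim_lat, dim_time),
                          missval = fill, prec = "double")
  nc <- ncdf4::nc_create(path, var)
  on.exit(ncdf4::nc_close(nc))
  # internal layout is [lat, lon, time]; netCDF var is (lon, lat, time)
  ncdf4::ncvar_put(nc, var, aperm(fs$values, c(2, 1, 3)))
  invisible(path)
}

#' Read a FieldSeries from a CF-style netCDF file
#'
#' Requires `lat`, `lon` and `time` coordinate variables and a `units`
#' attribute on the requested variable; the returned series is time-sorted.
#'
#' @param path netCDF file path
#' @param variable variable name; default: the file's first non-coordinate
#'   variable
#' @return a [field_series()]
#' @export
read_fields <- function(path, variable = NULL) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  if (is.null(variable)) variable <- names(nc$var)[1]
  if (!variable %in% names(nc$var))
    stopf("variable '%s' not found in %s", variable, path)
  need <- c("lat", "lon", "time")
  have <- c(names(nc$dim), names(nc$var))
  if (!all(need %in% have))
    stopf("format error: missing coordinate variable(s): %s",
          paste(setdiff(need, have), collapse = ", "))
  units <- ncdf4::ncatt_get(nc, variable, "units")
  if (!units$hasatt || !nzchar(units$value))
    stopf("format error: variable '%s' lacks a units attribute", variable)
  lat <- as.numeric(ncdf4::ncvar_get(nc, "lat"))
  lon <- as.numeric(ncdf4::ncvar_get(nc, "lon"))
  time <- as.Date(as.numeric(ncdf4::ncvar_get(nc, "time")), origin = "1970-01-01")
  vals <- ncdf4::ncvar_get(nc, variable, collapse_degen = FALSE)
  if (length(dim(vals)) == 2) dim(vals) <- c(dim(vals), 1L)
  vals <- aperm(vals, c(2, 1, 3)) # (lon, lat, time) -> [lat, lon, time]
  o <- order(time)
  vals <- vals[, , o, drop = FALSE]
  time <- time[o]
  # reconstruct edges from centers (assumes locally uniform spacing)
  grid <- geo_grid(edges_from_centers(lat, -90, 90),
                   edges_from_centers(lon, -180, 180))
  field_series(vals, grid, time, units$value, variable)
}

edges_from_centers <- function(c, lo, hi) {
  if (length(c) == 1) return(c(lo, hi))
  mid <- (c[-1] + c[-length(c)]) / 2
  c(max(lo, 2 * c[1] - mid[1]), mid, min(hi, 2 * c[length(c)] - mid[length(mid)]))
}
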