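# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk.

# small global grid with ncell = nlat * nlon cells
toy_grid <- function(nlat = 10, nlon = 20, lat_range = c(-60, 60)) {
  geo_grid(seq(lat_range[1], lat_range[2], length.out = nlat + 1),
           seq(-180, 180, length.out = nlon + 1))
}

# AR(1) noise matrix [ncell, ntime], stationary start
sim_ar1 <- function(ncell, ntime, rho, sd = 1) {
  x <- matrix(NA_real_, ncell, ntime)
  x[, 1] <- rnorm(ncell, 0, sd / sqrt(1 - rho^2))
  for (t in 2:ntime) x[, t] <- rho * x[, t - 1] + rnorm(ncell, 0, sd)
  x
}

# field_series wrapping a [ncell, ntime] matrix onto a toy grid
mat_to_fs <- function(m, grid, start = "1997-09", units = "mg C m-2 d-1",
                      name = "x") {
  nt <- ncol(m)
  field_series(array(m, c(length(grid$lat_edges) - 1,
                          length(grid$lon_edges) - 1, nt)),
               grid, month_seq(start, nt), units, name)
}

# independent closed-form OLS slope oracle (sum of deviation products over
# sum of squared deviations), NA-aware
ols_slope_oracle <- function(y, t) {
  ok <- !is.na(y)
  x <- t[ok]; yy <- y[ok]
  sum((x - mean(x)) * (yy - mean(yy))) / sum((x - mean(x))^2)
}

# noise-free synthetic configuration (deterministic fields)
quiet_config <- function(...) {
  synth_config(cloud_fraction = 0, cphyto_sdlog = 0,
               sd = c(npp = 0, par = 0, aph_frac = 0, sst = 0, aph = 0,
                      adg = 0, cphyto = 0, mld = 0),
               ...)
}
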