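# Synthetic gridded-ocean generator with known planted truth.
#
# Emulates the statistical structure a satellite ocean-color archive hands to
# the trend pipeline: 12-month seasonal cycles varying with latitude,
# spatially varying linear trends whose sign flips across a mean-SST
# isotherm, AR(1) residual noise initialized from its stationary
# distribution, planted spatial modes driven by index time series, cloud and
# polar-night missingness, and a stationary per-calendar-month inter-mission
# bias. NPP is constructed exactly as PAR * (aph/a) * phi_mu and the growth
# rate exactly as NPP / Cphyto, so the multiplicative identity holds to
# machine precision by construction.

#' Synthetic dataset configuration
#'
#' Defaults describe the desk-scale study conditions: a 2 degree global grid,
#' 300 months starting 1997-09, AR(1) noise, an NPP trend of -30
#' mg C m-2 d-1 per decade where mean SST exceeds 15 C and +20 below, 5%
#' random cloud cover and polar-night missingness where PAR < 1 mol photons
#' m-2 d-1.
#'
#' @param res_deg grid resolution, degrees
#' @param start first month (`"YYYY-MM"`)
#' @param n_months number of months
#' @param seed integer RNG seed; identical config + seed gives a
#'   bit-identical dataset
#' @param land include idealized continents (`FALSE` = all-ocean globe)
#' @param rho named vector of AR(1) coefficients per component, each in
#'   `[0, 1)`
#' @param sd named vector of AR(1) innovation standard deviations (component
#'   units)
#' @param npp_trend optional `[n_lat, n_lon]` matrix of planted NPP slopes
#'   (mg C m-2 d-1 per decade); overrides the isotherm rule
#' @param npp_trend_warm,npp_trend_cold NPP slope per decade where mean SST
#'   is above / below `isotherm_c`
#' @param isotherm_c SST isotherm (deg C) where the planted trend changes sign
#' @param trend named list of scalar slopes per decade for the remaining
#'   components (matrices allowed)
#' @param modes list of planted NPP anomaly modes; each element is a list
#'   with `pattern` (`[n_lat, n_lon]` matrix or `function(lat, lon)`),
#'   `loading` (amplitude, mg C m-2 d-1), and either `index` (numeric
#'   `n_months` series) or `rho_index`/`sd_index` to generate one
#' @param bias_table per-calendar-month mission-A bias: numeric of length 12
#'   or `[n_lat, n_lon, 12]` array (mg C m-2 d-1)
#' @param cloud_fraction probability a cell-month of ocean-color data is lost
#'   to cloud
#' @param par_night_threshold PAR (mol photons m-2 d-1) below which
#'   ocean-color retrievals are missing (polar night)
#' @param cphyto_sdlog lognormal scatter of phytoplankton carbon around its
#'   latitude-dependent mean
#' @param below_frac_base,below_frac_trend base fraction of NPP beneath the
#'   mixed layer and its absolute change per decade
#' @return an object of class `synth_config`
#' @export
synth_config <- function(res_deg = 2, start = "1997-09", n_months = 300,
                         seed = 1, land = TRUE,
                         rho = NULL, sd = NULL,
                         npp_trend = NULL,
                         npp_trend_warm = -30, npp_trend_cold = 20,
                         isotherm_c = 15,
                         trend = NULL,
                         modes = list(),
                         bias_table = NULL,
                         cloud_fraction = 0.05,
                         par_night_threshold = 1,
                         cphyto_sdlog = 0.08,
                         below_frac_base = 0.22, below_frac_trend = 0.035) {
  rho_def <- c(npp = 0.3, par = 0.2, aph_frac = 0.3, sst = 0.5,
               aph = 0.3, adg = 0.3, cphyto = 0.2, mld = 0.3)
  sd_def <- c(npp = 15, par = 1.5, aph_frac = 0.008, sst = 0.3,
              aph = 8e-4, adg = 6e-4, cphyto = 60, mld = 4)
  trend_def <- list(par = 0, aph_frac = -0.004, sst = 0.2,
                    aph = -4e-4, adg = -2e-4, cphyto = -15, mld = 0)
  if (!is.null(rho)) rho_def[names(rho)] <- rho
  if (!is.null(sd)) sd_def[names(sd)] <- sd
  if (!is.null(trend)) trend_def[names(trend)] <- trend
  if (any(rho_def < 0 | rho_def >= 1))
    stopf("AR(1) coefficients must lie in [0, 1)")
  if (any(sd_def < 0)) stopf("innovation SDs must be >= 0")
  if (cloud_fraction < 0 || cloud_fraction > 1)
    stopf("cloud_fraction must be in [0, 1]")
  if (n_months < 24) stopf("need at least 24 months")
  structure(list(
    res_deg = res_deg, start = start, n_months = n_months, seed = seed,
    land = land, rho = rho_def, sd = sd_def,
    npp_trend = npp_trend, npp_trend_warm = npp_trend_warm,
    npp_trend_cold = npp_trend_cold, isotherm_c = isotherm_c,
    trend = trend_def, modes = modes, bias_table = bias_table,
    cloud_fraction = cloud_fraction,
    par_night_threshold = par_night_threshold,
    cphyto_sdlog = cphyto_sdlog,
    below_frac_base = below_frac_base, below_frac_trend = below_frac_trend),
    class = "synth_config")
}

#' Idealized ocean mask
#'
#' Deterministic block continents (two Americas-like and Afro-Eurasian
#' landmasses, Australia, Antarctica) giving roughly 70% ocean.
#'
#' @param grid a [geo_grid()]
#' @param land if `FALSE`, every cell is ocean
#' @return logical `[n_lat, n_lon]` matrix, `TRUE` = ocean
#' @export
ocean_mask <- function(grid, land = TRUE) {
  cc <- grid_centers(grid)
  lat <- matrix(cc$lat, n_lat(grid), n_lon(grid))
  lon <- matrix(cc$lon, n_lat(grid), n_lon(grid), byrow = TRUE)
  if (!land) return(matrix(TRUE, n_lat(grid), n_lon(grid)))
  landm <-
    (lon >= -85 & lon <= -35 & lat >= -55 & lat <= 10) |
    (lon >= -125 & lon <= -65 & lat >= 10 & lat <= 70) |
    (lon >= -15 & lon <= 50 & lat >= -35 & lat <= 35) |
    (lon >= 5 & lon <= 140 & lat >= 35 & lat <= 75) |
    (lon >= 110 & lon <= 155 & lat >= -40 & lat <= -12) |
    (lat <= -78)
  !landm
}

# Latitude-dependent climatology builders. `m` is calendar month 1..12,
# `lat` in degrees; seasonal phase peaks in the local summer.
season_cos <- function(m, lat) {
  peak <- ifelse(lat >= 0, 7.5, 1.5) # mid-July north, mid-January south
  cos(2 * pi * (m - peak) / 12)
}

clim_funs <- list(
  sst = function(lat, m) -2 + 32 * cos(lat * pi / 180)^2 +
    1.5 * season_cos(m, lat) * sin(abs(lat) * pi / 180),
  par = function(lat, m) pmax(0.1, 40 * cos(lat * pi / 180) +
    28 * sin(abs(lat) * pi / 180) * season_cos(m, lat)),
  npp = function(lat, m) {
    base <- 350 + 300 * cos(lat * pi / 180)^2
    base + 0.5 * base * sin(abs(lat) * pi / 180) * season_cos(m, lat)
  },
  aph_frac = function(lat, m) 0.30 + 0.05 * cos(lat * pi / 180) +
    0.02 * season_cos(m, lat),
  aph = function(lat, m) 0.02 + 0.01 * sin(abs(lat) * pi / 180) +
    0.004 * season_cos(m, lat),
  adg = function(lat, m) 0.015 + 0.008 * sin(abs(lat) * pi / 180) +
    0.002 * season_cos(m, lat),
  cphyto = function(lat, m) 800 + 1200 * cos(lat * pi / 180)^2 +
    200 * season_cos(m, lat) * sin(abs(lat) * pi / 180),
  mld = function(lat, m) 40 + 60 * sin(abs(lat) * pi / 180)^2 -
    30 * season_cos(m, lat) * sin(abs(lat) * pi / 180)
)

clim_array <- function(fun, lat_c, n_lon_) {
  arr <- array(NA_real_, c(length(lat_c), n_lon_, 12))
  for (m in 1:12) arr[, , m] <- matrix(fun(lat_c, m), length(lat_c), n_lon_)
  arr
}

# AR(1) noise field [n_cell, n_time], stationary initialization.
ar1_noise <- function(n_cell, n_time, rho, sd) {
  if (sd == 0) return(matrix(0, n_cell, n_time))
  x <- matrix(NA_real_, n_cell, n_time)
  x[, 1] <- rnorm(n_cell, 0, sd / sqrt(1 - rho^2))
  for (t in 2:n_time) x[, t] <- rho * x[, t - 1] + rnorm(n_cell, 0, sd)
  x
}

as_pattern <- function(p, grid) {
  if (is.function(p)) {
    cc <- grid_centers(grid)
    lat <- matrix(cc$lat, n_lat(grid), n_lon(grid))
    lon <- matrix(cc$lon, n_lat(grid), n_lon(grid), byrow = TRUE)
    p <- p(lat, lon)
  }
  stopifnot(is.matrix(p))
  p
}

#' Generate a synthetic multi-component ocean dataset
#'
#' @param config a [synth_config()]
#' @return list with `fields` (named [field_series()] for `npp`, `par`,
#'   `aph_frac`, `phi_mu`, `aph`, `adg`, `cphyto`, `mu`, `sst`, `mld`,
#'   `npp_below`), `mask` (ocean mask), `grid`, and `truth` — the
#'   planted slopes, climatologies, modes, noise parameters and missingness
#'   needed to score recovery
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  grid <- grid_regular(config$res_deg)
  nla <- n_lat(grid); nlo <- n_lon(grid)
  n_cell <- nla * nlo
  time <- month_seq(config$start, config$n_months)
  months <- month_of(time)
  t_dec <- decimal_years(time)
  t_c <- (t_dec - mean(t_dec)) / 10 # centered, in decades
  mask <- ocean_mask(grid, config$land)
  cc <- grid_centers(grid)

  # mean-SST field drives the isotherm trend rule
  sst_clim <- clim_array(clim_funs$sst, cc$lat, nlo)
  sst_mean0 <- apply(sst_clim, c(1, 2), mean)
  npp_slope <- config$npp_trend
  if (is.null(npp_slope)) {
    npp_slope <- ifelse(sst_mean0 > config$isotherm_c,
                        config$npp_trend_warm, config$npp_trend_cold)
  }

  units <- c(npp = "mg C m-2 d-1", par = "mol photons m-2 d-1",
             aph_frac = "1", phi_mu = "mg C (mol photons)-1",
             aph = "m-1", adg = "m-1", cphyto = "mg C m-2", mu = "d-1",
             sst = "degree_C", mld = "m", npp_below = "mg C m-2 d-1")

  # stochastic base components: climatology + trend + AR(1) noise
  comp_names <- c("sst", "par", "npp", "aph_frac", "aph", "adg", "cphyto", "mld")
  clims <- lapply(comp_names, function(nm) clim_array(clim_funs[[nm]], cc$lat, nlo))
  names(clims) <- comp_names
  slopes <- lapply(comp_names, function(nm) {
    if (nm == "npp") return(npp_slope)
    s <- config$trend[[nm]]
    if (is.matrix(s)) s else matrix(s, nla, nlo)
  })
  names(slopes) <- comp_names

  fields <- list()
  for (nm in comp_names) {
    vals <- clims[[nm]][, , months, drop = FALSE] +
      outer(slopes[[nm]], t_c)
    noise <- ar1_noise(n_cell, config$n_months, config$rho[[nm]], config$sd[[nm]])
    dim(noise) <- c(nla, nlo, config$n_months)
    fields[[nm]] <- vals + noise
  }

  # planted NPP anomaly modes: loading * pattern * index(t)
  modes <- lapply(config$modes, function(md) {
    pat <- as_pattern(md$pattern, grid)
    idx <- md$index
    if (is.null(idx)) {
      rho_i <- if (is.null(md$rho_index)) 0.8 else md$rho_index
      sd_i <- if (is.null(md$sd_index)) 1 else md$sd_index
      idx <- as.vector(ar1_noise(1, config$n_months, rho_i, sd_i * sqrt(1 - rho_i^2)))
    }
    loading <- if (is.null(md$loading)) 1 else md$loading
    list(pattern = pat, index = idx, loading = loading)
  })
  for (md in modes) {
    fields$npp <- fields$npp +
      outer(md$loading * md$pattern, md$index)
  }

  fields$par <- pmax(fields$par, 0.01)
  fields$aph_frac <- pmin(pmax(fields$aph_frac, 0.01), 0.95)
  fields$cphyto <- pmax(fields$cphyto, 50)
  fields$mld <- pmax(fields$mld, 5)
  # multiplicative identity holds exactly by construction
  fields$phi_mu <- fields$npp / (fields$par * fields$aph_frac)
  fields$cphyto <- fields$cphyto *
    array(rlnorm(n_cell * config$n_months, 0, config$cphyto_sdlog),
          c(nla, nlo, config$n_months))
  fields$mu <- fields$npp / fields$cphyto
  below_frac <- pmin(pmax(
    config$below_frac_base + 0.1 * cos(matrix(cc$lat, nla, nlo) * pi / 180)^2,
    0.02), 0.5)
  below_frac_t <- outer(below_frac, rep(1, config$n_months)) +
    outer(matrix(config$below_frac_trend, nla, nlo), t_c)
  below_frac_t <- pmin(pmax(below_frac_t, 0), 0.6)
  fields$npp_below <- below_frac_t * fields$npp

  # missingness: land always; clouds + polar night for ocean-color fields
  cloud <- array(runif(n_cell * config$n_months) < config$cloud_fraction,
                 c(nla, nlo, config$n_months))
  night <- fields$par < config$par_night_threshold
  color_miss <- cloud | night
  land3 <- array(!mask, c(nla, nlo, config$n_months))
  color_fields <- c("npp", "par", "aph_frac", "phi_mu", "aph", "adg",
                    "cphyto", "mu", "npp_below")
  for (nm in names(fields)) {
    miss <- if (nm %in% color_fields) color_miss | land3 else land3
    fields[[nm]][miss] <- NA_real_
  }

  fs <- mapply(function(v, nm) field_series(v, grid, time, units[[nm]], nm),
               fields, names(fields), SIMPLIFY = FALSE)

  truth <- list(
    slopes = slopes, clims = clims, modes = modes,
    rho = config$rho, sd = config$sd,
    sst_mean = sst_mean0, isotherm_c = config$isotherm_c,
    bias_table = config$bias_table,
    missing_fraction = mean(color_miss[!land3]),
    below_frac_trend = config$below_frac_trend,
    time = time, seed = config$seed)
  list(fields = fs, mask = mask, grid = grid, truth = truth)
}

#' Generate two overlapping satellite missions from one underlying truth
#'
#' Mission B carries the underlying NPP truth on its date range; mission A is
#' truth plus a stationary per-calendar-month bias on its range. Both share
#' the truth's noise realization over the overlap, mimicking two sensors
#' viewing one ocean.
#'
#' @param config a [synth_config()]; its `bias_table` (length-12 vector or
#'   `[n_lat, n_lon, 12]` array) is the planted mission-A bias (default:
#'   a sinusoidal per-month offset, A biased low)
#' @param a_end last month of mission A (`"YYYY-MM"`)
#' @param b_start first month of mission B
#' @return list with `a`, `b` ([field_series()] of NPP), `truth_npp` (the
#'   unbiased full-record NPP series), `bias` (the `[n_lat, n_lon, 12]` bias
#'   actually applied), `mask`, `grid`, `truth`
#' @export
generate_two_missions <- function(config, a_end = "2007-12", b_start = "2002-07") {
  ds <- generate_dataset(config)
  npp <- ds$fields$npp
  time <- npp$time
  a_keep <- time <= as.Date(paste0(a_end, "-01"))
  b_keep <- time >= as.Date(paste0(b_start, "-01"))
  n_overlap <- sum(a_keep & b_keep)
  if (n_overlap < 12)
    stopf("mission overlap is %d months; need >= 12 to form monthly climatology differences",
          n_overlap)
  nla <- n_lat(ds$grid); nlo <- n_lon(ds$grid)
  bias <- config$bias_table
  if (is.null(bias)) bias <- -20 + 10 * cos(2 * pi * (1:12) / 12)
  if (is.null(dim(bias))) {
    stopifnot(length(bias) == 12)
    bias <- array(rep(bias, each = nla * nlo), c(nla, nlo, 12))
  }
  stopifnot(all(dim(bias) == c(nla, nlo, 12)))
  a_vals <- npp$values[, , a_keep, drop = FALSE] +
    bias[, , month_of(time[a_keep]), drop = FALSE]
  a <- field_series(a_vals, ds$grid, time[a_keep], npp$units, "npp_mission_a")
  b <- field_series(npp$values[, , b_keep, drop = FALSE], ds$grid,
                    time[b_keep], npp$units, "npp_mission_b")
  ds$truth$bias_table <- bias
  list(a = a, b = b, truth_npp = npp, bias = bias,
       mask = ds$mask, grid = ds$grid, truth = ds$truth, dataset = ds)
}
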