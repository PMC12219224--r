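# NPP component bookkeeping: the multiplicative identity, growth rates,
# global annual totals with climatological gap filling, and the fraction of
# production beneath the surface mixed layer.

MG_TO_PG <- 1e-18

#' Residual of the absorption-based NPP identity
#'
#' NPP is modeled as the product of PAR, the fraction of PAR absorbed by
#' phytoplankton (aph/a), and the net photosynthetic carbon efficiency
#' (phi_mu). This reports the residual `NPP - PAR * (aph/a) * phi_mu`;
#' on internally consistent data it is zero to machine precision.
#'
#' @param npp,par,aph_frac,phi_mu aligned [field_series()]
#' @return list: `max_abs_relative` residual over valid cells,
#'   `mean_abs_relative`, `n_valid`
#' @export
identity_residual <- function(npp, par, aph_frac, phi_mu) {
  if (!grepl("mg C", npp$units, fixed = TRUE))
    stopf("unit mismatch: NPP units are '%s', expected mg C m-2 d-1", npp$units)
  prod <- par$values * aph_frac$values * phi_mu$values
  resid <- npp$values - prod
  ok <- !is.na(resid) & !is.na(npp$values) & npp$values != 0
  rel <- abs(resid[ok]) / abs(npp$values[ok])
  list(max_abs_relative = if (any(ok)) max(rel) else NA_real_,
       mean_abs_relative = if (any(ok)) mean(rel) else NA_real_,
       n_valid = sum(ok))
}

#' Phytoplankton specific growth rate
#'
#' mu = NPP / Cphyto (per day, with NPP in mg C m-2 d-1 and euphotic-zone
#' integrated Cphyto in mg C m-2). Cells with non-positive Cphyto are left
#' missing and counted.
#'
#' @param npp,cphyto aligned [field_series()]
#' @return a [field_series()] of mu (d-1); attribute `n_nonpositive` counts
#'   dropped cells
#' @export
growth_rate <- function(npp, cphyto) {
  bad <- !is.na(cphyto$values) & cphyto$values <= 0
  denom <- cphyto$values
  denom[bad] <- NA_real_
  mu <- npp$values / denom
  out <- field_series(mu, npp$grid, npp$time, "d-1", "mu")
  attr(out, "n_nonpositive") <- sum(bad)
  out
}

#' Global NPP totals with climatological gap filling
#'
#' Monthly global total = sum over cells of NPP * area * days-in-month,
#' converted mg C to Pg C. Cells where NPP is missing are filled with the
#' monthly climatology, but only inside the sunlit domain (climatological
#' PAR above `par_threshold`); missing climatology inside that domain is
#' counted and left unfilled. Annual totals sum complete calendar years.
#'
#' @param npp NPP [field_series()] (mg C m-2 d-1)
#' @param clim NPP [monthly_climatology()] used for filling
#' @param par_clim PAR [monthly_climatology()] defining the sunlit fill
#'   domain
#' @param areas cell-area matrix (m2)
#' @param mask logical ocean mask
#' @param par_threshold mol photons m-2 d-1 (default 1)
#' @return object of class `global_series`: `monthly` data.frame (date,
#'   total_pg, rate_pg_yr, filled_area_fraction, n_unfillable), `annual`
#'   data.frame (year, total_pg, complete)
#' @export
global_annual_npp <- function(npp, clim, par_clim, areas, mask,
                              par_threshold = 1) {
  stopifnot(inherits(npp, "field_series"), inherits(clim, "climatology"),
            inherits(par_clim, "climatology"))
  nt <- length(npp$time)
  mo <- month_of(npp$time)
  dim_days <- days_in_month(npp$time)
  ocean_area <- sum(areas[mask])
  total <- filled_frac <- unfillable <- numeric(nt)
  for (t in seq_len(nt)) {
    v <- npp$values[, , t]
    fill_dom <- mask & is.na(v) & !is.na(par_clim$mean[, , mo[t]]) &
      par_clim$mean[, , mo[t]] > par_threshold
    cv <- clim$mean[, , mo[t]]
    can_fill <- fill_dom & !is.na(cv)
    v[can_fill] <- cv[can_fill]
    unfillable[t] <- sum(fill_dom & is.na(cv))
    filled_frac[t] <- sum(areas[can_fill]) / ocean_area
    use <- mask & !is.na(v)
    total[t] <- sum(v[use] * areas[use]) * dim_days[t] * MG_TO_PG
  }
  n_unfill_tot <- sum(unfillable)
  if (n_unfill_tot > 0)
    warning(sprintf("%d cell-months inside the sunlit domain had no climatology to fill with",
                    n_unfill_tot), call. = FALSE)
  monthly <- data.frame(date = npp$time, total_pg = total,
                        rate_pg_yr = total / dim_days * 365.25,
                        filled_area_fraction = filled_frac,
                        n_unfillable = unfillable)
  yr <- year_of(npp$time)
  annual <- do.call(rbind, lapply(sort(unique(yr)), function(y) {
    sel <- yr == y
    data.frame(year = y, total_pg = sum(total[sel]), complete = sum(sel) == 12)
  }))
  structure(list(monthly = monthly, annual = annual),
            class = "global_series")
}

#' @export
print.global_series <- function(x, ...) {
  comp <- x$annual[x$annual$complete, ]
  cat(sprintf("global_series: %d months; %d complete years, mean %.1f Pg C yr-1\n",
              nrow(x$monthly), nrow(comp), mean(comp$total_pg)))
  invisible(x)
}

#' Linear trend of global annual NPP
#'
#' OLS on complete-year annual totals versus calendar year. The net percent
#' change over the record is `100 * slope * n_years / mean`.
#'
#' @param gs a [global_annual_npp()] result (or a data.frame with `year`,
#'   `total_pg`)
#' @param min_years minimum annual values required (default 10)
#' @return list: `slope_pg_decade`, `slope_pg_yr`, `se_slope_pg_yr`,
#'   `ci90_halfwidth_pg_decade`, `mean_pg`, `sd_pg`, `net_pct_change`,
#'   `n_years`
#' @export
fit_global_trend <- function(gs, min_years = 10) {
  ann <- if (inherits(gs, "global_series")) gs$annual[gs$annual$complete, ] else gs
  n <- nrow(ann)
  if (n < min_years) stopf("only %d annual values (need >= %d)", n, min_years)
  x <- ann$year; y <- ann$total_pg
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  res <- y - (mean(y) + slope * (x - mean(x)))
  se <- sqrt(sum(res^2) / (n - 2) / sxx)
  list(slope_pg_decade = slope * 10, slope_pg_yr = slope,
       se_slope_pg_yr = se,
       ci90_halfwidth_pg_decade = qt(0.95, n - 2) * se * 10,
       mean_pg = mean(y), sd_pg = sd(y),
       net_pct_change = 100 * slope * n / mean(y),
       n_years = n)
}

#' Fraction of global NPP beneath the surface mixed layer
#'
#' Ratio of the global integral of below-mixed-layer NPP to total NPP,
#' monthly and by calendar year, over cells where both fields are valid.
#'
#' @param npp_total,npp_below aligned [field_series()] (mg C m-2 d-1)
#' @param areas cell-area matrix
#' @param mask logical ocean mask
#' @return list: `monthly` data.frame (date, fraction), `annual` data.frame
#'   (year, fraction, complete); months with zero total are NA and flagged
#' @export
below_mld_fraction <- function(npp_total, npp_below, areas, mask) {
  nt <- length(npp_total$time)
  dim_days <- days_in_month(npp_total$time)
  tot <- below <- numeric(nt)
  for (t in seq_len(nt)) {
    vt <- npp_total$values[, , t]
    vb <- npp_below$values[, , t]
    use <- mask & !is.na(vt) & !is.na(vb)
    tot[t] <- sum(vt[use] * areas[use]) * dim_days[t]
    below[t] <- sum(vb[use] * areas[use]) * dim_days[t]
  }
  frac <- ifelse(tot > 0, below / tot, NA_real_)
  monthly <- data.frame(date = npp_total$time, fraction = frac,
                        undefined = tot <= 0)
  yr <- year_of(npp_total$time)
  annual <- do.call(rbind, lapply(sort(unique(yr)), function(y) {
    sel <- yr == y & tot > 0
    data.frame(year = y,
               fraction = if (any(sel)) sum(below[sel]) / sum(tot[sel]) else NA_real_,
               complete = sum(yr == y) == 12)
  }))
  list(monthly = monthly, annual = annual)
}
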