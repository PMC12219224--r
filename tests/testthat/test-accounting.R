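test_that("the absorption-product identity and its arithmetic hold", {
  g <- toy_grid(1, 1)
  mk <- function(v, units, name) field_series(array(v, c(1, 1, 1)), g,
                                              month_seq("2000-01", 1), units, name)
  # PAR 40 x (aph/a) 0.05 x phi_mu 250 = 500 mg C m-2 d-1
  npp <- mk(500, "mg C m-2 d-1", "npp")
  out <- identity_residual(npp, mk(40, "mol photons m-2 d-1", "par"),
                           mk(0.05, "1", "aph_frac"),
                           mk(250, "mg C (mol photons)-1", "phi_mu"))
  expect_equal(out$max_abs_relative, 0)
  # any zero factor zeroes the product
  prod0 <- 40 * 0 * 250
  expect_equal(prod0, 0)
  # unit mismatch is an error
  expect_error(identity_residual(mk(500, "W m-2", "npp"),
                                 mk(40, "mol photons m-2 d-1", "par"),
                                 mk(0.05, "1", "a"), mk(250, "u", "p")),
               "unit")
})

test_that("growth rates follow mu = NPP / Cphyto with guarded denominators", {
  g <- toy_grid(1, 3)
  # one time step, three cells
  npp3 <- field_series(array(c(500, 0, 500), c(1, 3, 1)), g,
                       month_seq("2000-01", 1), "mg C m-2 d-1", "npp")
  cph3 <- field_series(array(c(1000, 1000, -5), c(1, 3, 1)), g,
                       month_seq("2000-01", 1), "mg C m-2", "cphyto")
  mu <- growth_rate(npp3, cph3)
  expect_equal(mu$values[1, 1, 1], 0.5)
  expect_equal(mu$values[1, 2, 1], 0)
  expect_true(is.na(mu$values[1, 3, 1]))
  expect_equal(attr(mu, "n_nonpositive"), 1L)
  expect_identical(mu$units, "d-1")
})

test_that("global totals match the closed-form integration oracle", {
  g <- grid_regular(2)
  areas <- cell_areas(g)
  # scale a mask to a known ocean area of 3.619e14 m2
  target <- 3.619e14
  ord <- order(as.vector(areas), decreasing = TRUE)
  csum <- cumsum(as.vector(areas)[ord])
  keep <- ord[seq_len(which.min(abs(csum - target)))]
  mask <- matrix(FALSE, 90, 180); mask[keep] <- TRUE
  ocean_area <- sum(areas[mask])
  n <- 12
  time <- month_seq("2001-01", n) # 365-day year
  npp <- field_series(array(500, c(90, 180, n)), g, time, "mg C m-2 d-1", "npp")
  clim <- monthly_climatology(npp, min_count = 1)
  par_clim <- monthly_climatology(
    field_series(array(40, c(90, 180, n)), g, time, "mol photons m-2 d-1", "par"),
    min_count = 1)
  gs <- global_annual_npp(npp, clim, par_clim, areas, mask)
  oracle <- 500 * 365 * ocean_area * 1e-18 # mg m-2 d-1 -> Pg over the year
  expect_equal(gs$annual$total_pg, oracle, tolerance = 1e-12)
  expect_equal(gs$annual$total_pg, 66.1, tolerance = 0.002)
  expect_true(all(gs$monthly$filled_area_fraction == 0))
  # a zero field integrates to zero
  npp0 <- field_series(array(0, c(90, 180, n)), g, time, "mg C m-2 d-1", "npp")
  gs0 <- global_annual_npp(npp0, monthly_climatology(npp0, min_count = 1),
                           par_clim, areas, mask)
  expect_equal(gs0$annual$total_pg, 0)
  # totals scale linearly with the field
  npp2 <- npp; npp2$values <- npp$values * 2
  gs2 <- global_annual_npp(npp2, monthly_climatology(npp2, min_count = 1),
                           par_clim, areas, mask)
  expect_equal(gs2$annual$total_pg, 2 * gs$annual$total_pg, tolerance = 1e-12)
})

test_that("climatological gap filling restores noise-free seasonal totals exactly", {
  set.seed(60)
  g <- grid_regular(6)
  areas <- cell_areas(g)
  mask <- matrix(TRUE, 30, 60)
  n <- 36
  time <- month_seq("2001-01", n)
  mo <- as.integer(format(time, "%m"))
  cyc <- 300 + 200 * sin(2 * pi * (1:12) / 12)
  full <- array(rep(cyc[mo], each = 30 * 60), c(30, 60, n))
  npp_full <- field_series(full, g, time, "mg C m-2 d-1", "npp")
  clim <- monthly_climatology(npp_full, min_count = 1)
  par_clim <- monthly_climatology(
    field_series(array(40, c(30, 60, n)), g, time, "mol photons m-2 d-1", "par"),
    min_count = 1)
  gs_full <- global_annual_npp(npp_full, clim, par_clim, areas, mask)
  holed <- full
  holed[sample(length(holed), round(0.05 * length(holed)))] <- NA
  gs_holed <- global_annual_npp(field_series(holed, g, time, "mg C m-2 d-1", "npp"),
                                clim, par_clim, areas, mask)
  expect_equal(gs_holed$annual$total_pg, gs_full$annual$total_pg,
               tolerance = 1e-10)
  expect_true(any(gs_holed$monthly$filled_area_fraction > 0))
  # outside the sunlit domain nothing is filled
  par_dark <- monthly_climatology(
    field_series(array(0.5, c(30, 60, n)), g, time, "mol photons m-2 d-1", "par"),
    min_count = 1)
  gs_dark <- global_annual_npp(field_series(holed, g, time, "mg C m-2 d-1", "npp"),
                               clim, par_dark, areas, mask)
  expect_true(all(gs_dark$monthly$filled_area_fraction == 0))
  expect_lt(gs_dark$annual$total_pg[1], gs_full$annual$total_pg[1])
})

test_that("the global trend fit matches line arithmetic", {
  years <- 1998:2022
  ann <- data.frame(year = years, total_pg = 60 - 0.18 * (years - 1998))
  ft <- fit_global_trend(ann)
  expect_equal(ft$slope_pg_decade, -1.8, tolerance = 1e-10)
  expect_equal(ft$mean_pg, 60 - 0.18 * 12, tolerance = 1e-12)
  expect_equal(ft$net_pct_change, 100 * (-0.18) * 25 / ft$mean_pg,
               tolerance = 1e-10)
  expect_equal(round(ft$net_pct_change, 1), -7.8)
  # constant record: zero slope, zero net change
  ft0 <- fit_global_trend(data.frame(year = years, total_pg = rep(57, 25)))
  expect_equal(ft0$slope_pg_decade, 0)
  expect_equal(ft0$net_pct_change, 0)
  expect_error(fit_global_trend(ann[1:5, ]), "annual values")
})

test_that("below-MLD fractions follow the integral ratio and recover planted deepening", {
  g <- toy_grid(4, 6)
  areas <- cell_areas(g)
  mask <- matrix(TRUE, 4, 6)
  n <- 48
  tot <- mat_to_fs(matrix(400, 24, n), g, "2000-01", name = "npp")
  quarter <- mat_to_fs(matrix(100, 24, n), g, "2000-01", name = "npp_below")
  bf <- below_mld_fraction(tot, quarter, areas, mask)
  expect_true(all(abs(bf$monthly$fraction - 0.25) < 1e-12))
  zero <- mat_to_fs(matrix(0, 24, n), g, "2000-01", name = "npp_below")
  expect_true(all(below_mld_fraction(tot, zero, areas, mask)$monthly$fraction == 0))
  # below-MLD share trending up while the total trends down
  cfg <- quiet_config(res_deg = 12, n_months = 120, seed = 61)
  ds <- generate_dataset(cfg)
  bf2 <- below_mld_fraction(ds$fields$npp, ds$fields$npp_below,
                            cell_areas(ds$grid), ds$mask)
  yrs <- bf2$annual[bf2$annual$complete, ]
  fit <- coef(lm(fraction ~ year, data = yrs))
  expect_gt(fit[["year"]], 0)
})
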