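test_that("effective sample size follows the lag-1 reduction formula", {
  set.seed(40)
  # oracle: recompute rho independently and apply n(1-rho)/(1+rho)
  x <- as.numeric(arima.sim(list(ar = 0.6), 303))
  out <- ar1_effective_n(x)
  rho_oracle <- cor(x[-303], x[-1])
  expect_equal(out$rho, rho_oracle, tolerance = 1e-12)
  expect_equal(out$n_eff, 303 * (1 - rho_oracle) / (1 + rho_oracle),
               tolerance = 1e-12)
  # the closed form at rho = 0.5, n = 303 gives n_eff = 101
  expect_equal(303 * (1 - 0.5) / (1 + 0.5), 101)
  # negative autocorrelation never inflates the sample size
  alt <- rep(c(1, -1), 50) + rnorm(100, 0, 0.1)
  out_neg <- ar1_effective_n(alt)
  expect_lt(out_neg$rho, 0)
  expect_equal(out_neg$n_eff, 100)
  expect_error(ar1_effective_n(rnorm(9)), "insufficient")
})

test_that("white-noise residuals leave inference essentially classical", {
  set.seed(41)
  n <- 300
  hits <- replicate(500, {
    out <- ar1_effective_n(rnorm(n))
    abs(out$rho) < 2 / sqrt(n)
  })
  expect_gte(mean(hits), 0.9)
})

test_that("trend_fit matches the closed-form OLS oracle and handles degeneracy", {
  set.seed(42)
  time <- month_seq("2000-01", 120)
  td <- decimal_years(time)
  for (i in 1:20) {
    y <- rnorm(120, 0, 5) + runif(1, -3, 3) * td
    y[sample(120, 15)] <- NA
    f <- trend_fit(y, td, min_months = 50)
    expect_equal(f$slope / 10, ols_slope_oracle(y, td), tolerance = 1e-10)
  }
  # exact line: slope 3 per decade, zero residuals, flagged significant
  y_line <- 0.3 * td
  f_line <- trend_fit(y_line, td)
  expect_equal(f_line$slope, 3, tolerance = 1e-10)
  expect_equal(f_line$rho, 0)
  expect_true(f_line$significant)
  # constant series: zero slope, not significant
  f_const <- trend_fit(rep(5, 120), td)
  expect_equal(f_const$slope, 0)
  expect_false(f_const$significant)
  # too few months: reported missing
  f_short <- trend_fit(c(rnorm(30), rep(NA, 90)), td)
  expect_true(is.na(f_short$slope))
})

test_that("the vectorized trend map agrees with the per-cell fit", {
  set.seed(43)
  g <- toy_grid(5, 8)
  n <- 200
  vals <- matrix(rnorm(40 * n, 0, 3), 40, n) +
    outer(runif(40, -5, 5), (seq_len(n) - n / 2) / 120)
  vals[sample(length(vals), 800)] <- NA
  fs <- mat_to_fs(vals, g, "2000-01")
  tr <- trend_map(fs, min_months = 60)
  td <- decimal_years(fs$time)
  for (cell in sample(40, 12)) {
    la <- (cell - 1) %% 5 + 1; lo <- (cell - 1) %/% 5 + 1
    f <- trend_fit(fs$values[la, lo, ], td, min_months = 60)
    expect_equal(tr$slope[la, lo], f$slope, tolerance = 1e-9)
    expect_equal(tr$rho[la, lo], f$rho, tolerance = 1e-9)
    expect_equal(tr$n_eff[la, lo], f$n_eff, tolerance = 1e-9)
    expect_equal(tr$ci90_halfwidth[la, lo], f$ci90_halfwidth, tolerance = 1e-9)
  }
})

test_that("normalized trends divide by the reference mean and flag zero means", {
  g <- toy_grid(1, 3)
  n <- 72
  vals <- rbind(rep(100, n), rep(0, n), rep(50, n))
  fs <- mat_to_fs(vals, g, "2000-01")
  td <- decimal_years(fs$time)
  tr <- trend_map(deseasonalize(fs, monthly_climatology(fs, min_count = 1)),
                  min_months = 60)
  tr$slope[] <- 10 # impose a known slope to isolate the normalization
  tr2 <- normalized_trend(tr, fs, format(range(fs$time), "%Y-%m"))
  expect_equal(tr2$normalized_slope[1, 1], 10) # 10 / 100 * 100
  expect_true(is.na(tr2$normalized_slope[1, 2]))
  expect_equal(tr2$n_zero_mean, 1L)
  expect_equal(tr2$normalized_slope[1, 3], 20)
})

test_that("area fractions weight by area, not cell count", {
  g <- toy_grid(1, 2)
  tr <- structure(list(
    slope = matrix(c(-5, -1), 1, 2),
    significant = matrix(c(TRUE, FALSE), 1, 2),
    normalized_slope = matrix(c(-10, -2), 1, 2)),
    class = "trend_result")
  areas <- matrix(c(1, 3), 1, 2)
  fr <- significant_area_fractions(tr, areas)
  expect_equal(fr$frac_sig_neg, 0.25)
  expect_equal(fr$frac_sig_pos, 0)
  expect_equal(fr$mean_rate_neg, -5)
  expect_equal(fr$mean_norm_neg, -10)
  # all significant negative
  tr$significant[] <- TRUE
  expect_equal(significant_area_fractions(tr, areas)$frac_sig_neg, 1)
  tr$slope[] <- NA
  expect_error(significant_area_fractions(tr, areas), "zero tested")
})

test_that("SST-binned summaries reproduce steps and conserve area", {
  g <- toy_grid(10, 12, c(-80, 80))
  areas <- cell_areas(g)
  cc <- grid_centers(g)
  sst <- matrix(30 - 0.35 * abs(cc$lat), 10, 12)
  slope <- ifelse(sst > 15, -30, 20)
  tr <- structure(list(
    slope = slope,
    significant = matrix(TRUE, 10, 12)),
    class = "trend_result")
  tab <- sst_bin_summary(tr, sst, areas)
  expect_equal(sum(tab$area_m2), sum(areas))
  warm <- tab[tab$sst_lo >= 16 & tab$area_m2 > 0, ]
  cold <- tab[tab$sst_hi <= 15 & tab$area_m2 > 0, ]
  expect_true(all(warm$p50 == -30))
  expect_true(all(cold$p50 == 20))
  expect_true(all(warm$frac_sig_neg == 1))
  expect_true(all(cold$frac_sig_pos == 1))
  # uniform trend: all percentiles collapse to it
  tr$slope[] <- 7
  tab_u <- sst_bin_summary(tr, sst, areas)
  nz <- tab_u[tab_u$area_m2 > 0, ]
  expect_true(all(nz$p10 == 7 & nz$p90 == 7))
})

test_that("mask overlap percentages follow the area ratio", {
  areas <- matrix(1, 1, 4)
  a <- matrix(c(TRUE, TRUE, TRUE, FALSE), 1, 4)
  b <- matrix(c(FALSE, TRUE, TRUE, TRUE), 1, 4)
  expect_equal(overlap_fraction(a, b, areas), 200 / 3, tolerance = 1e-12)
  expect_equal(overlap_fraction(a, a, areas), 100)
  expect_equal(overlap_fraction(a, !a, areas), 0)
  expect_error(overlap_fraction(a & FALSE, b, areas), "zero area")
})

test_that("doubling latitude resolution leaves area fractions unchanged", {
  # the same step pattern on a coarse grid and a lat-split refinement
  make_tr <- function(nlat) {
    g <- toy_grid(nlat, 8, c(-60, 60))
    cc <- grid_centers(g)
    sig <- matrix(cc$lat > 0, nlat, 8)
    list(tr = structure(list(slope = matrix(ifelse(sig, -10, 5), nlat, 8),
                             significant = sig), class = "trend_result"),
         areas = cell_areas(g))
  }
  c1 <- make_tr(6)
  c2 <- make_tr(12)
  f1 <- significant_area_fractions(c1$tr, c1$areas)
  f2 <- significant_area_fractions(c2$tr, c2$areas)
  expect_equal(f1$frac_sig_neg, f2$frac_sig_neg, tolerance = 1e-12)
})
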