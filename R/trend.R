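# Per-pixel trend estimation with AR(1)-corrected significance.
#
# Ordinary least-squares on deseasonalized anomalies versus decimal years at
# month centers. Serial correlation in the residuals is summarized by the
# lag-1 autocorrelation rho, which reduces the effective sample size to
# n_eff = n (1 - rho) / (1 + rho) (capped at n for rho < 0). The slope
# standard error is rescaled by sqrt(n / n_eff) and significance assessed by
# a two-tailed t test with df = n_eff - 2 at alpha = 0.10 (90% confidence).

#' Lag-1 autocorrelation and effective sample size of residuals
#'
#' @param residuals numeric vector of regression residuals (NA allowed;
#'   lag-1 pairs use consecutive valid values)
#' @return list with `rho` (lag-1 Pearson autocorrelation) and `n_eff`
#'   (`n(1-rho)/(1+rho)`, capped at `n` so negative rho never inflates the
#'   sample size)
#' @export
ar1_effective_n <- function(residuals) {
  ok <- !is.na(residuals)
  n <- sum(ok)
  if (n < 10) stopf("insufficient data: %d valid residuals (need >= 10)", n)
  x <- residuals
  a <- x[-length(x)]; b <- x[-1]
  p <- !is.na(a) & !is.na(b)
  rho <- if (sum(p) < 3) 0 else suppressWarnings(cor(a[p], b[p]))
  if (!is.finite(rho)) rho <- 0
  n_eff <- if (rho > 0) n * (1 - rho) / (1 + rho) else n
  list(rho = rho, n_eff = min(n_eff, n), n = n)
}

#' OLS trend with AR(1)-adjusted uncertainty for one series
#'
#' @param y anomaly values (NA = missing)
#' @param t time in decimal years
#' @param alpha two-tailed significance level (default 0.10, i.e. 90%
#'   confidence)
#' @param min_months minimum valid months required
#' @return list with `slope` (units per decade), `intercept`, `rho`, `n`,
#'   `n_eff`, `se_adj` (per decade), `ci90_halfwidth`, `significant`
#' @export
trend_fit <- function(y, t, alpha = 0.10, min_months = 60) {
  ok <- !is.na(y)
  n <- sum(ok)
  if (n < min_months)
    return(list(slope = NA_real_, intercept = NA_real_, rho = NA_real_,
                n = n, n_eff = NA_real_, se_adj = NA_real_,
                ci90_halfwidth = NA_real_, significant = NA))
  x <- t[ok]; yy <- y[ok]
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (yy - mean(yy))) / sxx
  intercept <- mean(yy) - slope * mean(x)
  res <- rep(NA_real_, length(y))
  res[ok] <- yy - (intercept + slope * x)
  rss <- sum(res[ok]^2)
  # machine-level residuals (exact lines, constants) count as zero variance
  if (rss <= 1e-24 * sum(yy^2)) rss <- 0
  sigma2 <- rss / (n - 2)
  if (sigma2 <= 0 || !is.finite(sigma2)) sigma2 <- 0
  ar <- if (sigma2 == 0) list(rho = 0, n_eff = n) else ar1_effective_n(res)
  n_eff <- ar$n_eff
  df <- n_eff - 2
  if (df < 2)
    return(list(slope = NA_real_, intercept = intercept, rho = ar$rho,
                n = n, n_eff = n_eff, se_adj = NA_real_,
                ci90_halfwidth = NA_real_, significant = NA))
  se <- sqrt(sigma2 / sxx)
  se_adj <- se * sqrt(n / n_eff)
  ci <- qt(1 - alpha / 2, df) * se_adj
  list(slope = slope * 10, intercept = intercept, rho = ar$rho, n = n,
       n_eff = n_eff, se_adj = se_adj * 10, ci90_halfwidth = ci * 10,
       significant = abs(slope * 10) > ci * 10)
}

#' Per-pixel trend map over a gridded anomaly series
#'
#' Vectorized masked OLS over all cells, with the AR(1) effective-sample-size
#' correction of [trend_fit()] applied cellwise. Cells with fewer than
#' `min_months` valid anomalies, or with `n_eff - 2 < 2`, are reported
#' missing and counted.
#'
#' @param anoms anomaly [field_series()] (from [deseasonalize()])
#' @param alpha two-tailed significance level (default 0.10)
#' @param min_months minimum valid months per cell (default 60)
#' @param correct_ar1 apply the effective-sample-size correction (disable
#'   only to quantify its necessity)
#' @return object of class `trend_result`: matrices `slope` (units/decade),
#'   `intercept`, `rho`, `n`, `n_eff`, `se_adj`, `ci90_halfwidth`, logical
#'   `significant`, plus counts of untestable cells
#' @export
trend_map <- function(anoms, alpha = 0.10, min_months = 60, correct_ar1 = TRUE) {
  stopifnot(inherits(anoms, "field_series"))
  d <- dim(anoms$values)
  n_cell <- d[1] * d[2]
  Y <- matrix(anoms$values, n_cell, d[3]) # [cell, time]
  t <- decimal_years(anoms$time)
  M <- !is.na(Y)
  Y0 <- Y; Y0[!M] <- 0
  n <- rowSums(M)
  Sx <- M %*% t
  Sxx <- M %*% t^2
  Sy <- rowSums(Y0)
  Sxy <- Y0 %*% t
  den <- Sxx - Sx^2 / n
  slope <- as.vector((Sxy - Sx * Sy / n) / den)
  intercept <- as.vector(Sy / n - slope * Sx / n)
  fit <- outer(intercept, rep(1, d[3])) + outer(slope, t)
  R <- (Y0 - fit) * M
  rss <- rowSums(R^2)
  rss[rss <= 1e-24 * rowSums(Y0^2)] <- 0 # machine-level residuals
  sigma2 <- rss / (n - 2)
  sigma2[!is.finite(sigma2) | sigma2 < 0] <- 0
  # lag-1 autocorrelation of residuals over consecutive valid pairs
  A <- R[, -d[3], drop = FALSE]; B <- R[, -1, drop = FALSE]
  P <- M[, -d[3], drop = FALSE] & M[, -1, drop = FALSE]
  np <- rowSums(P)
  SA <- rowSums(A * P); SB <- rowSums(B * P)
  SAA <- rowSums(A^2 * P); SBB <- rowSums(B^2 * P)
  SAB <- rowSums(A * B * P)
  vr <- (SAA - SA^2 / np) * (SBB - SB^2 / np)
  rho <- (SAB - SA * SB / np) / sqrt(pmax(vr, 0))
  rho[!is.finite(rho) | sigma2 == 0] <- 0
  rho <- pmin(rho, 1 - 1e-10)
  n_eff <- ifelse(rho > 0 & correct_ar1, n * (1 - rho) / (1 + rho), n)
  n_eff <- pmin(n_eff, n)
  df <- n_eff - 2
  se <- sqrt(sigma2 / as.vector(den))
  se_adj <- se * sqrt(n / n_eff)
  ci <- rep(NA_real_, n_cell)
  ok_df <- is.finite(df) & df >= 2
  ci[ok_df] <- qt(1 - alpha / 2, df[ok_df]) * se_adj[ok_df]
  low_n <- n < min_months
  low_df <- !low_n & df < 2
  bad <- low_n | low_df | !is.finite(slope)
  slope[bad] <- NA_real_
  se_adj[bad] <- NA_real_
  ci[bad] <- NA_real_
  sig <- abs(slope * 10) > ci * 10
  sig[bad] <- NA
  shape <- function(v) matrix(v, d[1], d[2])
  structure(list(
    slope = shape(slope * 10), intercept = shape(intercept),
    rho = shape(rho), n = shape(n), n_eff = shape(n_eff),
    se_adj = shape(se_adj * 10), ci90_halfwidth = shape(ci * 10),
    significant = shape(sig),
    n_untestable = sum(low_df), n_low_coverage = sum(low_n),
    alpha = alpha, min_months = min_months, units = anoms$units,
    grid = anoms$grid, correct_ar1 = correct_ar1),
    class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  tested <- sum(!is.na(x$slope))
  cat(sprintf("trend_result [%s/decade]: %d tested cells, %d significant (alpha = %.2f), %d untestable\n",
              x$units, tested, sum(x$significant, na.rm = TRUE), x$alpha,
              x$n_untestable))
  invisible(x)
}

#' Normalize decadal trends by a reference-period mean
#'
#' Attaches `mean_ref` (per-cell mean of the raw series over the reference
#' window) and `normalized_slope` (100 * slope / mean_ref, percent per
#' decade) to a trend result; cells with |mean_ref| below `eps` are left
#' missing and counted.
#'
#' @param tr a [trend_map()] result
#' @param raw_fs the raw (not deseasonalized) [field_series()]
#' @param window `c(from, to)` `"YYYY-MM"` reference window (e.g. the first
#'   and last complete calendar years of the record)
#' @param eps threshold on |mean_ref| below which normalization is undefined
#' @return `tr` with `mean_ref`, `normalized_slope` and `n_zero_mean` added
#' @export
normalized_trend <- function(tr, raw_fs, window, eps = 1e-10) {
  stopifnot(inherits(tr, "trend_result"))
  mean_ref <- fs_time_mean(raw_fs, window[1], window[2])
  norm <- 100 * tr$slope / mean_ref
  zero <- !is.na(mean_ref) & abs(mean_ref) < eps
  norm[zero] <- NA_real_
  tr$mean_ref <- mean_ref
  tr$normalized_slope <- norm
  tr$n_zero_mean <- sum(zero)
  tr$mean_ref_window <- window
  tr
}

#' Area-weighted accounting of significant trends
#'
#' Fractions of the tested ocean area with significant negative / positive
#' trends, and area-weighted mean rates (absolute and normalized) over each
#' significant class.
#'
#' @param tr a [trend_map()] result (run [normalized_trend()] first if
#'   normalized means are wanted)
#' @param areas cell-area matrix
#' @param mask logical ocean mask
#' @return list: `frac_sig_neg`, `frac_sig_pos`, `mean_rate_neg`,
#'   `mean_rate_pos`, `mean_norm_neg`, `mean_norm_pos`, `area_tested`
#' @export
significant_area_fractions <- function(tr, areas, mask = NULL) {
  stopifnot(inherits(tr, "trend_result"))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(areas), ncol(areas))
  tested <- mask & !is.na(tr$slope)
  if (!any(tested)) stopf("zero tested area")
  a_tot <- sum(areas[tested])
  neg <- tested & !is.na(tr$significant) & tr$significant & tr$slope < 0
  pos <- tested & !is.na(tr$significant) & tr$significant & tr$slope > 0
  wmean <- function(v, sel) if (any(sel)) sum(v[sel] * areas[sel]) / sum(areas[sel]) else NA_real_
  norm <- if (!is.null(tr$normalized_slope)) tr$normalized_slope else
    matrix(NA_real_, nrow(areas), ncol(areas))
  list(frac_sig_neg = sum(areas[neg]) / a_tot,
       frac_sig_pos = sum(areas[pos]) / a_tot,
       mean_rate_neg = wmean(tr$slope, neg),
       mean_rate_pos = wmean(tr$slope, pos),
       mean_norm_neg = wmean(norm, neg & !is.na(norm)),
       mean_norm_pos = wmean(norm, pos & !is.na(norm)),
       area_tested = a_tot)
}

#' Trend distribution within 1-degree mean-SST bins
#'
#' Assigns each tested cell to a 1 C bin of the reference-period mean SST and
#' reports area-weighted trend percentiles (10/25/50/75/90) plus the areal
#' fraction of significant positive and negative trends per bin.
#'
#' @param tr a [trend_map()] result
#' @param sst_mean `[n_lat, n_lon]` mean SST field (deg C) over the reference
#'   window
#' @param areas cell-area matrix
#' @param mask logical ocean mask
#' @param bin_width bin width in deg C (default 1)
#' @return data.frame of class `sst_bin_table`: bin bounds/center, total bin
#'   area, trend percentiles, significant-area fractions
#' @export
sst_bin_summary <- function(tr, sst_mean, areas, mask = NULL, bin_width = 1) {
  stopifnot(inherits(tr, "trend_result"))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(areas), ncol(areas))
  tested <- mask & !is.na(tr$slope) & !is.na(sst_mean)
  if (!any(tested)) stopf("zero tested area")
  lo <- floor(min(sst_mean[tested]) / bin_width) * bin_width
  hi <- ceiling(max(sst_mean[tested]) / bin_width) * bin_width
  edges <- seq(lo, hi, by = bin_width)
  bin <- findInterval(sst_mean, edges, rightmost.closed = TRUE)
  probs <- c(0.10, 0.25, 0.50, 0.75, 0.90)
  rows <- lapply(seq_len(length(edges) - 1), function(i) {
    sel <- tested & bin == i
    area <- sum(areas[sel])
    qs <- if (area > 0) weighted_quantile(tr$slope[sel], areas[sel], probs)
          else rep(NA_real_, 5)
    neg <- sel & !is.na(tr$significant) & tr$significant & tr$slope < 0
    pos <- sel & !is.na(tr$significant) & tr$significant & tr$slope > 0
    data.frame(sst_lo = edges[i], sst_hi = edges[i + 1],
               sst_center = (edges[i] + edges[i + 1]) / 2,
               area_m2 = area,
               p10 = qs[1], p25 = qs[2], p50 = qs[3], p75 = qs[4], p90 = qs[5],
               frac_sig_neg = if (area > 0) sum(areas[neg]) / area else NA_real_,
               frac_sig_pos = if (area > 0) sum(areas[pos]) / area else NA_real_)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sst_bin_table", "data.frame")
  out
}

#' Areal overlap of two significance masks
#'
#' Percent of the area of mask `a` that is also in mask `b`:
#' `100 * area(a & b) / area(a)`.
#'
#' @param mask_a,mask_b logical matrices on one grid (NA treated as `FALSE`)
#' @param areas cell-area matrix
#' @return percent overlap (scalar)
#' @export
overlap_fraction <- function(mask_a, mask_b, areas) {
  stopifnot(identical(dim(mask_a), dim(mask_b)))
  a <- !is.na(mask_a) & mask_a
  b <- !is.na(mask_b) & mask_b
  area_a <- sum(areas[a])
  if (area_a == 0) stopf("mask A covers zero area; overlap undefined")
  100 * sum(areas[a & b]) / area_a
}
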