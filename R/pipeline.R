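# Configuration-driven orchestration: synthetic generation (or input
# loading), mission blending, deseasonalization, per-pixel trends, EOF
# analysis, global accounting, and a machine+human readable run report.

#' Default pipeline configuration
#'
#' A complete synthetic-mode configuration: desk-scale 2 degree grid, 300
#' months from 1997-09, two missions with a planted per-calendar-month bias,
#' two planted NPP anomaly modes with index series, AR(1) noise, trend
#' testing at alpha = 0.10 with a 60-month minimum, EOF with 4 modes on a
#' 250 km equal-area grid.
#'
#' @param out_dir output directory for all stage products
#' @param seed integer seed controlling every random draw
#' @return nested configuration list (YAML-serializable)
#' @export
default_pipeline_config <- function(out_dir = tempfile("npprun"), seed = 1) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    synthetic = list(
      enabled = TRUE, res_deg = 2, start = "1997-09", n_months = 300,
      cloud_fraction = 0.05, modes = "default"),
    inputs = list(),
    blend = list(a_end = "2007-12", b_start = "2002-07",
                 min_obs = 3, log_space = TRUE),
    climatology = list(min_count = 5),
    trend = list(alpha = 0.10, min_months = 60, mean_ref_window = NULL,
                 variables = c("npp", "par", "aph_frac", "phi_mu",
                               "aph", "adg", "cphyto", "mu")),
    eof = list(k = 4, coverage = 0.8, target_km = 250),
    totals = list(par_threshold = 1)
  )
}

#' Validate a pipeline configuration
#'
#' Static checks performed before any computation: significance level in
#' (0, 1), at least one EOF mode, coverage in (0, 1\], positive equal-area
#' cell size, a workable record length, readable inputs when synthetic mode
#' is off.
#'
#' @param config a configuration list (see [default_pipeline_config()])
#' @return character vector of error messages (empty when valid); warnings,
#'   if any, as the `"warnings"` attribute
#' @export
validate_config <- function(config) {
  errs <- character()
  warns <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) errs[[length(errs) + 1]] <<- msg
  chk(is.numeric(config$seed) && length(config$seed) == 1, "seed must be a single integer")
  a <- config$trend$alpha
  chk(is.numeric(a) && a > 0 && a < 1, sprintf("trend$alpha must be in (0, 1), got %s", format(a)))
  chk(config$trend$min_months >= 10, "trend$min_months must be >= 10")
  chk(config$eof$k >= 1, "eof$k must be >= 1")
  chk(config$eof$coverage > 0 && config$eof$coverage <= 1, "eof$coverage must be in (0, 1]")
  chk(config$eof$target_km > 0, "eof$target_km must be positive")
  syn <- isTRUE(config$synthetic$enabled)
  if (syn) {
    chk(config$synthetic$n_months >= 24, "synthetic$n_months must be >= 24")
    chk(config$synthetic$res_deg > 0, "synthetic$res_deg must be positive")
    # blend window must sit inside the record
    months <- month_seq(config$synthetic$start, config$synthetic$n_months)
    rng <- format(range(months), "%Y-%m")
    if (!is.null(config$blend)) {
      if (config$blend$a_end > rng[2] || config$blend$b_start < rng[1])
        errs[[length(errs) + 1]] <- "blend overlap window lies outside the synthetic record"
    }
    if (!is.null(config$trend$mean_ref_window)) {
      w <- config$trend$mean_ref_window
      if (w[1] < rng[1] || w[2] > rng[2])
        errs[[length(errs) + 1]] <- "trend$mean_ref_window lies outside the data range"
    }
  } else {
    if (!length(config$inputs)) {
      errs[[length(errs) + 1]] <- "synthetic mode off but no input paths given"
    } else {
      missing_in <- !vapply(config$inputs, file.exists, logical(1))
      if (any(missing_in))
        errs[[length(errs) + 1]] <- paste("missing input file(s):",
          paste(unlist(config$inputs[missing_in]), collapse = ", "))
    }
  }
  if (is.null(config$out_dir) || !nzchar(config$out_dir))
    errs[[length(errs) + 1]] <- "out_dir must be set"
  structure(unlist(errs) %||% character(), warnings = warns)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

default_modes <- function() {
  list(
    list(pattern = function(lat, lon) exp(-(lat / 15)^2) *
           exp(-((lon + 140) / 50)^2),
         loading = 40, rho_index = 0.9, name = "tropical_pacific_like"),
    list(pattern = function(lat, lon) exp(-((abs(lat) - 45) / 10)^2) *
           sign(lat),
         loading = 20, rho_index = 0.7, name = "subpolar_dipole_like"))
}

# Decoy + planted index series written alongside synthetic data so the
# attribution stage exercises real index ranking.
synth_indices_csv <- function(truth, path, n_decoys = 2) {
  time <- truth$time
  df <- data.frame(date = time)
  for (i in seq_along(truth$modes))
    df[[paste0("planted_mode", i)]] <- truth$modes[[i]]$index
  for (j in seq_len(n_decoys)) {
    x <- numeric(length(time))
    x[1] <- rnorm(1)
    for (t in 2:length(time)) x[t] <- 0.8 * x[t - 1] + rnorm(1, 0, sqrt(1 - 0.8^2))
    df[[paste0("decoy", j)]] <- x
  }
  write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages: synthetic generation (or input loading), mission blending,
#' climatology and anomalies, per-pixel AR(1)-corrected trends with
#' normalized rates and area accounting, SST-binned trend summaries, EOF
#' decomposition with climate-index attribution, and global NPP accounting
#' (annual totals, trend, below-mixed-layer fraction). All stage outputs are
#' written under `config$out_dir`; a frozen copy of the resolved
#' configuration and a machine- and human-readable report are always
#' emitted. With a fixed seed the numerical outputs are reproducible
#' byte for byte.
#'
#' @param config configuration list, see [default_pipeline_config()]
#' @return the run report (list), invisibly; also written as `report.json`
#'   and `report.txt`
#' @export
run_pipeline <- function(config) {
  errs <- validate_config(config)
  if (length(errs))
    stopf("invalid configuration:\n  - %s", paste(errs, collapse = "\n  - "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(config, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  set.seed(config$seed)
  report <- list(seed = config$seed, stages = list(), counts = list(),
                 headline = list())
  timings <- list()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  # --- stage: data (synthetic or loaded) -----------------------------------
  if (isTRUE(config$synthetic$enabled)) {
    sc <- config$synthetic
    modes <- if (identical(sc$modes, "default")) default_modes() else sc$modes
    scfg <- synth_config(res_deg = sc$res_deg, start = sc$start,
                         n_months = sc$n_months, seed = config$seed,
                         cloud_fraction = sc$cloud_fraction %||% 0.05,
                         modes = modes %||% list())
    tm <- generate_two_missions(scfg,
                                a_end = config$blend$a_end,
                                b_start = config$blend$b_start)
    fields <- tm$dataset$fields
    mask <- tm$mask
    grid <- tm$grid
    idx_path <- file.path(config$out_dir, "climate_indices.csv")
    synth_indices_csv(tm$truth, idx_path)
    report$counts$synthetic_missing_fraction <- tm$truth$missing_fraction
    mission_a <- tm$a; mission_b <- tm$b
  } else {
    fields <- lapply(config$inputs, read_fields)
    grid <- fields[[1]]$grid
    mask <- ocean_mask(grid, land = FALSE)
    idx_path <- config$indices_csv
    mission_a <- fields$npp_mission_a
    mission_b <- fields$npp_mission_b
  }
  areas <- cell_areas(grid)
  timings$data <- tic() - t0; t0 <- tic()

  # --- stage: blend --------------------------------------------------------
  if (!is.null(mission_a) && !is.null(mission_b)) {
    stats <- collocated_stats(mission_a, mission_b,
                              log_space = isTRUE(config$blend$log_space))
    adj <- fit_adjustment(mission_a, mission_b,
                          min_obs = config$blend$min_obs)
    merged <- suppressWarnings(apply_and_merge(mission_a, mission_b, adj))
    write_adjustment(adj, file.path(config$out_dir, "blend_adjustment.nc"))
    jsonlite::write_json(
      list(r = stats$r, slope = stats$slope, mae_factor = stats$mae_factor,
           n = stats$n, n_excluded = stats$n_excluded),
      file.path(config$out_dir, "blend_stats.json"),
      auto_unbox = TRUE, digits = NA)
    report$headline$blend <- list(r = stats$r, slope = stats$slope,
                                  mae_factor = stats$mae_factor)
    report$counts$blend_unadjusted_cell_months <- attr(merged, "unadjusted")
    fields$npp <- merged
    fields$mu <- growth_rate(merged, fields$cphyto)
    fields$phi_mu <- field_series(
      merged$values / (fields$par$values * fields$aph_frac$values),
      grid, merged$time, fields$phi_mu$units, "phi_mu")
  }
  timings$blend <- tic() - t0; t0 <- tic()

  # --- stage: trends -------------------------------------------------------
  mr <- config$trend$mean_ref_window %||% complete_year_window(fields$npp$time)
  sst_mean <- fs_time_mean(fields$sst, mr[1], mr[2])
  trend_rows <- list()
  trends <- list()
  for (v in config$trend$variables) {
    fs <- fields[[v]]
    if (is.null(fs)) next
    clim <- monthly_climatology(fs, min_count = config$climatology$min_count)
    anoms <- deseasonalize(fs, clim)
    tr <- trend_map(anoms, alpha = config$trend$alpha,
                    min_months = config$trend$min_months)
    tr <- normalized_trend(tr, fs, mr)
    trends[[v]] <- tr
    fr <- significant_area_fractions(tr, areas, mask)
    trend_rows[[v]] <- data.frame(
      variable = v, frac_sig_neg = fr$frac_sig_neg,
      frac_sig_pos = fr$frac_sig_pos, mean_rate_neg = fr$mean_rate_neg,
      mean_rate_pos = fr$mean_rate_pos, mean_norm_neg = fr$mean_norm_neg,
      mean_norm_pos = fr$mean_norm_pos)
    write_trend_map(tr, file.path(config$out_dir, paste0("trend_", v, ".nc")))
    if (v == "npp") {
      bins <- sst_bin_summary(tr, sst_mean, areas, mask)
      write.csv(bins, file.path(config$out_dir, "sst_bin_summary.csv"),
                row.names = FALSE)
      report$counts$trend_untestable_cells <- tr$n_untestable
    }
  }
  trend_table <- do.call(rbind, trend_rows)
  write.csv(trend_table, file.path(config$out_dir, "trend_summary.csv"),
            row.names = FALSE)
  report$headline$trend_fractions <- trend_table
  if (!is.null(trends$npp) && !is.null(trends$aph_frac)) {
    sig_neg <- function(tr) !is.na(tr$significant) & tr$significant & tr$slope < 0
    sig_pos <- function(tr) !is.na(tr$significant) & tr$significant & tr$slope > 0
    safe_overlap <- function(a, b) tryCatch(overlap_fraction(a, b, areas),
                                            error = function(e) NA_real_)
    report$headline$overlap_npp_aphfrac <- list(
      decreasing = safe_overlap(sig_neg(trends$npp), sig_neg(trends$aph_frac)),
      increasing = safe_overlap(sig_pos(trends$npp), sig_pos(trends$aph_frac)))
  }
  timings$trends <- tic() - t0; t0 <- tic()

  # --- stage: EOF ----------------------------------------------------------
  npp_clim <- monthly_climatology(fields$npp,
                                  min_count = config$climatology$min_count)
  npp_anoms <- deseasonalize(fields$npp, npp_clim)
  eas <- downsample_equal_area(npp_anoms, config$eof$target_km, mask)
  eof <- eof_decompose(eas, k = config$eof$k,
                       coverage = config$eof$coverage)
  pcs_df <- data.frame(date = npp_anoms$time, eof$pcs)
  names(pcs_df) <- c("date", paste0("pc", seq_len(eof$k)))
  write.csv(pcs_df, file.path(config$out_dir, "eof_pcs.csv"), row.names = FALSE)
  modes_df <- data.frame(lat = eas$lat[eof$cells], lon = eas$lon[eof$cells],
                         area_m2 = eof$weights, eof$modes)
  names(modes_df) <- c("lat", "lon", "area_m2", paste0("mode", seq_len(eof$k)))
  write.csv(modes_df, file.path(config$out_dir, "eof_modes.csv"), row.names = FALSE)
  corr <- NULL
  if (!is.null(idx_path) && file.exists(idx_path)) {
    indices <- read_climate_indices(idx_path)
    corr <- correlate_indices(eof, indices)
    write.csv(corr, file.path(config$out_dir, "eof_index_correlations.csv"),
              row.names = FALSE)
  }
  report$headline$eof <- list(
    variance_fraction = eof$variance_fraction,
    pc1_range_pg = pc_npp_range(eof, 1),
    top_correlations = if (!is.null(corr)) corr[corr$best, c("mode", "index", "r")])
  report$counts$eof_cells = length(eof$cells)
  timings$eof <- tic() - t0; t0 <- tic()

  # --- stage: totals -------------------------------------------------------
  par_clim <- monthly_climatology(fields$par,
                                  min_count = config$climatology$min_count)
  gs <- suppressWarnings(global_annual_npp(fields$npp, npp_clim, par_clim,
                                           areas, mask,
                                           config$totals$par_threshold))
  gt <- fit_global_trend(gs)
  write.csv(cbind(gs$annual,
                  filled_fraction = tapply(gs$monthly$filled_area_fraction,
                                           year_of(gs$monthly$date), mean)),
            file.path(config$out_dir, "global_annual_npp.csv"),
            row.names = FALSE)
  bf <- below_mld_fraction(fields$npp, fields$npp_below, areas, mask)
  write.csv(bf$annual, file.path(config$out_dir, "below_mld_fraction.csv"),
            row.names = FALSE)
  report$headline$global <- list(
    mean_pg = gt$mean_pg, sd_pg = gt$sd_pg,
    trend_pg_decade = gt$slope_pg_decade,
    net_pct_change = gt$net_pct_change,
    mean_filled_fraction = mean(gs$monthly$filled_area_fraction),
    below_mld_fraction_mean = mean(bf$annual$fraction[bf$annual$complete],
                                   na.rm = TRUE))
  timings$totals <- tic() - t0

  report$stages <- names(timings)
  out <- report
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       dataframe = "rows", digits = NA)
  out$timings <- timings # timings deliberately excluded from report.json
  writeLines(format_report(report, timings),
             file.path(config$out_dir, "report.txt"))
  invisible(out)
}

complete_year_window <- function(time) {
  yr <- year_of(time)
  tab <- table(yr)
  full <- as.integer(names(tab)[tab == 12])
  if (!length(full)) return(format(range(time), "%Y-%m"))
  c(sprintf("%d-01", min(full)), sprintf("%d-12", max(full)))
}

format_report <- function(report, timings) {
  h <- report$headline
  lines <- c(
    "== ocean NPP pipeline report ==",
    sprintf("seed: %d", report$seed), "")
  if (!is.null(h$blend))
    lines <- c(lines, sprintf(
      "blend: r = %.3f, slope = %.3f, MAE factor = %.3f",
      h$blend$r, h$blend$slope, h$blend$mae_factor))
  if (!is.null(h$trend_fractions)) {
    tt <- h$trend_fractions
    lines <- c(lines, "", "significant-trend area fractions (of tested ocean area):")
    lines <- c(lines, sprintf(
      "  %-9s neg %5.1f%% (%7.3g /decade, %6.1f %%/decade)  pos %5.1f%% (%7.3g /decade, %6.1f %%/decade)",
      tt$variable, 100 * tt$frac_sig_neg, tt$mean_rate_neg, tt$mean_norm_neg,
      100 * tt$frac_sig_pos, tt$mean_rate_pos, tt$mean_norm_pos))
  }
  if (!is.null(h$overlap_npp_aphfrac))
    lines <- c(lines, "", sprintf(
      "overlap of significant NPP and aph/a trends: decreasing %.0f%%, increasing %.0f%%",
      h$overlap_npp_aphfrac$decreasing, h$overlap_npp_aphfrac$increasing))
  if (!is.null(h$eof)) {
    lines <- c(lines, "", sprintf(
      "EOF variance fractions: %s; PC1 global range %.2f Pg C yr-1",
      paste(sprintf("%.1f%%", 100 * h$eof$variance_fraction), collapse = ", "),
      h$eof$pc1_range_pg))
    if (!is.null(h$eof$top_correlations)) {
      tc <- h$eof$top_correlations
      lines <- c(lines, sprintf("  mode %d best index: %s (r = %.2f)",
                                tc$mode, tc$index, tc$r))
    }
  }
  if (!is.null(h$global))
    lines <- c(lines, "", sprintf(
      "global NPP: mean %.1f +/- %.1f Pg C yr-1; trend %.2f Pg C decade-1 (net %.1f%%); below-MLD fraction %.3f",
      h$global$mean_pg, h$global$sd_pg, h$global$trend_pg_decade,
      h$global$net_pct_change, h$global$below_mld_fraction_mean))
  c(lines, "", "stage timings (s):",
    sprintf("  %-8s %.1f", names(timings), unlist(timings)))
}
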