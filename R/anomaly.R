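# Monthly climatologies and deseasonalized anomalies.

#' Per-cell monthly climatology
#'
#' Mean of each calendar month over a window, per cell, with a minimum
#' valid-observation count below which the climatology is left missing.
#'
#' @param fs a [field_series()]
#' @param window optional `c(from, to)` `"YYYY-MM"` bounds (default: full
#'   record)
#' @param min_count minimum valid observations per calendar month per cell
#' @return object of class `climatology`: `mean` array `[n_lat, n_lon, 12]`,
#'   `counts`, `window`, `units`, `grid`
#' @export
monthly_climatology <- function(fs, window = NULL, min_count = 5) {
  stopifnot(inherits(fs, "field_series"))
  w <- if (is.null(window)) fs else fs_window(fs, window[1], window[2])
  mo <- month_of(w$time)
  nla <- dim(w$values)[1]; nlo <- dim(w$values)[2]
  mean12 <- array(NA_real_, c(nla, nlo, 12))
  counts <- array(0L, c(nla, nlo, 12))
  for (m in 1:12) {
    sel <- which(mo == m)
    if (!length(sel)) next
    vm <- w$values[, , sel, drop = FALSE]
    cnt <- apply(!is.na(vm), c(1, 2), sum)
    mu <- apply(vm, c(1, 2), function(v) mean(v, na.rm = TRUE))
    mu[cnt < min_count] <- NA_real_
    mu[!is.finite(mu)] <- NA_real_
    mean12[, , m] <- mu
    counts[, , m] <- cnt
  }
  structure(list(mean = mean12, counts = counts,
                 window = range(format(w$time, "%Y-%m")),
                 units = fs$units, grid = fs$grid, min_count = min_count),
            class = "climatology")
}

#' Deseasonalize a series against a monthly climatology
#'
#' Anomaly = value minus the climatology of its calendar month; missing
#' wherever either is missing. Over the climatology window the per-calendar-
#' month anomaly means vanish by construction.
#'
#' @param fs a [field_series()]
#' @param clim a [monthly_climatology()] result
#' @return anomaly [field_series()] (same grid, time, units)
#' @export
deseasonalize <- function(fs, clim) {
  stopifnot(inherits(fs, "field_series"), inherits(clim, "climatology"))
  anoms <- fs$values - clim$mean[, , month_of(fs$time), drop = FALSE]
  field_series(anoms, fs$grid, fs$time, fs$units,
               paste0(fs$name, "_anom"))
}
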