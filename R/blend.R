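# Inter-mission blending: collocated comparison statistics, per-calendar-month
# climatology-difference adjustment of the earlier mission to the later one,
# and merging of the harmonized records.

#' Collocated comparison statistics between two missions
#'
#' Pairs are formed cell-by-cell over common months where both series are
#' valid. For positive, log-normal-like quantities such as NPP, the
#' correlation and Type-1 (ordinary least-squares) slope are computed on
#' log10-transformed pairs and the mean absolute error is the multiplicative
#' factor `10^mean(|log10(a/b)|)` (symmetric in a and b, >= 1).
#'
#' @param a,b [field_series()] on one grid
#' @param log_space compare in log10 space (default `TRUE`; use `FALSE` for
#'   signed variables, where `mae` is then `mean(|a - b|)` in linear units)
#' @return list of class `comparison_stats`: `r`, `slope`, `intercept`,
#'   `mae_factor` (or linear `mae`), `n` pairs, `n_excluded` non-positive
#'   pairs dropped under `log_space`
#' @export
collocated_stats <- function(a, b, log_space = TRUE) {
  stopifnot(inherits(a, "field_series"), inherits(b, "field_series"))
  common <- intersect(format(a$time, "%Y-%m"), format(b$time, "%Y-%m"))
  if (!length(common)) stopf("no overlapping months")
  ia <- match(common, format(a$time, "%Y-%m"))
  ib <- match(common, format(b$time, "%Y-%m"))
  x <- as.vector(a$values[, , ia])
  y <- as.vector(b$values[, , ib])
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n_excluded <- 0L
  if (log_space) {
    pos <- x > 0 & y > 0
    n_excluded <- sum(!pos)
    x <- log10(x[pos]); y <- log10(y[pos])
  }
  if (length(x) < 3) stopf("insufficient data: %d valid pairs (need >= 3)", length(x))
  slope <- if (sd(x) == 0) NA_real_ else cov(x, y) / var(x)
  r <- suppressWarnings(cor(x, y))
  out <- list(
    r = r, slope = slope,
    intercept = mean(y) - slope * mean(x),
    n = length(x), n_excluded = n_excluded, log_space = log_space)
  out$mae_factor <- if (log_space) 10^mean(abs(x - y)) else NA_real_
  out$mae <- if (log_space) out$mae_factor else mean(abs(x - y))
  class(out) <- "comparison_stats"
  out
}

#' @export
print.comparison_stats <- function(x, ...) {
  cat(sprintf("collocated comparison (%s space): r = %.3f, slope = %.3f, %s = %.3f, n = %d\n",
              if (x$log_space) "log10" else "linear", x$r, x$slope,
              if (x$log_space) "MAE factor" else "MAE", x$mae, x$n))
  invisible(x)
}

#' Fit a per-calendar-month climatology-difference adjustment
#'
#' For each cell and calendar month, the adjustment is the mean of `b - a`
#' over overlap months where both missions are valid, requiring at least
#' `min_obs` such months (missing elsewhere). Adding the adjustment to
#' mission `a` harmonizes it to mission `b`'s radiometric baseline.
#'
#' @param a earlier mission (the one adjusted), a [field_series()]
#' @param b later (reference) mission
#' @param overlap optional `c(from, to)` `"YYYY-MM"` bounds restricting the
#'   overlap window (default: all common months)
#' @param min_obs minimum collocated observations per calendar month per cell
#' @return object of class `blend_adjustment`: `diff` array
#'   `[n_lat, n_lon, 12]`, `counts`, `units`, `grid`
#' @export
fit_adjustment <- function(a, b, overlap = NULL, min_obs = 3) {
  stopifnot(inherits(a, "field_series"), inherits(b, "field_series"))
  if (!identical(a$grid$lat_edges, b$grid$lat_edges) ||
      !identical(a$grid$lon_edges, b$grid$lon_edges))
    stopf("missions are on different grids")
  common <- intersect(format(a$time, "%Y-%m"), format(b$time, "%Y-%m"))
  if (!is.null(overlap))
    common <- common[common >= overlap[1] & common <= overlap[2]]
  if (!length(common)) stopf("no overlap between missions")
  ia <- match(common, format(a$time, "%Y-%m"))
  ib <- match(common, format(b$time, "%Y-%m"))
  mo <- month_of(a$time[ia])
  nla <- dim(a$values)[1]; nlo <- dim(a$values)[2]
  d <- b$values[, , ib, drop = FALSE] - a$values[, , ia, drop = FALSE]
  diff12 <- array(NA_real_, c(nla, nlo, 12))
  counts <- array(0L, c(nla, nlo, 12))
  for (m in sort(unique(mo))) {
    sel <- which(mo == m)
    dm <- d[, , sel, drop = FALSE]
    cnt <- apply(!is.na(dm), c(1, 2), sum)
    mu <- apply(dm, c(1, 2), function(v) mean(v, na.rm = TRUE))
    mu[cnt < min_obs] <- NA_real_
    mu[!is.finite(mu)] <- NA_real_
    diff12[, , m] <- mu
    counts[, , m] <- cnt
  }
  structure(list(diff = diff12, counts = counts, units = a$units,
                 grid = a$grid, min_obs = min_obs),
            class = "blend_adjustment")
}

#' Apply the adjustment to mission A and merge with mission B
#'
#' The adjusted series `a* = a + adj(calendar month)` replaces `a`; the merged
#' record is `a*` where only A observes, `b` where only B observes, and the
#' mean of the two where both do. Cell-months where A is valid but the
#' adjustment is undefined fall back to unadjusted A and are counted in the
#' `unadjusted` attribute (a warning reports the count).
#'
#' @param a,b mission [field_series()] on one grid
#' @param adj a [fit_adjustment()] result
#' @return merged [field_series()] spanning the union of the two time ranges
#' @export
apply_and_merge <- function(a, b, adj) {
  stopifnot(inherits(adj, "blend_adjustment"))
  if (!identical(a$grid$lat_edges, adj$grid$lat_edges) ||
      !identical(a$grid$lon_edges, adj$grid$lon_edges))
    stopf("adjustment grid does not match mission A")
  adj_t <- adj$diff[, , month_of(a$time), drop = FALSE]
  a_star <- a$values + adj_t
  # fall back to unadjusted A where A observes but no adjustment is defined
  fallback <- !is.na(a$values) & is.na(adj_t)
  n_fb <- sum(fallback)
  if (n_fb > 0) {
    a_star[fallback] <- a$values[fallback]
    warning(sprintf("%d cell-months lacked an adjustment; unadjusted mission-A values used",
                    n_fb), call. = FALSE)
  }
  all_months <- sort(unique(c(a$time, b$time)))
  nla <- dim(a$values)[1]; nlo <- dim(a$values)[2]
  out <- array(NA_real_, c(nla, nlo, length(all_months)))
  ia <- match(a$time, all_months)
  ib <- match(b$time, all_months)
  out[, , ia] <- a_star
  for (k in seq_along(ib)) {
    t <- ib[k]
    ba <- out[, , t]
    bb <- b$values[, , k]
    both <- !is.na(ba) & !is.na(bb)
    merged <- ifelse(is.na(ba), bb, ba)
    merged[both] <- (ba[both] + bb[both]) / 2
    out[, , t] <- merged
  }
  res <- field_series(out, a$grid, all_months, a$units, "merged")
  attr(res, "unadjusted") <- n_fb
  res
}
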