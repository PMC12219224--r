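# Empirical orthogonal function analysis of anomaly fields on the
# quasi-equal-area grid, with climate-index attribution.
#
# The anomaly matrix [time x cells] is column-centered, scaled by the square
# root of the cell areas, and decomposed by SVD. Variance fractions are
# squared singular values over their total; spatial modes are returned in
# anomaly units per unit PC (weights divided back out), so
# PC_i(t) * mode_i(cell) reconstructs that mode's anomaly contribution.

#' EOF decomposition of an equal-area anomaly matrix
#'
#' Cells with temporal coverage below `coverage` are dropped; remaining gaps
#' are set to the zero anomaly (the minimal-leverage fill). Each retained
#' column is re-centered, weighted by sqrt(area) and the matrix decomposed by
#' singular values. Modes are sign-oriented so that each PC correlates
#' non-negatively with time (signs are otherwise arbitrary).
#'
#' @param eas an `ea_field_series` from [downsample_equal_area()], or a plain
#'   `[time x cells]` matrix (then `weights` is required)
#' @param k number of modes to return (truncated to the rank with a warning)
#' @param weights cell areas; taken from `eas` when it is an
#'   `ea_field_series`
#' @param coverage minimum fraction of valid months per retained cell
#' @return object of class `eof_result`: `modes` `[cells, k]` in anomaly
#'   units per unit PC, `pcs` `[time, k]`, `variance_fraction` (length k),
#'   `singular_values` (full), `cells` (indices retained), `weights`, `time`
#' @export
eof_decompose <- function(eas, k = 4, weights = NULL, coverage = 0.8) {
  if (inherits(eas, "ea_field_series")) {
    X <- t(eas$values) # [time, cells]
    if (is.null(weights)) weights <- eas$areas
    time <- eas$time
    units <- eas$units
  } else {
    X <- as.matrix(eas)
    if (is.null(weights)) stopf("`weights` required for a plain matrix")
    time <- seq_len(nrow(X))
    units <- attr(eas, "units")
  }
  if (length(weights) != ncol(X))
    stopf("weights length (%d) != number of cells (%d)", length(weights), ncol(X))
  cov_frac <- colMeans(!is.na(X))
  keep <- which(cov_frac >= coverage)
  if (!length(keep)) stopf("no cells meet the %.0f%% coverage threshold", 100 * coverage)
  X <- X[, keep, drop = FALSE]
  w <- weights[keep]
  X[is.na(X)] <- 0
  X <- scale(X, center = TRUE, scale = FALSE)
  sw <- sqrt(w / mean(w))
  Xw <- sweep(X, 2, sw, "*")
  rank_max <- min(dim(Xw))
  if (k > rank_max) {
    warning(sprintf("k = %d exceeds the rank %d; truncated", k, rank_max),
            call. = FALSE)
    k <- rank_max
  }
  sv <- svd(Xw, nu = k, nv = k)
  d2 <- sv$d^2
  vf <- d2[seq_len(k)] / sum(d2)
  pcs <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  modes <- sweep(sv$v, 1, sw, "/")
  # sign convention: PC correlates non-negatively with time
  tnum <- as.numeric(time)
  for (i in seq_len(k)) {
    r <- suppressWarnings(cor(pcs[, i], tnum))
    if (is.finite(r) && r < 0) {
      pcs[, i] <- -pcs[, i]
      modes[, i] <- -modes[, i]
    }
  }
  structure(list(modes = modes, pcs = pcs, variance_fraction = vf,
                 singular_values = sv$d, cells = keep, weights = w,
                 time = time, units = units, k = k,
                 n_dropped = length(weights) - length(keep)),
            class = "eof_result")
}

#' @export
print.eof_result <- function(x, ...) {
  cat(sprintf("eof_result: %d modes over %d cells x %d months\n",
              x$k, length(x$cells), nrow(x$pcs)))
  cat("  variance fractions:",
      paste(sprintf("%.1f%%", 100 * x$variance_fraction), collapse = ", "), "\n")
  invisible(x)
}

#' Correlate principal components with climate indices
#'
#' Pearson correlation of each PC with each index over their common months;
#' pairs with fewer than `min_common` common months are skipped with a
#' warning. The table is ranked within each mode by |r|.
#'
#' @param eof an [eof_decompose()] result with a `Date` time axis
#' @param indices named list of data.frames with columns `date`, `value`
#'   (monthly), e.g. from [read_climate_indices()]
#' @param min_common minimum overlapping months per pair (default 24)
#' @return data.frame (`mode`, `index`, `r`, `n`, `best` flag marking each
#'   mode's most correlated index)
#' @export
correlate_indices <- function(eof, indices, min_common = 24) {
  stopifnot(inherits(eof, "eof_result"))
  pc_months <- format(as.Date(eof$time), "%Y-%m")
  rows <- list()
  for (nm in names(indices)) {
    idx <- indices[[nm]]
    im <- format(as.Date(idx$date), "%Y-%m")
    common <- intersect(pc_months, im)
    if (length(common) < min_common) {
      warning(sprintf("index '%s': only %d common months (< %d); skipped",
                      nm, length(common), min_common), call. = FALSE)
      next
    }
    ip <- match(common, pc_months)
    ii <- match(common, im)
    for (m in seq_len(eof$k)) {
      r <- suppressWarnings(cor(eof$pcs[ip, m], idx$value[ii],
                                use = "complete.obs"))
      rows[[length(rows) + 1]] <- data.frame(mode = m, index = nm, r = r,
                                             n = length(common))
    }
  }
  if (!length(rows)) stopf("no index had enough overlap")
  out <- do.call(rbind, rows)
  out <- out[order(out$mode, -abs(out$r)), ]
  out$best <- !duplicated(out$mode)
  rownames(out) <- NULL
  out
}

#' Read monthly climate indices from CSV
#'
#' Expects columns `date` (parseable as Date, monthly) and `value`; a wide
#' file with one `date` column and one column per index is also accepted.
#'
#' @param path CSV file path
#' @return named list of data.frames (`date`, `value`)
#' @export
read_climate_indices <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"date" %in% names(df)) stopf("climate index CSV needs a 'date' column")
  df$date <- as.Date(df$date)
  vars <- setdiff(names(df), "date")
  if (identical(vars, "value")) {
    nm <- sub("\\.csv$", "", basename(path))
    return(stats::setNames(list(df[c("date", "value")]), nm))
  }
  out <- lapply(vars, function(v) data.frame(date = df$date, value = df[[v]]))
  stats::setNames(out, vars)
}

#' Global-integral range of a mode, in Pg C per year
#'
#' Reconstructs the mode's global NPP-anomaly integral through time,
#' `sum(mode * area) * PC(t)`, converts mg C per day to Pg C per year
#' (factor 1e-18 * 365.25), and reports max minus min.
#'
#' @param eof an [eof_decompose()] result whose anomalies are NPP in
#'   mg C m-2 d-1
#' @param mode mode number
#' @param areas optional cell areas (default: the weights stored in `eof`)
#' @return range in Pg C yr-1 (scalar)
#' @export
pc_npp_range <- function(eof, mode = 1, areas = NULL) {
  stopifnot(inherits(eof, "eof_result"))
  if (!is.null(eof$units) && !grepl("mg C m-2 d-1", eof$units, fixed = TRUE))
    stopf("mode units are '%s'; Pg C range requires NPP in mg C m-2 d-1",
          eof$units)
  if (is.null(areas)) areas <- eof$weights
  integral <- sum(eof$modes[, mode] * areas) # mg C d-1 per unit PC
  series <- integral * eof$pcs[, mode] * 1e-18 * 365.25
  diff(range(series))
}
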