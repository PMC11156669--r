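# Annual fraction of stressed days (FSD) against a critical threshold, and
# nonparametric Mann-Kendall / Sen trend statistics for annual series.

#' Fraction of stressed days in one year
#'
#' FSD is the ratio of the number of days with SM strictly below the
#' critical threshold to the number of observed daily SM values in the
#' year; ties count as unstressed.
#'
#' @param sm Daily SM values for one calendar year (gaps allowed as `NA`).
#' @param theta Critical threshold (m^3/m^3).
#' @param min_obs_year Minimum valid days for a defined FSD (default 180).
#' @return FSD in [0, 1], or `NA` when undefined.
#' @export
fsd_year <- function(sm, theta, min_obs_year = 180L) {
  if (!is.finite(theta)) return(NA_real_)
  v <- sm[is.finite(sm)]
  if (length(v) < min_obs_year) return(NA_real_)
  sum(v < theta) / length(v)
}

#' Annual FSD series from a multi-year daily record
#'
#' @param dates Daily dates.
#' @param sm Daily SM values aligned with `dates`.
#' @inheritParams fsd_year
#' @return Named numeric vector of FSD per calendar year.
#' @export
fsd_annual <- function(dates, sm, theta, min_obs_year = 180L) {
  yr <- as.integer(format(as.Date(dates), "%Y"))
  vapply(split(sm, yr), fsd_year, numeric(1), theta = theta,
         min_obs_year = min_obs_year)
}

#' Per-pixel median FSD across SM products
#'
#' @param fsd_list List of equally-shaped numeric objects (vectors,
#'   matrices or arrays), one per SM product.
#' @return Element-wise median over defined products, same shape.
#' @export
fsd_median_across_products <- function(fsd_list) {
  stopifnot(length(fsd_list) >= 1L)
  d <- dim(fsd_list[[1L]])
  stack <- vapply(fsd_list, as.vector,
                  numeric(length(as.vector(fsd_list[[1L]]))))
  med <- apply(as.matrix(stack), 1L, function(v)
    if (any(is.finite(v))) stats::median(v, na.rm = TRUE) else NA_real_)
  if (!is.null(d)) dim(med) <- d
  med
}

#' Mann-Kendall trend test with Sen's slope
#'
#' Computes the Mann-Kendall S statistic with tie-corrected variance and
#' continuity-corrected normal approximation for the two-sided p value,
#' Sen's slope as the median of all pairwise slopes, and its 95%
#' confidence interval from the rank positions of the sorted pairwise
#' slopes at the MK variance.
#'
#' @param x Annual values (at least 8 finite values for a meaningful
#'   test).
#' @param t Time coordinate (default the observation index / year index).
#' @param conf Confidence level for the Sen interval (default 0.95).
#' @return A list of class `trend_result`: `slope` (per unit of `t`),
#'   `ci_low`, `ci_high`, `s_stat`, `var_s`, `p`, `n`.  A constant series
#'   yields slope 0 and p = 1.
#' @export
mann_kendall_sen <- function(x, t = seq_along(x), conf = 0.95) {
  ok <- is.finite(x) & is.finite(t)
  x <- x[ok]; t <- t[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 finite values")
  pairs <- utils::combn(n, 2L)
  dx <- x[pairs[2L, ]] - x[pairs[1L, ]]
  dt <- t[pairs[2L, ]] - t[pairs[1L, ]]
  S <- sum(sign(dx))
  ties <- table(x)
  tie_term <- sum(ties * (ties - 1) * (2 * ties + 5))
  var_s <- (n * (n - 1) * (2 * n + 5) - tie_term) / 18
  if (var_s <= 0) {
    res <- list(slope = 0, ci_low = 0, ci_high = 0, s_stat = S,
                var_s = var_s, p = 1, n = n)
    class(res) <- "trend_result"
    return(res)
  }
  z <- if (S > 0) (S - 1) / sqrt(var_s)
       else if (S < 0) (S + 1) / sqrt(var_s) else 0
  p <- 2 * stats::pnorm(-abs(z))
  slopes <- sort(dx[dt != 0] / dt[dt != 0])
  N <- length(slopes)
  slope <- stats::median(slopes)
  C <- stats::qnorm(1 - (1 - conf) / 2) * sqrt(var_s)
  lo_i <- max(1L, floor((N - C) / 2))
  hi_i <- min(N, ceiling((N + C) / 2) + 1L)
  res <- list(slope = slope, ci_low = slopes[lo_i], ci_high = slopes[hi_i],
              s_stat = S, var_s = var_s, p = p, n = n)
  class(res) <- "trend_result"
  res
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf(
    "<trend> Sen slope %.4g [%.4g, %.4g], MK S = %d, p = %.3g (n = %d)\n",
    x$slope, x$ci_low, x$ci_high, x$s_stat, x$p, x$n))
  invisible(x)
}

#' Regional FSD trends within climatological bins
#'
#' Assigns pixels to bins by their climatological mean FSD (half-open
#' intervals `[low, high)`; pixels below the lowest or at/above the
#' highest boundary are excluded to avoid extreme-fraction regions),
#' computes the per-bin spatial median (and quartiles) for each year, and
#' estimates the Mann-Kendall/Sen trend of each bin's median series.
#'
#' @param fsd Matrix `n_pixels x n_years` of annual FSD values.
#' @param years Numeric vector of years (columns of `fsd`).
#' @param bins Two-column matrix of bin boundaries; default the four bins
#'   10-30%, 30-50%, 50-70%, 70-90%.
#' @return A named list per bin with `n_pixels`, `series` (a `data.frame`
#'   `year`, `median`, `q25`, `q75`) and `trend` (a `trend_result`, or
#'   `NULL` for an empty bin).
#' @export
bin_and_trend <- function(fsd, years = seq_len(ncol(fsd)),
                          bins = cbind(c(0.1, 0.3, 0.5, 0.7),
                                       c(0.3, 0.5, 0.7, 0.9))) {
  stopifnot(is.matrix(fsd), ncol(fsd) == length(years))
  clim <- rowMeans(fsd, na.rm = TRUE)
  out <- list()
  for (b in seq_len(nrow(bins))) {
    lo <- bins[b, 1L]; hi <- bins[b, 2L]
    name <- sprintf("%d-%d%%", round(lo * 100), round(hi * 100))
    sel <- which(is.finite(clim) & clim >= lo & clim < hi)
    if (length(sel) == 0L) {
      out[[name]] <- list(n_pixels = 0L, series = NULL, trend = NULL)
      next
    }
    sub <- fsd[sel, , drop = FALSE]
    series <- data.frame(
      year = years,
      median = apply(sub, 2L, stats::median, na.rm = TRUE),
      q25 = apply(sub, 2L, stats::quantile, probs = 0.25, na.rm = TRUE),
      q75 = apply(sub, 2L, stats::quantile, probs = 0.75, na.rm = TRUE))
    tr <- if (sum(is.finite(series$median)) >= 8L)
      mann_kendall_sen(series$median, years) else NULL
    out[[name]] <- list(n_pixels = length(sel), series = series,
                        trend = tr)
  }
  class(out) <- "fsd_bin_trends"
  out
}

#' Mask pixels with substantial land-cover change
#'
#' @param x A `theta_map` or a numeric matrix.
#' @param change Fractional land-cover change per pixel, same grid.
#' @param threshold Pixels with change strictly above this are masked
#'   (default 0.10).
#' @return `x` with masked entries set to `NA`.
#' @export
mask_land_change <- function(x, change, threshold = 0.10) {
  if (inherits(x, "theta_map")) {
    stopifnot(all(dim(change) == dim(x$theta)))
    x$theta[change > threshold] <- NA_real_
    if (!is.null(x$se)) x$se[change > threshold] <- NA_real_
    return(x)
  }
  stopifnot(all(dim(change) == dim(x) | is.null(dim(x))))
  x[change > threshold] <- NA_real_
  x
}
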