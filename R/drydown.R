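# Dry-down identification in daily tower records and irregular satellite
# overpass series, and the peak-growing-season window for tower analysis.
#
# A dry-down is a maximal run of consecutive observations with strictly
# decreasing soil moisture ("decreasing" means SM(t) < SM(t-1) - tol with
# tol = 0 by default, so exact ties break a run).  The emitted segment
# includes the initial local maximum (the post-rain peak) through the last
# declining observation.

.decreasing_runs <- function(sm, tol = 0) {
  n <- length(sm)
  if (n < 2L) return(NULL)
  step <- (sm[-n] - sm[-1L]) > tol & is.finite(sm[-n]) & is.finite(sm[-1L])
  r <- rle(step)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (length(keep) == 0L) return(NULL)
  # step t covers observations t and t+1: run of steps i..j -> points i..j+1
  data.frame(start_idx = starts[keep], end_idx = ends[keep] + 1L)
}

.segment_frame <- function(series_id, dates, runs, n_obs) {
  data.frame(series_id = series_id,
             start_idx = runs$start_idx, end_idx = runs$end_idx,
             start_date = dates[runs$start_idx],
             end_date = dates[runs$end_idx],
             n_obs = n_obs,
             span_days = as.numeric(dates[runs$end_idx] -
                                    dates[runs$start_idx]))
}

#' Detect dry-downs in a daily series
#'
#' Finds maximal runs of consecutively decreasing daily soil moisture and
#' retains those with at least `min_days` days of decline that start from a
#' rain-gated peak: the run's first day (or the day before) had positive
#' precipitation, or - when no precipitation record exists - soil moisture
#' rose by at least `sm_rise` into the peak.
#'
#' @param series A `site_series` data frame (columns `date`, `sm`, and
#'   optionally `precip`), daily cadence.
#' @param min_days Minimum days of consecutive decline (default 10).
#' @param tol Decrease tolerance (m^3/m^3): a step counts as decreasing
#'   when SM drops by more than `tol` (default 0, strict decrease).
#' @param rain_gate Require the pre-run rain evidence (default TRUE).
#' @param rain_thresh Precipitation (mm/day) strictly above which a day
#'   counts as rainy (default 0).
#' @param sm_rise Minimum SM rise into the peak accepted as rain evidence
#'   when precipitation is unavailable (default 0.005 m^3/m^3).
#' @param series_id Identifier copied into the segment table.
#' @return A `data.frame` of segments: `series_id`, `start_idx`,
#'   `end_idx`, `start_date`, `end_date`, `n_obs`, `span_days`.  Empty
#'   (zero rows) when nothing qualifies.
#' @export
detect_drydowns_daily <- function(series, min_days = 10L, tol = 0,
                                  rain_gate = TRUE, rain_thresh = 0,
                                  sm_rise = 0.005, series_id = "site") {
  stopifnot(is.data.frame(series), all(c("date", "sm") %in% names(series)))
  sm <- series$sm
  dates <- as.Date(series$date)
  empty <- .segment_frame(character(0), dates,
                          data.frame(start_idx = integer(0),
                                     end_idx = integer(0)), integer(0))
  if (length(sm) < min_days + 1L) return(empty)
  runs <- .decreasing_runs(sm, tol)
  if (is.null(runs)) return(empty)
  span <- runs$end_idx - runs$start_idx  # days of decline at daily cadence
  runs <- runs[span >= min_days, , drop = FALSE]
  if (nrow(runs) == 0L) return(empty)
  if (rain_gate) {
    precip <- series$precip
    has_precip <- !is.null(precip) && any(is.finite(precip))
    ok <- vapply(runs$start_idx, function(s) {
      if (has_precip) {
        rain_now <- is.finite(precip[s]) && precip[s] > rain_thresh
        rain_prev <- s > 1L && is.finite(precip[s - 1L]) &&
          precip[s - 1L] > rain_thresh
        if (rain_now || rain_prev) return(TRUE)
      }
      s > 1L && is.finite(sm[s]) && is.finite(sm[s - 1L]) &&
        (sm[s] - sm[s - 1L]) >= sm_rise
    }, logical(1))
    runs <- runs[ok, , drop = FALSE]
  }
  if (nrow(runs) == 0L) return(empty)
  .segment_frame(series_id, dates, runs,
                 runs$end_idx - runs$start_idx + 1L)
}

#' Detect dry-downs in an irregular overpass series
#'
#' Finds maximal runs of consecutive overpasses with strictly decreasing
#' soil moisture and retains those with at least `min_obs` overpasses
#' spanning at least `min_span_days` days - the satellite rule (5
#' overpasses for 1-3-day revisit products, 4 for 2-4-day revisit, over
#' >= 10 days).
#'
#' @param dates Overpass dates (strictly increasing; duplicates are an
#'   input error).
#' @param sm Soil moisture at each overpass (m^3/m^3).
#' @param min_obs Minimum overpasses per segment (default 5).
#' @param min_span_days Minimum segment span in days (default 10).
#' @param tol Decrease tolerance as in [detect_drydowns_daily()].
#' @param series_id Identifier copied into the segment table.
#' @return Segment `data.frame` as in [detect_drydowns_daily()].
#' @export
detect_drydowns_overpass <- function(dates, sm, min_obs = 5L,
                                     min_span_days = 10L, tol = 0,
                                     series_id = "pixel") {
  dates <- as.Date(dates)
  stopifnot(length(dates) == length(sm))
  if (anyDuplicated(dates)) stop("duplicate overpass dates")
  if (is.unsorted(dates)) stop("overpass dates must be increasing")
  empty <- .segment_frame(character(0), dates,
                          data.frame(start_idx = integer(0),
                                     end_idx = integer(0)), integer(0))
  runs <- .decreasing_runs(sm, tol)
  if (is.null(runs)) return(empty)
  n_obs <- runs$end_idx - runs$start_idx + 1L
  span <- as.numeric(dates[runs$end_idx] - dates[runs$start_idx])
  keep <- n_obs >= min_obs & span >= min_span_days
  runs <- runs[keep, , drop = FALSE]
  if (nrow(runs) == 0L) return(empty)
  .segment_frame(series_id, dates, runs,
                 runs$end_idx - runs$start_idx + 1L)
}

#' Peak growing season from a multi-year GPP record
#'
#' Among the 12 candidate three-calendar-month windows (wrap-around
#' allowed), returns the one with the maximum mean gross primary
#' productivity across all available years.  Ties go to the earliest
#' window in calendar order.
#'
#' @param dates Daily dates.
#' @param gpp Daily GPP values (any consistent flux unit).
#' @return A list of class `season_window`: `months` (the three calendar
#'   months), `start_month`, `end_month`, `mean_gpp`.
#' @export
peak_growing_season <- function(dates, gpp) {
  dates <- as.Date(dates)
  stopifnot(length(dates) == length(gpp))
  ok <- is.finite(gpp)
  if (!any(ok)) stop("all GPP values are missing")
  mo <- as.integer(format(dates[ok], "%m"))
  g <- gpp[ok]
  best <- NULL
  for (start in 1:12) {
    months <- ((start - 1L):(start + 1L)) %% 12L + 1L
    m <- mean(g[mo %in% months])
    if (is.nan(m)) next
    # strict improvement keeps the earliest window on ties
    if (is.null(best) || m > best$mean_gpp)
      best <- list(months = months, start_month = start,
                   end_month = months[3L], mean_gpp = m)
  }
  if (is.null(best)) stop("no window with GPP data")
  class(best) <- "season_window"
  best
}

#' Restrict a daily series to a season window
#'
#' @param series A `site_series` data frame.
#' @param window A `season_window` from [peak_growing_season()].
#' @return The rows of `series` whose calendar month falls in the window.
#' @export
filter_to_season <- function(series, window) {
  stopifnot(inherits(window, "season_window"))
  mo <- as.integer(format(as.Date(series$date), "%m"))
  series[mo %in% window$months, , drop = FALSE]
}

#' Pool paired samples from dry-down segments
#'
#' Concatenates (SM, response) pairs over all segments, dropping pairs with
#' a missing response, and retains per-pair segment provenance.
#'
#' @param segments Segment `data.frame` from a detector.
#' @param sm Soil moisture vector the segment indices refer to.
#' @param y Response vector (EF or dLST) aligned with `sm`.
#' @return A `data.frame` with columns `sm`, `y`, `segment` (zero rows
#'   when nothing valid remains).
#' @export
pool_samples <- function(segments, sm, y) {
  stopifnot(is.data.frame(segments), length(sm) == length(y))
  if (nrow(segments) == 0L)
    return(data.frame(sm = numeric(0), y = numeric(0),
                      segment = integer(0)))
  idx <- mapply(function(s, e) s:e, segments$start_idx, segments$end_idx,
                SIMPLIFY = FALSE)
  seg <- rep(seq_len(nrow(segments)), lengths(idx))
  idx <- unlist(idx)
  out <- data.frame(sm = sm[idx], y = y[idx], segment = seg)
  out[is.finite(out$sm) & is.finite(out$y), , drop = FALSE]
}
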