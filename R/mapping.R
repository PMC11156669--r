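# Per-pixel threshold mapping: dry-down detection + breakpoint selection on
# gridded stacks, site-level estimation, ensemble assembly with relative
# uncertainty, and map comparison utilities.

.new_theta_map <- function(lat, lon, theta, se, sm_lo, sm_hi,
                           provenance = list()) {
  structure(list(lat = lat, lon = lon, theta = theta, se = se,
                 sm_lo = sm_lo, sm_hi = sm_hi, provenance = provenance),
            class = "theta_map")
}

#' @export
print.theta_map <- function(x, ...) {
  nd <- sum(is.finite(x$theta))
  cat(sprintf("<theta_map> %d x %d pixels, %d defined\n",
              length(x$lat), length(x$lon), nd))
  if (nd > 0)
    cat(sprintf("  theta: median %.3f, range [%.3f, %.3f] m3/m3\n",
                stats::median(x$theta[is.finite(x$theta)]),
                min(x$theta, na.rm = TRUE), max(x$theta, na.rm = TRUE)))
  invisible(x)
}

.pixel_theta <- function(dates, sm, y, daily, min_obs, min_span_days,
                         min_days, min_n, min_side) {
  ok <- is.finite(sm)
  if (sum(ok) < min_n) return(c(NA_real_, NA_real_))
  if (daily) {
    seg <- detect_drydowns_daily(
      data.frame(date = dates[ok], sm = sm[ok]), min_days = min_days,
      rain_gate = TRUE)
  } else {
    seg <- detect_drydowns_overpass(dates[ok], sm[ok], min_obs = min_obs,
                                    min_span_days = min_span_days)
  }
  p <- pool_samples(seg, sm[ok], y[ok])
  if (nrow(p) < min_n) return(c(NA_real_, NA_real_))
  ms <- model_select(p$sm, p$y, min_n = min_n, min_side = min_side)
  if (ms$status != "ok" || ms$winner != "piecewise")
    return(c(NA_real_, NA_real_))
  c(ms$theta, ms$se_theta)
}

#' Estimate a threshold map from satellite-style SM and dLST stacks
#'
#' Per pixel: detect overpass dry-downs in the SM series, pool the
#' (SM, dLST) pairs over all dry-downs, run AIC model selection, and keep
#' the threshold only where the linear-plus-plateau model wins.  Pixels
#' with no qualifying dry-downs or a single-regime winner are missing.
#'
#' @param sm,dlst Arrays `n_lat x n_lon x n_time` on a common grid and
#'   time base (a `grid_sim` can be passed as `sm`, in which case `dlst`,
#'   `dates`, `lat`, `lon` are taken from it).
#' @param dates Time coordinate (length `n_time`).
#' @param lat,lon Pixel-center coordinates.
#' @param min_obs,min_span_days Overpass dry-down rule (defaults 5 and 10).
#' @param min_n Minimum pooled samples per pixel (default 15).
#' @param min_side Minimum points per regime in the breakpoint fit.
#' @param provenance Named list recorded on the map (SM product, LST
#'   product, variant).
#' @return A `theta_map` with per-pixel `theta` and `se` matrices plus the
#'   observed SM range per pixel.
#' @export
estimate_theta_map <- function(sm, dlst = NULL, dates = NULL, lat = NULL,
                               lon = NULL, min_obs = 5L,
                               min_span_days = 10L, min_n = 15L,
                               min_side = 3L, provenance = list()) {
  if (inherits(sm, "grid_sim")) {
    g <- sm
    sm <- g$sm
    if (is.null(dlst)) dlst <- g$dlst
    dates <- g$dates; lat <- g$lat; lon <- g$lon
  }
  stopifnot(length(dim(sm)) == 3L, all(dim(sm) == dim(dlst)),
            dim(sm)[3L] == length(dates))
  .map_over_pixels(sm, dlst, dates, lat, lon, daily = FALSE,
                   min_obs = min_obs, min_span_days = min_span_days,
                   min_days = 10L, min_n = min_n, min_side = min_side,
                   provenance = provenance)
}

#' Diagnose a threshold map from model output (daily EF and SM)
#'
#' The Earth-system-model variant of [estimate_theta_map()]: dry-downs are
#' at least `min_days` consecutive days of decreasing SM in the daily
#' model output, and the response is the evaporative fraction.
#'
#' @param ef Daily EF stack `n_lat x n_lon x n_time` (a `grid_sim` can be
#'   passed, in which case its `ef` field is used).
#' @param sm Daily SM stack.
#' @inheritParams estimate_theta_map
#' @param min_days Minimum days of consecutive decline (default 10).
#' @return A `theta_map`.
#' @export
esm_theta_map <- function(ef, sm = NULL, dates = NULL, lat = NULL,
                          lon = NULL, min_days = 10L, min_n = 15L,
                          min_side = 3L, provenance = list()) {
  if (inherits(ef, "grid_sim")) {
    g <- ef
    ef <- g$ef
    if (is.null(sm)) sm <- g$sm
    dates <- g$dates; lat <- g$lat; lon <- g$lon
  }
  stopifnot(length(dim(sm)) == 3L, all(dim(sm) == dim(ef)),
            dim(sm)[3L] == length(dates))
  .map_over_pixels(sm, ef, dates, lat, lon, daily = TRUE, min_obs = 5L,
                   min_span_days = 10L, min_days = min_days,
                   min_n = min_n, min_side = min_side,
                   provenance = provenance)
}

.map_over_pixels <- function(sm, y, dates, lat, lon, daily, min_obs,
                             min_span_days, min_days, min_n, min_side,
                             provenance) {
  nlat <- dim(sm)[1L]; nlon <- dim(sm)[2L]
  theta <- se <- sm_lo <- sm_hi <- matrix(NA_real_, nlat, nlon)
  for (i in seq_len(nlat)) {
    for (j in seq_len(nlon)) {
      v <- sm[i, j, ]
      if (any(is.finite(v))) {
        sm_lo[i, j] <- min(v, na.rm = TRUE)
        sm_hi[i, j] <- max(v, na.rm = TRUE)
      }
      res <- .pixel_theta(dates, v, y[i, j, ], daily, min_obs,
                          min_span_days, min_days, min_n, min_side)
      theta[i, j] <- res[1L]
      se[i, j] <- res[2L]
    }
  }
  .new_theta_map(lat, lon, theta, se, sm_lo, sm_hi, provenance)
}

#' Site-level threshold from a daily tower record
#'
#' The flux-tower pipeline: derive the response (EF from turbulent fluxes
#' or dLST from longwave extremes), restrict to the peak growing season,
#' detect daily dry-downs, pool samples and run AIC model selection.
#'
#' @param series A `site_series` data frame.
#' @param response `"ef"` or `"dlst"`.
#' @param season Restrict to the peak-growing-season window determined
#'   from the GPP record (default TRUE; satellite-style analyses use the
#'   full year).
#' @param min_days Minimum days of decline per dry-down (default 10).
#' @param cfg A [derivation_config()] for the derivations.
#' @param min_n,min_side Passed to [model_select()].
#' @return A `theta_selection`.
#' @export
estimate_site_theta <- function(series, response = c("ef", "dlst"),
                                season = TRUE, min_days = 10L,
                                cfg = derivation_config(), min_n = 15L,
                                min_side = 3L) {
  response <- match.arg(response)
  s <- series
  if (season && any(is.finite(s$gpp))) {
    win <- peak_growing_season(s$date, s$gpp)
    s <- filter_to_season(s, win)
  }
  y <- if (response == "ef") {
    evaporative_fraction(s$le, s$h)
  } else {
    dlst_from_longwave(s$lw_max, s$lw_min, cfg)
  }
  seg <- detect_drydowns_daily(s, min_days = min_days)
  p <- pool_samples(seg, s$sm, y)
  model_select(p$sm, p$y, min_n = min_n, min_side = min_side)
}

#' Threshold-variant maps for ensemble construction
#'
#' Expands one fitted map into its three estimate variants - the per-pixel
#' threshold minus one standard error, the threshold, and the threshold
#' plus one standard error - each clipped to the pixel's observed SM range.
#'
#' @param map A `theta_map`.
#' @return Named list of three `theta_map`s (`lower`, `estimate`,
#'   `upper`).
#' @export
theta_variant_maps <- function(map) {
  stopifnot(inherits(map, "theta_map"))
  se <- ifelse(is.finite(map$se), map$se, 0)
  clip <- function(m) pmin(pmax(m, map$sm_lo), map$sm_hi)
  mk <- function(th, variant) {
    prov <- map$provenance
    prov$variant <- variant
    .new_theta_map(map$lat, map$lon, th, map$se, map$sm_lo, map$sm_hi,
                   prov)
  }
  list(lower = mk(clip(map$theta - se), "lower"),
       estimate = mk(map$theta, "estimate"),
       upper = mk(clip(map$theta + se), "upper"))
}

#' Assemble a threshold ensemble
#'
#' Stacks member maps (e.g. the 18 members from 3 SM products x 2 LST
#' products x 3 estimate variants), and per pixel computes the median over
#' defined members and the relative uncertainty, the ratio of the standard
#' error across members (SD/sqrt(m), switchable to plain SD) to the
#' median.  Pixels with fewer than `min_members` defined members are
#' masked.
#'
#' @param maps List of `theta_map`s on the same grid (at least 2).
#' @param min_members Minimum defined members per pixel (default 6).
#' @param se_scale `"se"` (SD/sqrt(m), default) or `"sd"`.
#' @return A list of class `theta_ensemble`: `lat`, `lon`, `members`
#'   (array `n_lat x n_lon x n_members`), `median`, `rel_uncertainty`,
#'   `n_members` (per-pixel defined count).
#' @export
build_ensemble <- function(maps, min_members = 6L,
                           se_scale = c("se", "sd")) {
  se_scale <- match.arg(se_scale)
  if (length(maps) == 0L) stop("ensemble needs at least one member map")
  stopifnot(all(vapply(maps, inherits, logical(1), "theta_map")))
  if (length(maps) < 2L) stop("ensemble needs at least 2 members")
  lat <- maps[[1L]]$lat; lon <- maps[[1L]]$lon
  for (m in maps)
    if (!identical(m$lat, lat) || !identical(m$lon, lon))
      stop("ensemble members are on different grids")
  stack <- array(NA_real_, c(length(lat), length(lon), length(maps)))
  for (k in seq_along(maps)) stack[, , k] <- maps[[k]]$theta
  n_def <- apply(stack, c(1, 2), function(v) sum(is.finite(v)))
  med <- apply(stack, c(1, 2), stats::median, na.rm = TRUE)
  sdv <- apply(stack, c(1, 2), stats::sd, na.rm = TRUE)
  se <- if (se_scale == "se") sdv / sqrt(pmax(n_def, 1)) else sdv
  mask <- n_def < min_members
  med[mask] <- NA_real_
  rel <- se / med
  rel[mask | !is.finite(med) | med == 0] <- NA_real_
  structure(list(lat = lat, lon = lon, members = stack, median = med,
                 rel_uncertainty = rel, n_members = n_def,
                 min_members = min_members, se_scale = se_scale),
            class = "theta_ensemble")
}

#' Compare a threshold map against tower estimates
#'
#' For each tower site, takes the median of defined map pixels within a
#' `window x window` pixel block around the nearest pixel, then computes
#' the Pearson correlation (and its two-sided test) between the map-window
#' medians and the tower thresholds.
#'
#' @param map A `theta_map` (or `theta_ensemble`, whose median is used).
#' @param towers `data.frame` with columns `lat`, `lon`, `theta`.
#' @param window Odd window size in pixels (default 3).
#' @return List with `r`, `p`, `n` and the paired `table`; `r` is `NA`
#'   with `status = "undefined"` when fewer than 3 pairs are defined.
#' @export
compare_to_towers <- function(map, towers, window = 3L) {
  if (inherits(map, "theta_ensemble"))
    map <- .new_theta_map(map$lat, map$lon, map$median, NULL, NULL, NULL)
  stopifnot(inherits(map, "theta_map"),
            all(c("lat", "lon", "theta") %in% names(towers)))
  half <- (window - 1L) %/% 2L
  nlat <- length(map$lat); nlon <- length(map$lon)
  map_val <- vapply(seq_len(nrow(towers)), function(s) {
    i <- which.min(abs(map$lat - towers$lat[s]))
    j <- which.min(abs(map$lon - towers$lon[s]))
    block <- map$theta[max(1L, i - half):min(nlat, i + half),
                       max(1L, j - half):min(nlon, j + half)]
    if (any(is.finite(block))) stats::median(block[is.finite(block)])
    else NA_real_
  }, numeric(1))
  tab <- data.frame(lat = towers$lat, lon = towers$lon,
                    tower_theta = towers$theta, map_theta = map_val)
  ok <- is.finite(tab$tower_theta) & is.finite(tab$map_theta)
  if (sum(ok) < 3L)
    return(list(r = NA_real_, p = NA_real_, n = sum(ok), table = tab,
                status = "undefined"))
  ct <- stats::cor.test(tab$tower_theta[ok], tab$map_theta[ok],
                        method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok), table = tab,
       status = "ok")
}

#' Pixel-wise average of threshold maps
#'
#' Used for the multi-model mean of model-diagnosed maps.
#'
#' @param maps List of `theta_map`s on the same grid.
#' @return A `theta_map` whose `theta` is the per-pixel mean over defined
#'   members.
#' @export
average_maps <- function(maps) {
  stopifnot(length(maps) >= 1L,
            all(vapply(maps, inherits, logical(1), "theta_map")))
  lat <- maps[[1L]]$lat; lon <- maps[[1L]]$lon
  stack <- array(NA_real_, c(length(lat), length(lon), length(maps)))
  for (k in seq_along(maps)) stack[, , k] <- maps[[k]]$theta
  m <- apply(stack, c(1, 2), function(v)
    if (any(is.finite(v))) mean(v, na.rm = TRUE) else NA_real_)
  .new_theta_map(lat, lon, m, NULL, maps[[1L]]$sm_lo, maps[[1L]]$sm_hi,
                 list(variant = "multi-map mean"))
}

#' Difference between two threshold maps
#'
#' @param a,b `theta_map`s on the same grid.
#' @return Matrix `a - b` where both are defined, `NA` elsewhere.
#' @export
difference_map <- function(a, b) {
  stopifnot(inherits(a, "theta_map"), inherits(b, "theta_map"))
  if (!identical(a$lat, b$lat) || !identical(b$lon, a$lon))
    stop("maps are on different grids")
  a$theta - b$theta
}

#' Write / read a threshold map as long-format CSV
#'
#' Plain-text serialization (columns `lat`, `lon`, `theta`, `se`) of a
#' `theta_map`; missing pixels are written as empty fields.
#'
#' @param map A `theta_map`.
#' @param path File path.
#' @return `write_theta_map_csv` returns the path invisibly;
#'   `read_theta_map_csv` returns a `theta_map`.
#' @export
write_theta_map_csv <- function(map, path) {
  stopifnot(inherits(map, "theta_map"))
  grid <- expand.grid(lat = map$lat, lon = map$lon)
  grid$theta <- as.vector(map$theta)
  grid$se <- if (is.null(map$se)) NA_real_ else as.vector(map$se)
  utils::write.csv(grid, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_theta_map_csv
#' @export
read_theta_map_csv <- function(path) {
  d <- utils::read.csv(path)
  lat <- sort(unique(d$lat)); lon <- sort(unique(d$lon))
  theta <- se <- matrix(NA_real_, length(lat), length(lon))
  i <- match(d$lat, lat); j <- match(d$lon, lon)
  theta[cbind(i, j)] <- d$theta
  se[cbind(i, j)] <- d$se
  .new_theta_map(lat, lon, theta, se, NULL, NULL, list(source = path))
}
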