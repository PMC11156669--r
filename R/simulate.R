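# Synthetic site, grid and feature-table generators with known ground truth.
#
# The site generator emulates the qualitative behaviour the analysis relies
# on: rain-pulse-driven soil moisture that decays between events (so that
# multi-day dry-downs occur), an evaporative fraction and a diurnal LST
# amplitude that respond to SM through the linear-plus-plateau curve around
# a known threshold, and fluxes/longwave radiation that are exactly
# consistent with those responses.

#' Configuration for the synthetic site generator
#'
#' @param n_days Number of daily steps.
#' @param rain_rate Expected rain events per day (Poisson intensity).
#' @param pulse_mean Mean SM jump per rain event (m^3/m^3, exponential).
#' @param decay_rate Daily fractional decay of SM towards `sm_min`.
#' @param sm_min,sm_max Soil moisture bounds (m^3/m^3).
#' @param theta_true Generative critical threshold (m^3/m^3); must lie
#'   strictly between `sm_min` and `sm_max`.
#' @param a_ef,b_ef Plateau level and water-limited slope of the EF
#'   response (unitless; unitless per m^3/m^3).
#' @param a_dlst,b_dlst Plateau level (K) and slope (K per m^3/m^3,
#'   negative) of the dLST response.
#' @param noise_sd_ef,noise_sd_dlst Gaussian noise SD added to EF and dLST.
#' @param emissivity Surface emissivity in (0, 1] used to emit outgoing
#'   longwave radiation.
#' @param available_energy Notional available energy R (W/m^2) partitioned
#'   into LE = EF * R and H = (1 - EF) * R.
#' @param base_lst Diurnal midpoint land-surface temperature (K).
#' @param gpp_peak_doy Day of year at which the seasonal GPP cycle peaks.
#' @param seed Integer seed; every stochastic draw of the simulation is
#'   governed by it.
#' @return A list of class `site_sim_config`.
#' @export
site_sim_config <- function(n_days = 730L, rain_rate = 0.08,
                            pulse_mean = 0.06, decay_rate = 0.04,
                            sm_min = 0.05, sm_max = 0.45,
                            theta_true = 0.20, a_ef = 0.65, b_ef = 2.0,
                            a_dlst = 8.0, b_dlst = -80.0,
                            noise_sd_ef = 0.05, noise_sd_dlst = 1.5,
                            emissivity = 0.97, available_energy = 120,
                            base_lst = 295, gpp_peak_doy = 200L,
                            seed = 1L) {
  if (n_days <= 0) stop("n_days must be positive")
  if (emissivity <= 0 || emissivity > 1) stop("emissivity must be in (0, 1]")
  if (!(sm_min < theta_true && theta_true < sm_max))
    stop("theta_true must lie strictly between sm_min and sm_max")
  if (b_dlst >= 0) stop("b_dlst must be negative (dLST rises as SM falls)")
  structure(as.list(environment()), class = "site_sim_config")
}

#' Simulate a daily flux-tower-style site record
#'
#' Soil moisture follows a pulse-and-decay process: rain events (Poisson
#' arrivals, exponential pulse sizes) lift SM additively; between events SM
#' decays exponentially towards `sm_min`, which guarantees strictly
#' decreasing dry-down runs.  EF and dLST are generated from the
#' linear-plus-plateau curve around `theta_true` plus Gaussian noise (EF
#' clipped to [0.01, 0.99] so the flux inversion stays well defined).
#' LE and H partition a fixed available energy by EF; the daily maximum and
#' minimum outgoing longwave radiation are emitted by the Stefan-Boltzmann
#' law from LSTs placed symmetrically around `base_lst` at dLST/2, so the
#' longwave-based dLST inversion recovers the generative dLST exactly.
#' GPP carries a smooth seasonal cycle peaking at `gpp_peak_doy`.
#'
#' @param config A [site_sim_config()].
#' @return A `data.frame` of class `site_series` with columns `date`, `sm`,
#'   `precip` (mm/day), `le`, `h`, `lw_max`, `lw_min` (W/m^2), `gpp`, and
#'   the noise-free `ef_true`, `dlst_true` plus realized `ef`, `dlst` kept
#'   as generative ground truth (attributes carry the config).
#' @export
simulate_site <- function(config = site_sim_config()) {
  stopifnot(inherits(config, "site_sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- as.integer(cfg$n_days)
  sigma <- 5.670374419e-8

  n_events <- stats::rpois(n, cfg$rain_rate)
  pulses <- vapply(n_events, function(k)
    if (k > 0) sum(stats::rexp(k, rate = 1 / cfg$pulse_mean)) else 0,
    numeric(1))

  sm <- numeric(n)
  sm0 <- min(cfg$sm_max, cfg$sm_min + 2.5 * cfg$pulse_mean)
  prev <- sm0
  for (t in seq_len(n)) {
    val <- cfg$sm_min + (prev - cfg$sm_min) * (1 - cfg$decay_rate) + pulses[t]
    sm[t] <- min(max(val, cfg$sm_min), cfg$sm_max)
    prev <- sm[t]
  }

  ef_true <- plateau_response(sm, cfg$a_ef, cfg$b_ef, cfg$theta_true)
  dlst_true <- plateau_response(sm, cfg$a_dlst, cfg$b_dlst, cfg$theta_true)
  ef <- ef_true + stats::rnorm(n, 0, cfg$noise_sd_ef)
  ef <- pmin(pmax(ef, 0.01), 0.99)
  dlst <- pmax(dlst_true + stats::rnorm(n, 0, cfg$noise_sd_dlst), 0)

  le <- ef * cfg$available_energy
  h <- (1 - ef) * cfg$available_energy
  lst_max <- cfg$base_lst + dlst / 2
  lst_min <- cfg$base_lst - dlst / 2
  lw_max <- cfg$emissivity * sigma * lst_max^4
  lw_min <- cfg$emissivity * sigma * lst_min^4

  date <- as.Date("2015-01-01") + seq_len(n) - 1L
  doy <- as.integer(format(date, "%j"))
  gpp <- 5 + 4 * cos(2 * pi * (doy - cfg$gpp_peak_doy) / 365.25)

  out <- data.frame(date = date, sm = sm, precip = pulses * 100,
                    le = le, h = h, lw_max = lw_max, lw_min = lw_min,
                    gpp = gpp, ef = ef, dlst = dlst,
                    ef_true = ef_true, dlst_true = dlst_true)
  attr(out, "config") <- cfg
  class(out) <- c("site_series", "data.frame")
  out
}

#' Configuration for the synthetic grid generator
#'
#' Each pixel runs the site process with a critical threshold linked to the
#' pixel's covariates, then is subsampled to the satellite revisit.
#'
#' @param n_lat,n_lon Grid shape.
#' @param covariate_fields Named list of `n_lat x n_lon` matrices (default:
#'   a smooth aridity-index gradient, an LAI field and a sand-fraction
#'   field).
#' @param theta_link Named numeric coefficients mapping covariates to the
#'   per-pixel threshold: `intercept` plus one coefficient per covariate.
#'   The linked threshold is clipped to [0.06, 0.40] m^3/m^3.
#' @param revisit_days Sampling interval in days (1 = daily).
#' @param years Length of the simulated record in years.
#' @param noise_sd_dlst,noise_sd_ef Response noise SDs passed per pixel.
#' @param rain_rate,pulse_mean,decay_rate,sm_min,sm_max As in
#'   [site_sim_config()].
#' @param seed Integer seed; per-pixel streams are derived from it.
#' @return A list of class `grid_sim_config`.
#' @export
grid_sim_config <- function(n_lat = 4L, n_lon = 4L,
                            covariate_fields = NULL,
                            theta_link = c(intercept = 0.26,
                                           aridity = -0.04,
                                           lai = 0.02, sand = -0.05),
                            revisit_days = 1L, years = 2L,
                            noise_sd_dlst = 1.5, noise_sd_ef = 0.05,
                            rain_rate = 0.08, pulse_mean = 0.06,
                            decay_rate = 0.04, sm_min = 0.05,
                            sm_max = 0.45, seed = 1L) {
  if (n_lat <= 0 || n_lon <= 0) stop("degenerate grid: need >= 1 pixel")
  if (is.null(covariate_fields)) {
    lat_g <- matrix(seq(0, 1, length.out = n_lat), n_lat, n_lon)
    lon_g <- matrix(seq(0, 1, length.out = n_lon), n_lat, n_lon,
                    byrow = TRUE)
    set.seed(seed)
    covariate_fields <- list(
      aridity = 0.5 + 2.5 * lon_g + 0.3 * lat_g,
      lai = 0.5 + 4 * lat_g,
      sand = matrix(stats::runif(n_lat * n_lon, 0.2, 0.8), n_lat, n_lon))
  }
  stopifnot(length(covariate_fields) > 0,
            all(vapply(covariate_fields, function(m)
              all(is.finite(m)) && all(dim(m) == c(n_lat, n_lon)),
              logical(1))))
  structure(as.list(environment()), class = "grid_sim_config")
}

.theta_from_link <- function(cfg) {
  th <- matrix(cfg$theta_link[["intercept"]], cfg$n_lat, cfg$n_lon)
  for (nm in names(cfg$covariate_fields)) {
    if (nm %in% names(cfg$theta_link))
      th <- th + cfg$theta_link[[nm]] * cfg$covariate_fields[[nm]]
  }
  pmin(pmax(th, 0.06), 0.40)
}

#' Simulate gridded SM and dLST stacks with a known threshold field
#'
#' Runs the site process independently per pixel with
#' `theta_true = theta_link(covariates)`, emits daily series subsampled at
#' the configured revisit interval, and returns the generative threshold
#' field for recovery tests.
#'
#' @param config A [grid_sim_config()].
#' @return A list of class `grid_sim`: `dates` (sampled dates), `sm` and
#'   `dlst` (arrays `n_lat x n_lon x n_time`), `ef` (same shape),
#'   `theta_true` (matrix), `lat`, `lon` (pixel-center coordinates) and the
#'   config.
#' @export
simulate_grid <- function(config = grid_sim_config()) {
  stopifnot(inherits(config, "grid_sim_config"))
  cfg <- config
  theta_true <- .theta_from_link(cfg)
  n_days <- as.integer(round(cfg$years * 365))
  keep <- seq(1L, n_days, by = as.integer(cfg$revisit_days))
  nt <- length(keep)
  sm <- dlst <- ef <- array(NA_real_, c(cfg$n_lat, cfg$n_lon, nt))
  for (i in seq_len(cfg$n_lat)) {
    for (j in seq_len(cfg$n_lon)) {
      scfg <- site_sim_config(
        n_days = n_days, rain_rate = cfg$rain_rate,
        pulse_mean = cfg$pulse_mean, decay_rate = cfg$decay_rate,
        sm_min = cfg$sm_min, sm_max = cfg$sm_max,
        theta_true = theta_true[i, j],
        noise_sd_ef = cfg$noise_sd_ef, noise_sd_dlst = cfg$noise_sd_dlst,
        seed = (cfg$seed * 10007L + i * 101L + j) %% .Machine$integer.max)
      s <- simulate_site(scfg)
      sm[i, j, ] <- s$sm[keep]
      dlst[i, j, ] <- s$dlst[keep]
      ef[i, j, ] <- s$ef[keep]
    }
  }
  structure(list(dates = as.Date("2015-01-01") + keep - 1L,
                 sm = sm, dlst = dlst, ef = ef, theta_true = theta_true,
                 lat = seq(0.125, by = 0.25, length.out = cfg$n_lat),
                 lon = seq(0.125, by = 0.25, length.out = cfg$n_lon),
                 config = cfg),
            class = "grid_sim")
}

#' Simulate a covariate feature table with a known response
#'
#' Test bed for the driver-attribution procedure: named informative
#' covariates act on the response through supplied effect functions, noise
#' covariates are independent of it.
#'
#' @param n Number of rows (pixels); at least 50.
#' @param informative Named list of effect functions; each covariate is
#'   drawn Uniform(0, 1) and its function value added to the response.
#' @param n_noise Number of additional independent Uniform(0, 1) noise
#'   covariates (named `noise1`, `noise2`, ...).
#' @param noise_sd Gaussian SD added to the response.
#' @param seed Integer seed.
#' @return A `data.frame` with the covariates and a `theta_crit` response
#'   column; attribute `informative` names the true drivers.
#' @export
simulate_feature_table <- function(n = 2000L,
                                   informative = list(
                                     aridity = function(x) 0.30 - 0.15 * x),
                                   n_noise = 10L, noise_sd = 0.02,
                                   seed = 1L) {
  if (n < 50) stop("n must be at least 50")
  if (length(informative) == 0) stop("informative set must be non-empty")
  if (is.null(names(informative)) || any(!nzchar(names(informative))))
    stop("informative effects must be named")
  set.seed(seed)
  X <- as.data.frame(lapply(seq_along(informative),
                            function(i) stats::runif(n)))
  names(X) <- names(informative)
  response <- rowSums(mapply(function(f, x) f(x), informative, X))
  if (n_noise > 0) {
    N <- as.data.frame(matrix(stats::runif(n * n_noise), n, n_noise))
    names(N) <- paste0("noise", seq_len(n_noise))
    X <- cbind(X, N)
  }
  X$theta_crit <- response + stats::rnorm(n, 0, noise_sd)
  attr(X, "informative") <- names(informative)
  X
}

#' Write a simulated site series as a FLUXNET-style CSV
#'
#' @param series A `site_series` from [simulate_site()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_site_csv <- function(series, path) {
  cols <- c("date", "sm", "precip", "le", "h", "lw_max", "lw_min", "gpp")
  utils::write.csv(as.data.frame(series)[, cols], path, row.names = FALSE)
  invisible(path)
}
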