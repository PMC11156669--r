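# Derivation of the analysis variables: diurnal LST amplitude from outgoing
# longwave radiation (Stefan-Boltzmann inversion) or LST samples,
# evaporative fraction from turbulent fluxes, and product bias correction
# of satellite soil moisture.

#' Derivation configuration
#'
#' @param emissivity Surface emissivity in (0, 1]; treated as a site
#'   constant.  Because the same emissivity enters the forward emission and
#'   the inversion, the estimated threshold is insensitive to its value
#'   (emissivity rescales dLST monotonically and the breakpoint abscissa
#'   depends only on SM).
#' @param sigma Stefan-Boltzmann constant (W/m^2/K^4).
#' @param sm_bias Named numeric vector of product biases (m^3/m^3) to be
#'   subtracted from retrieved soil moisture.  Defaults to the in-situ
#'   validated biases of the three L-band products.
#' @return A list of class `derivation_config`.
#' @export
derivation_config <- function(emissivity = 0.97,
                              sigma = 5.670374419e-8,
                              sm_bias = c("SMAP-IB" = 0.002,
                                          "SCA-V" = 0.008,
                                          "SMOS-IC" = -0.054)) {
  if (emissivity <= 0 || emissivity > 1) stop("emissivity must be in (0, 1]")
  structure(list(emissivity = emissivity, sigma = sigma, sm_bias = sm_bias),
            class = "derivation_config")
}

#' Diurnal LST amplitude from outgoing longwave extremes
#'
#' Inverts the Stefan-Boltzmann law for the daily maximum and minimum
#' outgoing longwave radiation:
#' `dLST = ((LWmax/sigma)^(1/4) - (LWmin/sigma)^(1/4)) / emissivity^(1/4)`.
#' Emissivity is a same-site, same-day constant, so it factors out of the
#' difference of fourth roots.
#'
#' @param lw_max,lw_min Daily maximum and minimum outgoing longwave
#'   radiation (W/m^2), vectors.
#' @param cfg A [derivation_config()].
#' @return dLST in K (non-negative), same length as the inputs.
#' @export
dlst_from_longwave <- function(lw_max, lw_min, cfg = derivation_config()) {
  stopifnot(inherits(cfg, "derivation_config"),
            length(lw_max) == length(lw_min))
  bad <- is.finite(lw_max) & is.finite(lw_min) & (lw_min <= 0 | lw_max <= 0)
  if (any(bad)) stop("non-positive longwave radiation is not physical")
  ord <- is.finite(lw_max) & is.finite(lw_min) & lw_max < lw_min
  if (any(ord)) stop("lw_max < lw_min: daily extremes are mis-ordered")
  ((lw_max / cfg$sigma)^(1 / 4) - (lw_min / cfg$sigma)^(1 / 4)) /
    cfg$emissivity^(1 / 4)
}

#' Diurnal LST amplitude from within-day LST samples
#'
#' @param lst_samples Vector of LST samples (K) for one day (e.g. 24 hourly
#'   geostationary values, or 4 polar-orbiter overpasses).
#' @param min_samples Minimum number of valid samples for a defined
#'   amplitude (default 2).
#' @return max - min of the valid samples (K), or `NA` when fewer than
#'   `min_samples` are valid.
#' @export
dlst_from_lst_samples <- function(lst_samples, min_samples = 2L) {
  v <- lst_samples[is.finite(lst_samples)]
  if (length(v) < min_samples) return(NA_real_)
  max(v) - min(v)
}

#' Evaporative fraction from turbulent fluxes
#'
#' `EF = LE / (LE + H)`.  Days whose available energy `LE + H` falls below
#' the floor are returned as missing rather than raising an error: a small
#' or negative denominator (night, transition hours) makes the ratio
#' meaningless, not the record invalid.
#'
#' @param le,h Latent and sensible heat flux (W/m^2), vectors.
#' @param floor Minimum `LE + H` (W/m^2) for a defined EF (default 10).
#' @return EF (unitless), `NA` where undefined; lies in [0, 1] whenever
#'   both fluxes are non-negative.
#' @export
evaporative_fraction <- function(le, h, floor = 10) {
  stopifnot(length(le) == length(h))
  den <- le + h
  ifelse(is.finite(den) & den > floor, le / den, NA_real_)
}

#' Subtract a validated product bias from soil moisture
#'
#' @param sm Soil moisture (m^3/m^3), vector.
#' @param product Product name; must be a name of `cfg$sm_bias`.
#' @param cfg A [derivation_config()].
#' @return Bias-corrected SM, clipped at 0.
#' @export
correct_sm_bias <- function(sm, product, cfg = derivation_config()) {
  stopifnot(inherits(cfg, "derivation_config"))
  if (!product %in% names(cfg$sm_bias))
    stop(sprintf("unknown product '%s'; configured: %s", product,
                 paste(names(cfg$sm_bias), collapse = ", ")))
  pmax(sm - cfg$sm_bias[[product]], 0)
}

#' Read a FLUXNET-style daily CSV
#'
#' Reads a comma-separated daily record, maps columns to the package's
#' canonical names and converts the -9999 sentinel to missing.
#'
#' @param path CSV path.
#' @param col_map Named character vector mapping canonical names (`date`,
#'   `sm`, `precip`, `le`, `h`, `lw_max`, `lw_min`, `gpp`) to the file's
#'   column names; identity by default.
#' @param na_sentinel Sentinel value treated as missing (default -9999).
#' @return A `data.frame` of class `site_series`.
#' @export
read_site_csv <- function(path, col_map = NULL, na_sentinel = -9999) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  canonical <- c("date", "sm", "precip", "le", "h", "lw_max", "lw_min",
                 "gpp")
  if (is.null(col_map)) col_map <- stats::setNames(canonical, canonical)
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (nm in canonical) {
    src <- if (nm %in% names(col_map)) col_map[[nm]] else nm
    if (src %in% names(raw)) {
      v <- raw[[src]]
      if (is.numeric(v)) v[v == na_sentinel] <- NA
      out[[nm]] <- v
    } else {
      out[[nm]] <- NA
    }
  }
  out$date <- as.Date(out$date)
  class(out) <- c("site_series", "data.frame")
  out
}
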