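# Linear-plus-plateau breakpoint regression for EF-SM and dLST-SM coupling.
#
# The response model is
#   y = a + b (SM - theta)   if SM <  theta
#   y = a                    if SM >= theta
# where theta is the critical soil moisture threshold, a the unstressed
# (energy-limited) response level and b the slope of the water-limited phase.
# The fit is continuous at theta by construction.

#' Linear-plus-plateau response curve
#'
#' Evaluates the two-regime response used throughout the package: linear in
#' soil moisture below the critical threshold, constant above it.
#'
#' @param sm Soil moisture (m^3/m^3), numeric vector.
#' @param a Plateau level (response units): the unstressed value of EF (its
#'   maximum) or of dLST (its minimum).
#' @param b Slope of the water-limited phase (response units per m^3/m^3);
#'   positive for EF, negative for dLST.
#' @param theta Critical soil moisture threshold (m^3/m^3).
#' @return Numeric vector of responses, same length as `sm`.
#' @export
plateau_response <- function(sm, a, b, theta) {
  ifelse(sm < theta, a + b * (sm - theta), a)
}

# Conditional least squares for fixed theta: OLS of y on u = min(SM-theta, 0).
# Closed-form normal equations; returns a, b and the residual sum of squares.
.plateau_ols <- function(sm, y, theta) {
  u <- pmin(sm - theta, 0)
  n <- length(y)
  su <- sum(u); suu <- sum(u * u)
  sy <- sum(y); suy <- sum(u * y)
  den <- n * suu - su * su
  if (den <= .Machine$double.eps * n * max(suu, 1)) {
    a <- sy / n
    return(list(a = a, b = 0, rss = sum((y - a)^2)))
  }
  b <- (n * suy - su * sy) / den
  a <- (sy - b * su) / n
  r <- y - a - b * u
  list(a = a, b = b, rss = sum(r * r))
}

.new_plateau_fit <- function(model, a = NA_real_, b = NA_real_,
                             theta = NA_real_, se_theta = NA_real_,
                             rss = NA_real_, n = 0L, k = NA_integer_,
                             status = "ok") {
  structure(list(model = model, a = a, b = b, theta = theta,
                 se_theta = se_theta, rss = rss, n = as.integer(n),
                 k = as.integer(k), status = status),
            class = "plateau_fit")
}

#' @export
print.plateau_fit <- function(x, ...) {
  cat(sprintf("<%s fit> status: %s, n = %d\n", x$model, x$status, x$n))
  if (x$status == "ok") {
    cat(sprintf("  a = %.4g, b = %.4g", x$a, x$b))
    if (!is.na(x$theta))
      cat(sprintf(", theta = %.4g (se %.4g)", x$theta, x$se_theta))
    cat(sprintf("\n  rss = %.4g, k = %d\n", x$rss, x$k))
  }
  invisible(x)
}

.drop_na_pairs <- function(sm, y) {
  stopifnot(length(sm) == length(y))
  ok <- is.finite(sm) & is.finite(y)
  list(sm = sm[ok], y = y[ok])
}

#' Constant (intercept-only) fit
#'
#' The energy-limited limiting case: the response does not depend on soil
#' moisture at all.  `a` is the sample mean and the residual sum of squares
#' is the total sum of squares about it.
#'
#' @param sm Soil moisture values (used only for sample bookkeeping).
#' @param y Response values (EF or dLST).
#' @return A `plateau_fit` with `b = 0` and `theta` undefined; `k = 2`
#'   parameters (mean + error variance).  `status` is `"insufficient_data"`
#'   when fewer than 3 valid pairs are supplied.
#' @export
fit_constant <- function(sm, y) {
  d <- .drop_na_pairs(sm, y)
  n <- length(d$y)
  if (n < 3L)
    return(.new_plateau_fit("constant", n = n, k = 2L,
                            status = "insufficient_data"))
  a <- mean(d$y)
  .new_plateau_fit("constant", a = a, b = 0, rss = sum((d$y - a)^2),
                   n = n, k = 2L)
}

#' Simple linear fit
#'
#' The single-regime candidate: ordinary least squares of the response on
#' soil moisture over the whole sample (water-limited-only reading).
#'
#' @inheritParams fit_constant
#' @return A `plateau_fit` with `theta` undefined and `k = 3`.  `status`
#'   is `"degenerate"` when SM has zero variance, `"insufficient_data"`
#'   when n < 3.
#' @export
fit_linear <- function(sm, y) {
  d <- .drop_na_pairs(sm, y)
  n <- length(d$y)
  if (n < 3L)
    return(.new_plateau_fit("linear", n = n, k = 3L,
                            status = "insufficient_data"))
  sxx <- sum((d$sm - mean(d$sm))^2)
  if (sxx <= 0)
    return(.new_plateau_fit("linear", n = n, k = 3L, status = "degenerate"))
  b <- sum((d$sm - mean(d$sm)) * (d$y - mean(d$y))) / sxx
  a <- mean(d$y) - b * mean(d$sm)
  r <- d$y - a - b * d$sm
  # report the intercept in `a` and slope in `b` (y = a + b * SM)
  .new_plateau_fit("linear", a = a, b = b, rss = sum(r * r), n = n, k = 3L)
}

# Delta-method standard error of the breakpoint via the standard segmented
# linearization: refit y ~ u + V at theta-hat with u = min(SM - theta, 0)
# and V = -1[SM < theta] (the derivative of u in theta times 1/b), then
# se(theta) = se(gamma-hat) / |b-hat|.
.se_theta_delta <- function(sm, y, theta) {
  u <- pmin(sm - theta, 0)
  V <- -as.numeric(sm < theta)
  X <- cbind(1, u, V)
  n <- length(y)
  if (n <= 3L) return(NA_real_)
  XtXinv <- tryCatch(solve(crossprod(X)), error = function(e) NULL)
  if (is.null(XtXinv)) return(NA_real_)
  beta <- XtXinv %*% crossprod(X, y)
  rss <- sum((y - X %*% beta)^2)
  se_gamma <- sqrt(max(rss, 0) / (n - 3L) * XtXinv[3L, 3L])
  b <- beta[2L]
  if (!is.finite(b) || abs(b) < .Machine$double.eps) return(NA_real_)
  unname(se_gamma / abs(b))
}

.se_theta_bootstrap <- function(sm, y, min_side, B, seed) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(y)
  th <- vapply(seq_len(B), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    f <- fit_piecewise(sm[idx], y[idx], min_side = min_side,
                       se_method = "none")
    if (f$status == "ok") f$theta else NA_real_
  }, numeric(1))
  stats::sd(th, na.rm = TRUE)
}

#' Linear-plus-plateau breakpoint fit
#'
#' Fits the two-regime model by profiling the breakpoint: within every
#' interval between consecutive sorted SM values that leaves at least
#' `min_side` points on each side, the conditional least-squares problem in
#' (a, b) is solved in closed form and the residual sum of squares is
#' minimized over theta inside the interval (Brent search plus endpoint
#' checks); the global minimizer over all admissible intervals is returned.
#' The fitted curve is continuous at the breakpoint by construction.
#'
#' The breakpoint standard error is computed with the delta method on the
#' standard segmented-regression linearization (refitting with the
#' indicator "gap" covariate at the estimate); a seeded nonparametric pair
#' bootstrap is available as a cross-check.
#'
#' When the data carry no plateau within the observed range (e.g. a pure
#' line), the profiled breakpoint is pushed against the admissible boundary
#' without improving on the straight-line fit; that outcome is reported as
#' `status = "no_breakpoint"` rather than as a spurious threshold.
#'
#' Identifiability guard: a breakpoint is only meaningful when both regimes
#' are actually observed over a non-trivial extent of soil moisture, so the
#' admissible breakpoint window excludes the outer `edge_frac` of the
#' observed SM span on each side (in addition to the `min_side` point
#' counts).  A sliver "plateau" carried by a handful of extreme SM values
#' is thereby reported as `no_breakpoint` instead of a spurious threshold.
#'
#' @inheritParams fit_constant
#' @param min_side Minimum number of points required strictly below and at
#'   or above any candidate breakpoint (default 3).
#' @param edge_frac Fraction of the observed SM span excluded from the
#'   admissible breakpoint window at each end (default 0.1); set to 0 to
#'   disable the span guard and rely on point counts alone.
#' @param se_method `"delta"` (default), `"bootstrap"`, or `"none"`.
#' @param B Number of bootstrap resamples when `se_method = "bootstrap"`.
#' @param seed Seed for the bootstrap resampling.
#' @return A `plateau_fit` with `k = 4`; `theta` and `se_theta` populated
#'   when `status == "ok"`.
#' @export
fit_piecewise <- function(sm, y, min_side = 3L, edge_frac = 0.1,
                          se_method = c("delta", "bootstrap", "none"),
                          B = 200L, seed = NULL) {
  se_method <- match.arg(se_method)
  d <- .drop_na_pairs(sm, y)
  sm <- d$sm; y <- d$y
  n <- length(y)
  if (n < 2L * min_side + 1L)
    return(.new_plateau_fit("piecewise", n = n, k = 4L,
                            status = "insufficient_data"))
  xs <- sort(unique(sm))
  span <- diff(range(xs))
  if (length(xs) < 2L || span <= 0)
    return(.new_plateau_fit("piecewise", n = n, k = 4L,
                            status = "degenerate"))
  win <- c(min(xs) + edge_frac * span, max(xs) - edge_frac * span)
  n_below <- cumsum(tabulate(match(sort(sm), xs), nbins = length(xs)))
  # theta in (xs[i], xs[i+1]] puts n_below[i] points in the linear regime
  valid <- which(n_below[-length(xs)] >= min_side &
                 (n - n_below[-length(xs)]) >= min_side &
                 xs[-1L] > win[1L] & xs[-length(xs)] < win[2L])
  if (length(valid) == 0L)
    return(.new_plateau_fit("piecewise", n = n, k = 4L,
                            status = "no_breakpoint"))
  best <- list(rss = Inf, theta = NA_real_)
  obj <- function(t) .plateau_ols(sm, y, t)$rss
  for (i in valid) {
    lo <- max(xs[i], win[1L]); hi <- min(xs[i + 1L], win[2L])
    opt <- stats::optimize(obj, lower = lo, upper = hi, tol = 1e-10)
    cand <- rbind(c(opt$minimum, opt$objective), c(lo, obj(lo)),
                  c(hi, obj(hi)))
    j <- which.min(cand[, 2L])
    if (cand[j, 2L] < best$rss)
      best <- list(rss = cand[j, 2L], theta = cand[j, 1L])
  }
  sol <- .plateau_ols(sm, y, best$theta)
  # boundary guard: a breakpoint jammed against the admissible window that
  # does not beat the straight line indicates no plateau in range
  lo_allowed <- max(xs[min(valid)], win[1L])
  hi_allowed <- min(xs[max(valid) + 1L], win[2L])
  tol_b <- 1e-7 * span
  lin <- fit_linear(sm, y)
  at_boundary <- (best$theta - lo_allowed) <= tol_b ||
                 (hi_allowed - best$theta) <= tol_b
  if (at_boundary && lin$status == "ok" && sol$rss >= lin$rss - 1e-9)
    return(.new_plateau_fit("piecewise", n = n, k = 4L,
                            status = "no_breakpoint"))
  se <- switch(se_method,
               delta = .se_theta_delta(sm, y, best$theta),
               bootstrap = .se_theta_bootstrap(sm, y, min_side, B, seed),
               none = NA_real_)
  .new_plateau_fit("piecewise", a = sol$a, b = sol$b, theta = best$theta,
                   se_theta = se, rss = sol$rss, n = n, k = 4L)
}

# AIC on the Gaussian profile likelihood: n log(rss/n) + 2k, with a floor
# on rss so exact fits do not produce -Inf.
.aic_rss <- function(rss, n, k, rss_floor = 1e-12) {
  n * log(max(rss, rss_floor) / n) + 2 * k
}

#' Candidate-model selection by AIC
#'
#' Fits the candidate response models (constant, linear, linear-plus-
#' plateau) to pooled dry-down samples and selects the one with the lowest
#' Akaike Information Criterion, `n log(RSS/n) + 2k` with k = 2, 3 and 4
#' parameters respectively.  Ties go to the model with fewer parameters.
#' A critical threshold is reported only when the linear-plus-plateau
#' model wins.
#'
#' @inheritParams fit_piecewise
#' @param min_n Minimum pooled sample size for any selection (default 15).
#' @param candidates Character subset of
#'   `c("constant", "linear", "piecewise")`; the default is all three, and
#'   `c("linear", "piecewise")` mimics a strict two-linear-candidates
#'   reading.
#' @return An object of class `theta_selection`: list with `fits` (named
#'   list of `plateau_fit`s), `aic` (named vector), `winner`, `theta`,
#'   `se_theta` and `status`.
#' @export
model_select <- function(sm, y, min_n = 15L, min_side = 3L,
                         candidates = c("constant", "linear", "piecewise"),
                         se_method = "delta") {
  candidates <- match.arg(candidates, several.ok = TRUE)
  d <- .drop_na_pairs(sm, y)
  out <- structure(list(fits = list(), aic = numeric(0), winner = NA_character_,
                        theta = NA_real_, se_theta = NA_real_,
                        n = length(d$y), status = "ok"),
                   class = "theta_selection")
  if (length(d$y) < min_n) {
    out$status <- "insufficient_data"
    return(out)
  }
  fits <- list()
  if ("constant" %in% candidates) fits$constant <- fit_constant(d$sm, d$y)
  if ("linear" %in% candidates) fits$linear <- fit_linear(d$sm, d$y)
  if ("piecewise" %in% candidates)
    fits$piecewise <- fit_piecewise(d$sm, d$y, min_side = min_side,
                                    se_method = se_method)
  usable <- vapply(fits, function(f) f$status == "ok", logical(1))
  out$fits <- fits
  if (!any(usable)) {
    out$status <- "no_model"
    return(out)
  }
  aic <- vapply(fits[usable], function(f) .aic_rss(f$rss, f$n, f$k),
                numeric(1))
  out$aic <- aic
  k <- vapply(fits[usable], function(f) f$k, integer(1))
  # lowest AIC wins; exact ties resolved toward fewer parameters
  ord <- order(aic, k)
  out$winner <- names(aic)[ord[1L]]
  if (out$winner == "piecewise") {
    out$theta <- fits$piecewise$theta
    out$se_theta <- fits$piecewise$se_theta
  }
  out
}

#' @export
print.theta_selection <- function(x, ...) {
  cat(sprintf("<model selection> status: %s, n = %d\n", x$status, x$n))
  if (length(x$aic)) {
    cat("  AIC:", paste(sprintf("%s %.2f", names(x$aic), x$aic),
                        collapse = ", "), "\n")
    cat(sprintf("  winner: %s", x$winner))
    if (!is.na(x$theta))
      cat(sprintf(" (theta = %.4f +/- %.4f m3/m3)", x$theta, x$se_theta))
    cat("\n")
  }
  invisible(x)
}

#' Breakpoint estimate with its standard-error variants
#'
#' Returns the three threshold variants used as ensemble members:
#' the estimate minus one standard error, the estimate, and the estimate
#' plus one standard error, each clipped to the observed SM range.
#'
#' @param fit A `plateau_fit` from [fit_piecewise()] (or the piecewise
#'   winner of [model_select()]).
#' @param sm_range Optional length-2 numeric giving the observed SM range
#'   used for clipping.
#' @return Named numeric vector `c(lower=, estimate=, upper=)`.
#' @export
theta_variants <- function(fit, sm_range = NULL) {
  stopifnot(inherits(fit, "plateau_fit"))
  if (fit$status != "ok" || is.na(fit$theta))
    stop("theta_variants() requires a successful piecewise fit")
  se <- if (is.finite(fit$se_theta)) fit$se_theta else 0
  v <- c(lower = fit$theta - se, estimate = fit$theta,
         upper = fit$theta + se)
  if (!is.null(sm_range)) {
    stopifnot(length(sm_range) == 2L)
    v <- pmin(pmax(v, min(sm_range)), max(sm_range))
  }
  v
}
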