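---
title: "Estimating critical soil moisture thresholds from dry-downs"
author: "thetacrit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating critical soil moisture thresholds from dry-downs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thetacrit)
```

## The problem

During rain-free dry-downs, surface soil moisture (SM) decays until, at a
critical level $\theta_{crit}$, evapotranspiration becomes water limited:
below the threshold the evaporative fraction
$EF = LE / (LE + H)$ declines with SM, and the diurnal amplitude of land
surface temperature ($dLST$, daily maximum minus minimum) rises as an
increasing share of available energy goes into sensible heat.  Above the
threshold both are insensitive to SM (the energy-limited regime).
`thetacrit` estimates $\theta_{crit}$ from this two-regime behaviour, maps
it per pixel with ensemble uncertainty, quantifies how many days per year
ecosystems spend below it, and attributes its spatial variation to
environmental drivers.

## The response model

Both responses are modelled by a continuous linear-plus-plateau curve

$$
y = \begin{cases} a + b\,(SM - \theta_{crit}) & SM < \theta_{crit} \\
a & SM \ge \theta_{crit}, \end{cases}
$$

where $a$ is the unstressed response level (maximum EF, or minimum dLST),
$b$ the slope of the water-limited phase ($b > 0$ for EF, $b < 0$ for
dLST), and $\theta_{crit}$ the breakpoint in m$^3$/m$^3$.  The model is
fitted by profiling the breakpoint: for fixed $\theta$ the problem is
ordinary least squares in $(a, b)$ on the basis
$u = \min(SM - \theta, 0)$, solved in closed form; the residual sum of
squares is then minimized over $\theta$ within every interval between
consecutive sorted SM values (Brent search plus endpoint checks), and the
global minimizer is returned.  A dense-grid search over $10^4$ candidate
breakpoints is used as an independent oracle in the test suite.

Candidate models per sample are the intercept-only fit (purely
energy-limited), the single straight line (purely water-limited) and the
linear-plus-plateau fit, compared by
$AIC = n\,\log(RSS/n) + 2k$ with $k = 2, 3, 4$ respectively; the lowest
AIC wins, ties go to fewer parameters, and a threshold is reported only
when the plateau model wins.  An RSS floor of $10^{-12}$ keeps the
log-likelihood finite on exact fits.  A flat energy-limited candidate is
the natural limit of the plateau model; users wanting a strict
two-linear-candidates comparison can pass
`candidates = c("linear", "piecewise")`.

### Identifiability guard

A breakpoint is only interpretable when both regimes are observed over a
non-trivial extent of soil moisture.  Besides requiring `min_side = 3`
points on each side of the breakpoint, the admissible breakpoint window
excludes the outer 10% of the observed SM span on each end
(`edge_frac = 0.1`).  Without this guard, data generated by a single
straight line frequently admit a sliver "plateau" over the last few
extreme SM values that fits noise well enough for the AIC to prefer it;
with the guard such fits collapse onto the window boundary without
improving on the straight line and are reported as `no_breakpoint`.  The
guard is conservative for genuine thresholds near the edge of the sampled
SM range: those pixels are reported as undefined rather than as uncertain
estimates.

### Breakpoint standard error

The default standard error of $\hat\theta$ uses the delta method on the
standard segmented-regression linearization: at the estimate, the model is
refitted with the gap covariate $V = -\mathbf{1}[SM < \hat\theta]$
alongside $u$, and $se(\hat\theta) = se(\hat\gamma)/|\hat b|$ where
$\gamma$ is the gap coefficient.  A seeded pair bootstrap
(`se_method = "bootstrap"`, B = 200 by default) is available as a
cross-check; the two agree in scale on the synthetic testbed.  We make no
claim of bit-equality with any particular segmented-regression
implementation's internal estimator; on 200 synthetic sites the
$\pm 2\,se$ interval covers the generative threshold about 90% of the
time.

## Dry-down detection

Daily tower series: maximal runs of strictly decreasing SM (ties break a
run; the tolerance is configurable) lasting at least 10 days of decline,
whose starting peak follows rain (positive precipitation on the peak day
or the day before, or an SM rise of at least 0.005 m$^3$/m$^3$ when no
precipitation record exists - satellite grids carry none).  The 10-day
rule is a parameter (`min_days`), and weakening it to 9 or strengthening
to 11 yields a superset/subset of segments, which the suite checks.
Tower analysis is restricted to the peak growing season - the
three-calendar-month window (wrap-around allowed) with the highest
multi-year mean GPP, earliest window on ties - while satellite-style and
model-output analyses use the full year.

Irregular overpass series: maximal runs of consecutive overpasses with
decreasing SM, kept when they contain at least `min_obs` overpasses (5
for 1-3-day revisit products, 4 for 2-4-day revisit) spanning at least 10
days.  Samples from all dry-downs of a site or pixel are pooled before
fitting; at least 15 pooled pairs are required.

## Surface variables

dLST is obtained either directly as max minus min of within-day LST
samples (at least 2 valid samples) or by inverting the Stefan-Boltzmann
law from daily outgoing-longwave extremes,
$dLST = ((LW_{max}/\sigma)^{1/4} - (LW_{min}/\sigma)^{1/4})
/ \varepsilon^{1/4}$.  Emissivity (default 0.97) is treated as a per-site
constant; because it enters emission and inversion identically it cancels
exactly, and the breakpoint abscissa depends only on SM, so
$\theta_{crit}$ is insensitive to it.  EF requires
$LE + H \ge 10$ W/m$^2$ (a configurable floor suppressing
night/transition noise); smaller denominators yield missing values, not
errors.  Satellite SM is bias-corrected by subtracting per-product
offsets validated against in-situ networks (0.002, 0.008 and -0.054
m$^3$/m$^3$ for the three default products), clipped at zero.

## Mapping, ensemble and uncertainty

Per pixel, overpass dry-down detection feeds pooled (SM, dLST) samples
into the AIC selection; pixels with no qualifying dry-downs or a
single-regime winner are missing.  Each fitted map expands into three
variant members (estimate and estimate $\pm$ one standard error, clipped
to the pixel's observed SM range), so three SM products crossed with two
LST products yield an 18-member ensemble.  The reported map is the
per-pixel member median; relative uncertainty is the ratio of the
standard error across members to the median.  "Standard error" here is
SD/$\sqrt{m}$ over the $m$ defined members (a literal reading;
`se_scale = "sd"` switches to the plain SD).  Pixels with fewer than
`min_members = 6` defined members - one full SM-LST pairing with its
variants - are masked rather than reported from a thin ensemble.  Tower
comparison extracts the median of defined pixels in a 3x3 window around
each site and reports the Pearson correlation with its two-sided test.
Model-output (daily EF) maps use the 10-day daily rule, and model minus
observation difference maps are defined where both are.

## Stress exposure and trends

The annual fraction of stressed days is the number of observed days with
SM strictly below $\theta_{crit}$ (ties count as unstressed) over the
number of observed days; years with fewer than 180 valid days are
undefined.  Across SM products the per-pixel median is taken.  Trends use
the Mann-Kendall test with tie-corrected variance and continuity
correction, and Sen's slope (median of all pairwise slopes) with the
rank-based 95% interval; a constant series returns slope 0 and p = 1.
Regional series bin pixels by climatological mean FSD into half-open bins
[10, 30), [30, 50), [50, 70), [70, 90)% - the extremes below 10% and at
or above 90% are excluded - and trend each bin's annual spatial median.
Pixels with more than 10% land-cover change are masked (strictly greater;
exactly 10% is retained).  No autocorrelation prewhitening is applied;
the test's empirical size on white-noise series is checked at 5% $\pm$ 2%
in the suite.

## Driver attribution

The spatial driver analysis regresses pixel thresholds on covariates with
a random forest (the standard `randomForest` learner) wrapped in the
bespoke selection procedure: recursive feature elimination drops the
covariate with the lowest out-of-bag permutation importance (10
permutations per covariate, seeded) until three remain, then re-adds
candidates in stored importance order, keeping each only if the
out-of-bag $R^2$ - computed as $1 - SSE/SST$ on out-of-bag predictions,
one of two common conventions - improves by at least 0.005; the
combination with the highest out-of-bag $R^2$ along that path is
selected.  Hyperparameters (variables per split between 2 and the number
of covariates, trees between 50 and 5000) are tuned on the same
out-of-bag criterion over a coarse seeded grid.

Shapley attributions use the permutation-sampling estimator with an
interventional background: for each sampled covariate ordering, the
marginal change in the background-averaged prediction as each covariate
switches from background to the explained row is credited to that
covariate.  Contributions along one ordering telescope from the
background mean to the row's prediction, so local accuracy holds exactly
for the averaged estimate, which the suite asserts to $10^{-10}$.  The
estimator's Monte-Carlo error affects only the split among covariates,
shrinking with the number of sampled orderings.  Group contrasts
(biomes, climate or aridity classes, crop types) use the Kruskal-Wallis
rank test, with H = 0 and p = 1 on fully tied samples.  The aridity index
follows the PET/P convention (higher = drier); class boundaries are
supplied as configuration, with `unep_aridity_classes()` providing the
conventional five-class table converted to that convention.

## What the synthetic generator emulates - and what it does not

The site generator produces rain pulses (Poisson arrivals, exponential
sizes), exponential SM decay towards a floor between events (so dry-downs
are strictly decreasing by construction), EF and dLST drawn from the
plateau curve around a known threshold plus Gaussian noise, EF-consistent
fluxes for a fixed available energy of 120 W/m$^2$, longwave extremes
emitted by the Stefan-Boltzmann law around a 295 K diurnal midpoint (the
level is arbitrary: only the amplitude carries signal), and a seasonal
GPP cycle.  Defaults (two years, 0.08 events/day, 0.06 m$^3$/m$^3$ mean
pulse, 4%/day decay, SM in [0.05, 0.45], $\theta = 0.20$, EF noise 0.05,
dLST noise 1.5 K) are chosen so that a site realistically yields a few
tens of dry-downs with both regimes sampled.  Satellite SM observational
noise is not characterized by a published value; the generator exposes
the noise SD as a knob without claiming a data-anchored default.

Real data differ in ways the generator does not emulate: autocorrelated
and heteroscedastic retrieval errors, seasonal confounding between
energy and water limitation, drainage that is not a single exponential,
irregular gaps, and footprint mismatch between point towers and 25-km
pixels.  Passing tests therefore demonstrate the correctness and
statistical calibration of the procedure under the stated generative
assumptions, not retrieval-error robustness.

## Numerical choices and problem sizes

Brent's tolerance for the per-interval profile is $10^{-10}$; recovered
noise-free parameters are exact to $10^{-6}$.  The suite and the
acceptance script use: 50 random instances against the $10^4$-point grid
oracle; 200 synthetic sites (n = 150, EF noise 0.05) for recovery and
coverage; 100 two-year sites for EF-vs-dLST method consistency; 100
seeds per regime for the selection operating characteristics; 1000 null
series of length 40 for the trend test's size; a 100-pixel, 40-year
field with a +0.003/yr drift for trend recovery; an 8x8 two-year daily
grid for map recovery; and five seeds of a 2000-row, 10-covariate table
for driver recovery.  These sizes give stable statistics while keeping a
full run in single-digit minutes on one core.

## Known limitations

Single-breakpoint model only (no soil-water-potential thresholds, no
multi-breakpoint fits, no heteroscedastic errors); no energy-balance
closure correction or cloud masking of LST; Mann-Kendall p-values assume
serial independence; grids are serialized as plain CSV rather than
NetCDF/GeoTIFF, and regridding beyond what the simulator provides is out
of scope.  The threshold is treated as time-invariant in the trend
analysis, consistent with multi-decadal site evidence that its drift is
small relative to the FSD signal.
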