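# thetacrit

Critical soil moisture thresholds of plant water stress from dry-down
breakpoint regression.

## What it does and for whom

During rain-free dry-downs, declining surface soil moisture (SM)
eventually limits evapotranspiration.  The SM level at which that happens
— the critical threshold θ_crit — separates the energy-limited regime
(evaporative fraction EF = LE/(LE+H) insensitive to SM, diurnal LST
amplitude dLST flat) from the water-limited regime (EF falls, dLST rises
as SM drops).  `thetacrit` is for land–atmosphere and ecohydrology
researchers who want to estimate θ_crit from flux-tower or satellite-style
records, map it with ensemble uncertainty, quantify annual water-stress
exposure and its multi-decadal trend, and attribute its spatial variation
to environmental drivers.

The core statistic is the continuous linear-plus-plateau regression

    y = a + b (SM − θ_crit)   if SM < θ_crit
    y = a                     if SM ≥ θ_crit

fitted to (SM, EF) or (SM, dLST) pairs pooled over dry-downs by profiling
the breakpoint (closed-form conditional least squares in (a, b), Brent
search over θ per inter-point interval), selected against intercept-only
and straight-line candidates by AIC = n log(RSS/n) + 2k, with a
delta-method (or bootstrap) standard error for θ_crit.

The pipeline around it:

- **Surface variables**: dLST from outgoing-longwave extremes via
  Stefan–Boltzmann inversion or from within-day LST samples; EF from
  turbulent fluxes with a 10 W/m² denominator floor; per-product SM bias
  correction.
- **Dry-downs**: ≥ 10-day strictly decreasing runs after rain in daily
  series; ≥ 5 (or 4) consecutive decreasing overpasses spanning ≥ 10 days
  in irregular series; tower analysis restricted to the peak-GPP
  three-month season.
- **Mapping**: per-pixel fits, 18-member ensembles (SM products × LST
  products × estimate ± SE variants) with per-pixel median and relative
  uncertainty, tower comparison via 3×3-window medians and Pearson r,
  model-output (EF-based) maps and difference maps.
- **Stress exposure**: annual fraction of stressed days (SM < θ_crit over
  observed days), per-product medians, Mann–Kendall/Sen trends with
  rank-based 95% intervals, FSD-bin regional series, land-cover-change
  masking.
- **Drivers**: recursive feature elimination around a random forest with
  an out-of-bag ΔR² ≥ 0.005 add-back rule and hyperparameter search,
  exactly locally-accurate permutation-sampling Shapley attributions,
  Kruskal–Wallis group tests, aridity (PET/P) classification.
- **Synthetic data**: seeded site/grid/feature-table generators with known
  ground truth (rain-pulse SM decay, plateau-curve responses, flux- and
  longwave-consistent records), so the whole pipeline is testable without
  downloads.

## Worked example

```r
library(thetacrit)

# a two-year synthetic site with a known threshold of 0.22 m3/m3
cfg  <- site_sim_config(theta_true = 0.22, seed = 101)
site <- simulate_site(cfg)

estimate_site_theta(site, response = "dlst")
#> <model selection> status: ok, n = 145
#>   AIC: constant 446.25, linear 188.14, piecewise 109.45
#>   winner: piecewise (theta = 0.2236 +/- 0.0046 m3/m3)

estimate_site_theta(site, response = "ef")
#> <model selection> status: ok, n = 145
#>   AIC: constant -601.52, linear -810.38, piecewise -850.64
#>   winner: piecewise (theta = 0.2216 +/- 0.0065 m3/m3)
```

145 (SM, response) pairs were pooled from the site's peak-growing-season
dry-downs; the linear-plus-plateau model beats both single-regime
candidates by a wide AIC margin, and both responses recover the
generative threshold (0.22) well within two standard errors of each
other.

```r
# gridded analysis: 4x4 pixels, covariate-linked thresholds
g   <- simulate_grid(grid_sim_config(n_lat = 4, n_lon = 4, years = 2,
                                     seed = 7))
map <- estimate_theta_map(g)
map
#> <theta_map> 4 x 4 pixels, 16 defined
#>   theta: median 0.211, range [0.117, 0.307] m3/m3

ens <- build_ensemble(theta_variant_maps(map), min_members = 2)
median(ens$rel_uncertainty, na.rm = TRUE)
#> [1] 0.0074

# stress exposure against the fitted threshold, and a trend
fsd_annual(site$date, site$sm, theta = 0.2236)
#>  2015  2016
#> 0.792 0.655

mann_kendall_sen(c(0.31, 0.35, 0.33, 0.38, 0.36, 0.41, 0.44, 0.42,
                   0.47, 0.49))
#> <trend> Sen slope 0.02 [0.015, 0.026], MK S = 39, p = 0.000677 (n = 10)
```

The map reproduces the covariate-driven threshold field (wetter pixels
have higher thresholds), the variant ensemble's relative uncertainty is
under 1% at this noise level, and the ten-year FSD series shows a
significant upward Sen slope of 0.02/yr with its 95% interval.

See `vignettes/thetacrit-methods.Rmd` for the model, its assumptions,
parameter defaults, and what the synthetic testbed does and does not
demonstrate.

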