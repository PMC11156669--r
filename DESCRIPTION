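Package: thetacrit
Title: Critical Soil Moisture Thresholds of Plant Water Stress from
    Dry-Down Breakpoint Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the critical surface soil moisture threshold at
    which evapotranspiration becomes water limited, from dry-down
    episodes in flux-tower and satellite records.  Provides derivation
    of the evaporative fraction and the diurnal land-surface-temperature
    amplitude from turbulent fluxes and outgoing longwave radiation,
    detection of soil-moisture dry-downs in daily and irregular overpass
    series, linear-plus-plateau breakpoint regression with AIC model
    selection and breakpoint standard errors, per-pixel threshold mapping
    with ensemble medians and relative uncertainty, annual
    fraction-of-stressed-days series with Mann-Kendall/Sen trend
    statistics, and a recursive-feature-elimination random-forest driver
    analysis with Shapley-value dependence.  A synthetic-data module
    generates site and gridded inputs with known ground truth so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
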