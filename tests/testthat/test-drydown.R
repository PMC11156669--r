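# Builds small daily series by hand: a rain day lifts SM, then SM declines
# by a fixed step per day.
make_series <- function(sm, precip = rep(0, length(sm)),
                        start = as.Date("2018-05-01")) {
  data.frame(date = start + seq_along(sm) - 1, sm = sm, precip = precip)
}

test_that("a rain-gated 12-day decline yields exactly one segment", {
  sm <- c(0.15, 0.30, 0.30 - 0.01 * (1:12))
  precip <- c(0, 5, rep(0, 12))
  seg <- detect_drydowns_daily(make_series(sm, precip))
  expect_equal(nrow(seg), 1)
  expect_equal(seg$span_days, 12)
  expect_equal(seg$start_idx, 2)
  expect_equal(seg$end_idx, 14)
})

test_that("a 9-day decline stays below the 10-day rule", {
  sm <- c(0.15, 0.30, 0.30 - 0.01 * (1:9))
  precip <- c(0, 5, rep(0, 9))
  expect_equal(nrow(detect_drydowns_daily(make_series(sm, precip))), 0)
})

test_that("two rain-separated declines match the exhaustive run scan", {
  sm <- c(0.10, 0.32, 0.32 - 0.01 * (1:11),   # 11-day decline
          0.40, 0.40 - 0.008 * (1:14))        # 14-day decline
  precip <- rep(0, length(sm)); precip[c(2, 14)] <- c(6, 9)
  ser <- make_series(sm, precip)
  seg <- detect_drydowns_daily(ser)
  runs <- brute_decreasing_runs(sm)
  long <- Filter(function(r) (r["end"] - r["start"]) >= 10, runs)
  expect_equal(nrow(seg), length(long))
  expect_equal(seg$start_idx, vapply(long, `[[`, numeric(1), "start"))
  expect_equal(seg$end_idx, vapply(long, `[[`, numeric(1), "end"))
  expect_equal(seg$span_days, c(11, 14))
})

test_that("the rain gate blocks declines that do not follow rain", {
  sm <- c(0.32, 0.32 - 0.01 * (1:12))
  ser <- make_series(sm)           # no precip, no prior SM rise
  expect_equal(nrow(detect_drydowns_daily(ser)), 0)
  # an SM rise of >= 0.005 substitutes for rain when precip is absent
  sm2 <- c(0.25, 0.32, 0.32 - 0.01 * (1:12))
  ser2 <- make_series(sm2)
  ser2$precip <- NULL
  expect_equal(nrow(detect_drydowns_daily(ser2)), 1)
})

test_that("exact SM ties break a run", {
  sm <- c(0.1, 0.35, 0.35 - 0.01 * (1:6), rep(0.29 - 0.06, 2),
          0.23 - 0.01 * (1:6))
  precip <- rep(0, length(sm)); precip[2] <- 4
  expect_equal(nrow(detect_drydowns_daily(make_series(sm, precip))), 0)
})

test_that("a weaker minimum-day rule detects a superset of segments", {
  s <- simulate_site(site_sim_config(seed = 31))
  seg9 <- detect_drydowns_daily(s, min_days = 9)
  seg10 <- detect_drydowns_daily(s, min_days = 10)
  seg11 <- detect_drydowns_daily(s, min_days = 11)
  expect_gte(nrow(seg9), nrow(seg10))
  expect_gte(nrow(seg10), nrow(seg11))
  expect_true(all(seg11$start_idx %in% seg9$start_idx))
})

test_that("detection is invariant to a constant SM offset", {
  s <- simulate_site(site_sim_config(seed = 17))
  a <- detect_drydowns_daily(s)
  s2 <- s; s2$sm <- s2$sm + 0.1
  b <- detect_drydowns_daily(s2)
  expect_equal(a[c("start_idx", "end_idx", "span_days")],
               b[c("start_idx", "end_idx", "span_days")])
})

test_that("overpass rule requires both the count and the 10-day span", {
  d5 <- as.Date("2016-07-01") + c(0, 3, 6, 9, 12)
  sm5 <- c(0.30, 0.27, 0.24, 0.20, 0.17)
  expect_equal(nrow(detect_drydowns_overpass(d5, sm5, min_obs = 5)), 1)
  d8 <- as.Date("2016-07-01") + c(0, 2, 4, 6, 8)
  expect_equal(nrow(detect_drydowns_overpass(d8, sm5, min_obs = 5)), 0)
  # the 4-overpass rule for the 2-4 day revisit product
  d4 <- as.Date("2016-07-01") + c(0, 4, 8, 11)
  sm4 <- c(0.28, 0.25, 0.21, 0.18)
  expect_equal(nrow(detect_drydowns_overpass(d4, sm4, min_obs = 4)), 1)
  expect_equal(nrow(detect_drydowns_overpass(d4, sm4, min_obs = 5)), 0)
})

test_that("overpass detection validates its date axis", {
  d <- as.Date("2016-07-01") + c(0, 3, 3, 9)
  expect_error(detect_drydowns_overpass(d, c(4, 3, 2, 1)), "duplicate")
})

test_that("peak growing season picks the GPP-maximizing 3-month window", {
  dates <- seq(as.Date("2014-01-01"), as.Date("2016-12-31"), by = "day")
  doy <- as.integer(format(dates, "%j"))
  north <- 5 + 4 * cos(2 * pi * (doy - 196) / 365)  # mid-July peak
  w <- peak_growing_season(dates, north)
  expect_equal(sort(w$months), c(6, 7, 8))
  # constant GPP: earliest window wins the tie
  w0 <- peak_growing_season(dates, rep(3, length(dates)))
  expect_equal(w0$start_month, 1)
  expect_equal(sort(w0$months), c(1, 2, 3))
  # southern-hemisphere January peak wraps around the year end;
  # cross-check against an exhaustive search over all 12 windows
  south <- 5 + 4 * cos(2 * pi * (doy - 15) / 365)
  ws <- peak_growing_season(dates, south)
  mo <- as.integer(format(dates, "%m"))
  means <- vapply(1:12, function(st) {
    mean(south[mo %in% (((st - 1):(st + 1)) %% 12 + 1)])
  }, numeric(1))
  expect_equal(ws$start_month, which.max(means))
  expect_equal(sort(ws$months), c(1, 2, 12))
  expect_error(peak_growing_season(dates, rep(NA_real_, length(dates))),
               "missing")
})

test_that("pooling concatenates segment pairs and drops missing responses", {
  sm <- c(0.1, 0.32, 0.32 - 0.01 * (1:11), 0.40, 0.40 - 0.008 * (1:14))
  precip <- rep(0, length(sm)); precip[c(2, 14)] <- c(6, 9)
  ser <- make_series(sm, precip)
  seg <- detect_drydowns_daily(ser)
  y <- seq_along(sm) * 0.01
  pooled <- pool_samples(seg, sm, y)
  expect_equal(nrow(pooled), sum(seg$n_obs))
  expect_equal(sort(unique(pooled$segment)), seq_len(nrow(seg)))
  # missing responses are dropped pair-wise
  y2 <- y; y2[seg$start_idx[1] + 0:2] <- NA
  expect_equal(nrow(pool_samples(seg, sm, y2)), sum(seg$n_obs) - 3)
  expect_equal(nrow(pool_samples(seg, sm, rep(NA_real_, length(sm)))), 0)
  # permutation invariance to segment order
  rev_seg <- seg[rev(seq_len(nrow(seg))), ]
  a <- pool_samples(seg, sm, y)
  b <- pool_samples(rev_seg, sm, y)
  expect_equal(sort(a$sm), sort(b$sm))
})
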