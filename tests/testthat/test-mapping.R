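small_grid <- function(noise = 0, seed = 2, n_lat = 2, n_lon = 2,
                       revisit = 1, years = 2) {
  simulate_grid(grid_sim_config(n_lat = n_lat, n_lon = n_lon,
                                years = years, revisit_days = revisit,
                                noise_sd_dlst = noise,
                                noise_sd_ef = ifelse(noise == 0, 0, 0.05),
                                seed = seed))
}

test_that("noise-free grids are mapped back to the true field", {
  g <- small_grid(noise = 0, seed = 2)
  m <- estimate_theta_map(g)
  expect_equal(m$theta, g$theta_true, tolerance = 1e-4)
  # thresholds lie inside each pixel's observed SM range
  expect_true(all(m$theta >= m$sm_lo & m$theta <= m$sm_hi, na.rm = TRUE))
})

test_that("noisy 8x8 grid recovery stays within 0.02 m3/m3 RMSE", {
  g <- simulate_grid(grid_sim_config(n_lat = 8, n_lon = 8, years = 2,
                                     revisit_days = 1, seed = 20))
  m <- estimate_theta_map(g)
  ok <- is.finite(m$theta)
  expect_gte(sum(ok), 48)  # most pixels defined
  rmse <- sqrt(mean((m$theta[ok] - g$theta_true[ok])^2))
  expect_lte(rmse, 0.02)
})

test_that("a pixel without dry-downs is reported missing", {
  g <- small_grid(noise = 0, seed = 3)
  g$sm[1, 1, ] <- seq(0.10, 0.40, length.out = dim(g$sm)[3])  # monotone rise
  m <- estimate_theta_map(g)
  expect_true(is.na(m$theta[1, 1]))
  expect_false(anyNA(m$theta[-1]))
})

test_that("model-output maps (daily EF rule) recover and average correctly", {
  g <- small_grid(noise = 0, seed = 4)
  m <- esm_theta_map(g)
  expect_equal(m$theta, g$theta_true, tolerance = 1e-3)
  # multi-model mean equals the pixel-wise average of member maps
  m2 <- m; m2$theta <- m2$theta + 0.02
  m3 <- m; m3$theta <- m3$theta - 0.01
  avg <- average_maps(list(m, m2, m3))
  expect_equal(avg$theta, (m$theta + m2$theta + m3$theta) / 3)
  # identical inputs difference to zero everywhere
  expect_true(all(difference_map(m, m) == 0, na.rm = TRUE))
})

test_that("difference maps propagate missingness and antisymmetry", {
  g <- small_grid(noise = 0, seed = 5)
  a <- estimate_theta_map(g)
  b <- a; b$theta <- b$theta * 1.1
  expect_equal(difference_map(a, b), -difference_map(b, a))
  b$theta[2, 1] <- NA
  expect_true(is.na(difference_map(a, b)[2, 1]))
  c_ <- a; c_$lat <- a$lat + 1
  expect_error(difference_map(a, c_), "different grids")
})

test_that("ensemble median and spread match direct recomputation", {
  g <- small_grid(noise = 1.0, seed = 6)
  base <- estimate_theta_map(g)
  maps <- lapply(c(0, 0.01, -0.01, 0.02, -0.02, 0.005), function(off) {
    m <- base; m$theta <- m$theta + off; m
  })
  ens <- build_ensemble(maps, min_members = 6)
  stack <- sapply(maps, function(m) as.vector(m$theta))
  med <- apply(stack, 1, median)
  se <- apply(stack, 1, sd) / sqrt(ncol(stack))
  expect_equal(as.vector(ens$median), med)
  expect_equal(as.vector(ens$rel_uncertainty), se / med)
})

test_that("identical members give zero relative uncertainty and the member value", {
  g <- small_grid(noise = 0, seed = 7)
  m <- estimate_theta_map(g)
  ens <- build_ensemble(rep(list(m), 6))
  expect_equal(ens$median, m$theta)
  expect_true(all(ens$rel_uncertainty == 0, na.rm = TRUE))
  # median of {0.1, 0.2, 0.3} style members
  maps <- lapply(c(0.1, 0.2, 0.3), function(v) {
    mm <- m; mm$theta[] <- v; mm
  })
  e3 <- build_ensemble(maps, min_members = 3)
  expect_true(all(e3$median == 0.2))
  expect_error(build_ensemble(list()), "at least one")
  expect_error(build_ensemble(list(m)), "at least 2")
})

test_that("ensemble median is order-invariant and bounded by members", {
  g <- small_grid(noise = 1.5, seed = 8)
  base <- estimate_theta_map(g)
  maps <- lapply(seq(-0.02, 0.03, length.out = 6), function(off) {
    m <- base; m$theta <- m$theta + off; m
  })
  e1 <- build_ensemble(maps)
  e2 <- build_ensemble(rev(maps))
  expect_equal(e1$median, e2$median)
  lo <- apply(sapply(maps, function(m) as.vector(m$theta)), 1, min)
  hi <- apply(sapply(maps, function(m) as.vector(m$theta)), 1, max)
  expect_true(all(as.vector(e1$median) >= lo - 1e-12, na.rm = TRUE))
  expect_true(all(as.vector(e1$median) <= hi + 1e-12, na.rm = TRUE))
})

test_that("variant maps bracket the estimate within the pixel SM range", {
  g <- small_grid(noise = 1.0, seed = 9)
  m <- estimate_theta_map(g)
  v <- theta_variant_maps(m)
  expect_true(all(v$lower$theta <= v$estimate$theta + 1e-12, na.rm = TRUE))
  expect_true(all(v$upper$theta >= v$estimate$theta - 1e-12, na.rm = TRUE))
  expect_true(all(v$upper$theta <= m$sm_hi + 1e-12, na.rm = TRUE))
  expect_equal(v$lower$provenance$variant, "lower")
})

test_that("ensemble relative uncertainty shrinks with response noise", {
  rel <- vapply(c(3.0, 1.5, 0.5), function(nl) {
    g <- small_grid(noise = nl, seed = 10, years = 2)
    m <- estimate_theta_map(g)
    v <- theta_variant_maps(m)
    ens <- build_ensemble(v, min_members = 2)
    median(ens$rel_uncertainty, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(rel) < 0))
})

test_that("tower comparison reproduces perfect and mirrored agreement", {
  g <- small_grid(noise = 0, seed = 11, n_lat = 3, n_lon = 3)
  m <- estimate_theta_map(g)
  towers <- data.frame(lat = rep(m$lat, each = 3), lon = rep(m$lon, 3),
                       theta = as.vector(t(g$theta_true)))
  # the map is built from the towers' own generative truth: r = 1
  cmp <- compare_to_towers(m, towers, window = 1)
  expect_equal(cmp$r, 1, tolerance = 1e-4)
  expect_lt(cmp$p, 0.01)
  # mirrored about the mean: r = -1
  towers$theta <- 2 * mean(towers$theta) - towers$theta
  expect_equal(compare_to_towers(m, towers, window = 1)$r, -1,
               tolerance = 1e-4)
  # closed-form Pearson on a 5-pair hand-checkable table
  t5 <- towers[1:5, ]
  got <- compare_to_towers(m, t5, window = 1)
  x <- t5$theta
  y <- vapply(1:5, function(i) {
    m$theta[which.min(abs(m$lat - t5$lat[i])),
            which.min(abs(m$lon - t5$lon[i]))]
  }, numeric(1))
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$r, r_manual, tolerance = 1e-12)
  # under 3 defined pairs: undefined-correlation signal
  expect_equal(compare_to_towers(m, towers[1:2, ])$status, "undefined")
})

test_that("maps survive the CSV round trip", {
  g <- small_grid(noise = 0.5, seed = 12)
  m <- estimate_theta_map(g)
  path <- withr::local_tempfile(fileext = ".csv")
  write_theta_map_csv(m, path)
  back <- read_theta_map_csv(path)
  expect_equal(back$theta, m$theta, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(back$lat, m$lat)
})
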