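# Shared fixtures and independent oracles used across the suite.

# Draw one (SM, response) sample from the linear-plus-plateau model.
make_plateau_sample <- function(n = 150, theta = 0.20, a = 0.6, b = 2.0,
                                sd = 0.05, sm_range = c(0.05, 0.45),
                                seed = 1) {
  set.seed(seed)
  sm <- runif(n, sm_range[1], sm_range[2])
  y <- plateau_response(sm, a, b, theta) + rnorm(n, 0, sd)
  list(sm = sm, y = y)
}

# Independent oracle: dense grid search for the breakpoint, solving the
# conditional least squares by QR (stats::lm.fit) rather than the package's
# closed-form normal equations.
grid_oracle_theta <- function(sm, y, n_grid = 1e4, min_side = 3,
                              edge_frac = 0.1) {
  span <- diff(range(sm))
  lo <- min(sm) + edge_frac * span
  hi <- max(sm) - edge_frac * span
  grid <- seq(lo, hi, length.out = n_grid)
  ok <- vapply(grid, function(t)
    sum(sm < t) >= min_side && sum(sm >= t) >= min_side, logical(1))
  grid <- grid[ok]
  rss <- vapply(grid, function(t) {
    u <- pmin(sm - t, 0)
    sum(stats::lm.fit(cbind(1, u), y)$residuals^2)
  }, numeric(1))
  list(theta = grid[which.min(rss)], rss = min(rss),
       step = diff(grid[1:2]))
}

# Independent oracle: exhaustive enumeration of maximal strictly
# decreasing runs in a vector (O(n^2) definition check).
brute_decreasing_runs <- function(sm, tol = 0) {
  n <- length(sm)
  runs <- list()
  i <- 1
  while (i < n) {
    j <- i
    while (j < n && is.finite(sm[j]) && is.finite(sm[j + 1]) &&
           (sm[j] - sm[j + 1]) > tol) j <- j + 1
    if (j > i) runs[[length(runs) + 1]] <- c(start = i, end = j)
    i <- max(j, i + 1)
  }
  runs
}

# Independent oracle: Sen's slope as the median over all pairwise slopes,
# enumerated with explicit loops.
brute_sen_slope <- function(x, t = seq_along(x)) {
  sl <- c()
  n <- length(x)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (t[j] != t[i]) sl <- c(sl, (x[j] - x[i]) / (t[j] - t[i]))
  median(sl)
}
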