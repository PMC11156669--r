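test_that("RFE keeps the informative driver and reports a sane OOB R^2", {
  tab <- simulate_feature_table(n = 600, n_noise = 6, noise_sd = 0.02,
                                seed = 5)
  r <- rfe_select(tab, ntree = 200, seed = 5)
  expect_true("aridity" %in% r$selected)
  expect_gt(r$final_oob_r2, 0.5)
  expect_setequal(union(r$selected,
                        setdiff(r$elimination_order, r$selected)),
                  union(r$selected, r$elimination_order))
  # elimination order covers everything phase 1 dropped
  expect_equal(length(r$oob_r2_path),
               length(r$elimination_order))
})

test_that("RFE with min_keep covering all candidates is a no-op loop", {
  tab <- simulate_feature_table(n = 120, n_noise = 3, seed = 6)
  p <- ncol(tab) - 1
  r <- rfe_select(tab, min_keep = p, ntree = 100, seed = 2)
  expect_setequal(r$selected, setdiff(names(tab), "theta_crit"))
  expect_length(r$elimination_order, 0)
})

test_that("RFE rejects degenerate inputs", {
  tab <- simulate_feature_table(n = 120, n_noise = 3, seed = 7)
  tab$theta_crit <- 1
  expect_error(rfe_select(tab), "degenerate response")
  tab2 <- simulate_feature_table(n = 120, n_noise = 0, seed = 7)
  expect_error(rfe_select(tab2, ntree = 50), "at least 4")
})

test_that("an all-noise response yields near-zero explanatory power", {
  r2 <- vapply(1:3, function(seed) {
    tab <- simulate_feature_table(
      n = 300, informative = list(aridity = function(x) 0 * x),
      n_noise = 6, noise_sd = 0.02, seed = seed)
    rfe_select(tab, ntree = 150, seed = seed)$final_oob_r2
  }, numeric(1))
  expect_lt(mean(r2), 0.05)
})

test_that("hyperparameter search is reproducible and within ranges", {
  tab <- simulate_feature_table(n = 300, n_noise = 4, seed = 9)
  sel <- setdiff(names(tab), "theta_crit")
  t1 <- tune_forest(tab, sel, ntree_grid = c(50L, 250L), seed = 4)
  t2 <- tune_forest(tab, sel, ntree_grid = c(50L, 250L), seed = 4)
  expect_identical(t1$grid, t2$grid)
  expect_true(t1$mtry >= 2 && t1$mtry <= length(sel))
  expect_true(t1$ntree %in% c(50L, 250L))
  # the tuned configuration is at least as good as any evaluated default
  expect_gte(t1$oob_r2, max(t1$grid$oob_r2) - 1e-12)
  expect_error(tune_forest(tab, sel[1]), "at least 2")
})

test_that("Shapley attributions are exactly locally accurate", {
  tab <- simulate_feature_table(n = 200, n_noise = 2, noise_sd = 0.01,
                                seed = 10)
  X <- tab[setdiff(names(tab), "theta_crit")]
  set.seed(1)
  rf <- randomForest::randomForest(X, tab$theta_crit, ntree = 150)
  sh <- shap_values(rf, X[1:25, ], background = X[1:40, ], n_perm = 4,
                    seed = 2)
  recon <- sh$base + rowSums(sh$values)
  expect_equal(unname(recon), unname(sh$prediction[1:25]),
               tolerance = 1e-10)
})

test_that("Shapley dependence tracks a monotone driver and flags noise", {
  tab <- simulate_feature_table(
    n = 500, informative = list(aridity = function(x) 0.30 - 0.15 * x),
    n_noise = 2, noise_sd = 0.01, seed = 11)
  X <- tab[setdiff(names(tab), "theta_crit")]
  set.seed(3)
  rf <- randomForest::randomForest(X, tab$theta_crit, ntree = 200)
  idx <- seq(1, 500, by = 4)
  sh <- shap_values(rf, X[idx, ], background = X[1:50, ], n_perm = 6,
                    seed = 4)
  dep <- shap_dependence(sh, X[idx, ], "aridity", bins = 8)
  # binned SHAP means decrease with aridity (threshold falls as it dries)
  expect_lt(cor(dep$curve$x, dep$curve$shap), -0.9)
  expect_true(all(diff(dep$curve$shap) < 0.02))
  imp <- shap_importance(sh)
  expect_equal(names(which.max(imp)), "aridity")
  expect_lt(max(imp[c("noise1", "noise2")]), 0.1 * imp["aridity"])
  expect_error(shap_dependence(sh, X[idx, ], "absent"), "unknown feature")
})

test_that("Kruskal-Wallis matches the hand-computed rank statistic", {
  # 3 groups x 3 values, no ties: H by the rank-sum formula
  vals <- c(1, 2, 3, 10, 11, 12, 20, 21, 22)
  grp <- rep(c("a", "b", "c"), each = 3)
  n <- 9
  rk <- rank(vals)
  H_manual <- 12 / (n * (n + 1)) *
    sum(tapply(rk, grp, sum)^2 / 3) - 3 * (n + 1)
  got <- kruskal_wallis(vals, grp)
  expect_equal(got$H, H_manual, tolerance = 1e-12)
  expect_equal(got$df, 2)
  expect_lt(got$p, 0.05)
})

test_that("Kruskal-Wallis edge cases and invariances hold", {
  expect_equal(kruskal_wallis(rep(2, 8), rep(c("a", "b"), 4))$p, 1)
  two <- kruskal_wallis(c(1, 2, 3, 10, 11, 12),
                        rep(c("lo", "hi"), each = 3))
  expect_lt(two$p, 0.05)
  # invariance under strictly monotone transforms
  set.seed(5)
  v <- runif(30); g <- rep(c("a", "b", "c"), 10)
  expect_equal(kruskal_wallis(v, g)$H, kruskal_wallis(exp(5 * v), g)$H)
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "at least 2 groups")
})

test_that("aridity classification is half-open, monotone and order-free", {
  tab <- unep_aridity_classes()
  ai <- c(0.5, 1 / 0.65, 3, 10, 50)
  lab <- aridity_classify(ai, tab)
  expect_equal(as.character(lab),
               c("humid", "dry sub-humid", "semi-arid", "arid",
                 "hyperarid"))
  # boundary values land in the interval whose lower edge they touch
  expect_equal(as.character(aridity_classify(2, tab)), "semi-arid")
  # labels are monotone in the index
  expect_true(all(diff(as.integer(aridity_classify(sort(ai), tab))) >= 0))
  expect_equal(aridity_classify(rev(ai), tab), rev(lab))
  expect_error(aridity_classify(ai), "required")
})
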