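# Attribution of spatial threshold variation to climatic, biotic and
# edaphic covariates: recursive feature elimination around a random-forest
# learner with an out-of-bag R^2 add-back rule, hyperparameter search,
# permutation-sampling Shapley attributions, and nonparametric group
# comparisons.
#
# The forest learner itself is the standard randomForest implementation;
# the elimination loop, the add-back rule, the out-of-bag bookkeeping and
# the hyperparameter search are the bespoke procedure implemented here.

.oob_r2 <- function(rf, y) {
  pred <- rf$predicted
  ok <- is.finite(pred)
  1 - sum((y[ok] - pred[ok])^2) / sum((y[ok] - mean(y[ok]))^2)
}

.fit_rf <- function(table, predictors, response, ntree, mtry = NULL,
                    n_perm = 10L, seed = NULL, importance = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  p <- length(predictors)
  if (is.null(mtry)) mtry <- max(1L, floor(p / 3))
  randomForest::randomForest(
    x = table[, predictors, drop = FALSE], y = table[[response]],
    ntree = ntree, mtry = min(mtry, p), importance = importance,
    nPerm = n_perm)
}

.perm_importance <- function(rf) {
  # %IncMSE: permutation importance computed on out-of-bag samples
  imp <- randomForest::importance(rf, type = 1L, scale = FALSE)
  stats::setNames(imp[, 1L], rownames(imp))
}

#' Recursive feature elimination with an OOB add-back rule
#'
#' Phase 1 fits a random forest on all candidate covariates, ranks them by
#' out-of-bag permutation importance, drops the least important, and
#' repeats until `min_keep` covariates remain, storing the elimination
#' order.  Phase 2 adds the eliminated covariates back one at a time in
#' stored importance order (most recently eliminated first); a covariate
#' stays only if the out-of-bag R^2 improves by at least `delta_r2`.  The
#' covariate combination with the highest out-of-bag R^2 seen along the
#' add-back path is returned as the selection.
#'
#' @param table `data.frame` of covariates plus the response column.
#' @param response Response column name (default `"theta_crit"`).
#' @param min_keep Number of covariates phase 1 keeps (default 3).
#' @param delta_r2 Minimum OOB R^2 gain for an add-back to stick
#'   (default 0.005).
#' @param ntree Trees per forest (default 500).
#' @param n_perm Permutations per covariate for the importance (default
#'   10).
#' @param seed Integer seed governing every forest fit.
#' @return A list of class `rfe_result`: `elimination_order`, `selected`,
#'   `oob_r2_path` (phase-1 R^2 per step), `addback` (per-candidate
#'   decision table), `final_oob_r2`, `ntree`.
#' @export
rfe_select <- function(table, response = "theta_crit", min_keep = 3L,
                       delta_r2 = 0.005, ntree = 500L, n_perm = 10L,
                       seed = 1L) {
  stopifnot(response %in% names(table))
  y <- table[[response]]
  if (!is.numeric(y) || stats::var(y) == 0)
    stop("degenerate response: zero variance")
  predictors <- setdiff(names(table), response)
  keep <- vapply(predictors, function(p)
    is.numeric(table[[p]]) && stats::var(table[[p]]) > 0, logical(1))
  predictors <- predictors[keep]
  if (length(predictors) < 4L) stop("need at least 4 candidate covariates")
  if (nrow(table) < 50L) stop("need at least 50 rows")
  min_keep <- min(min_keep, length(predictors))

  current <- predictors
  eliminated <- character(0)
  r2_path <- numeric(0)
  step <- 0L
  while (length(current) > min_keep) {
    step <- step + 1L
    rf <- .fit_rf(table, current, response, ntree, n_perm = n_perm,
                  seed = seed + step)
    r2_path <- c(r2_path, .oob_r2(rf, y))
    imp <- .perm_importance(rf)[current]
    worst <- names(which.min(imp))
    eliminated <- c(eliminated, worst)
    current <- setdiff(current, worst)
  }
  rf0 <- .fit_rf(table, current, response, ntree, n_perm = n_perm,
                 seed = seed, importance = FALSE)
  r2_cur <- .oob_r2(rf0, y)
  best <- list(set = current, r2 = r2_cur)
  addback <- data.frame(feature = character(0), oob_r2 = numeric(0),
                        kept = logical(0))
  for (k in rev(seq_along(eliminated))) {
    cand <- c(current, eliminated[k])
    rf_k <- .fit_rf(table, cand, response, ntree, n_perm = n_perm,
                    seed = seed + 1000L + k, importance = FALSE)
    r2_new <- .oob_r2(rf_k, y)
    kept <- r2_new >= r2_cur + delta_r2
    addback <- rbind(addback,
                     data.frame(feature = eliminated[k], oob_r2 = r2_new,
                                kept = kept))
    if (kept) {
      current <- cand
      r2_cur <- r2_new
      if (r2_new > best$r2) best <- list(set = current, r2 = r2_new)
    }
  }
  structure(list(elimination_order = eliminated, selected = best$set,
                 oob_r2_path = r2_path, addback = addback,
                 final_oob_r2 = best$r2, ntree = ntree,
                 response = response),
            class = "rfe_result")
}

#' @export
print.rfe_result <- function(x, ...) {
  cat(sprintf("<RFE> selected %d covariates (OOB R^2 = %.3f):\n  %s\n",
              length(x$selected), x$final_oob_r2,
              paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' Random-forest hyperparameter search on out-of-bag R^2
#'
#' Coarse, seeded grid search over the number of covariates tried per
#' split (2 to the number of selected covariates) and the number of trees
#' (50 to 5000), maximizing out-of-bag R^2.
#'
#' @param table Covariate table with the response column.
#' @param selected Covariates to use (e.g. from [rfe_select()]).
#' @param response Response column name.
#' @param mtry_grid,ntree_grid Candidate values; defaults span the stated
#'   ranges coarsely.
#' @param seed Integer seed; results are reproducible given it.
#' @return List with `mtry`, `ntree`, `oob_r2`, and the full `grid` of
#'   evaluated configurations.
#' @export
tune_forest <- function(table, selected, response = "theta_crit",
                        mtry_grid = NULL, ntree_grid = c(50L, 250L, 1500L),
                        seed = 1L) {
  p <- length(selected)
  if (p < 2L) stop("need at least 2 selected covariates")
  if (is.null(mtry_grid))
    mtry_grid <- sort(unique(pmin(p, c(2L, max(2L, floor(p / 3)),
                                       max(2L, floor(p / 2)), p))))
  grid <- expand.grid(mtry = mtry_grid, ntree = ntree_grid)
  grid$oob_r2 <- NA_real_
  y <- table[[response]]
  for (i in seq_len(nrow(grid))) {
    rf <- .fit_rf(table, selected, response, ntree = grid$ntree[i],
                  mtry = grid$mtry[i], seed = seed + i,
                  importance = FALSE)
    grid$oob_r2[i] <- .oob_r2(rf, y)
  }
  b <- which.max(grid$oob_r2)
  list(mtry = grid$mtry[b], ntree = grid$ntree[b],
       oob_r2 = grid$oob_r2[b], grid = grid)
}

#' Shapley attributions by permutation sampling
#'
#' Estimates per-row, per-covariate Shapley values of a fitted regression
#' model with the permutation-sampling estimator: for each sampled
#' ordering of the covariates, the marginal change in the
#' background-averaged prediction as each covariate's value is switched
#' from the background to the explained row is credited to that covariate.
#' Because the contributions along one ordering telescope from the
#' background mean to the row's prediction, local accuracy (base value +
#' row attributions = model prediction) holds exactly for the averaged
#' estimate as well.
#'
#' @param model A fitted model with a `predict` method (e.g.
#'   `randomForest`).
#' @param X `data.frame` of rows to explain (covariate columns only).
#' @param background Background `data.frame` defining the reference
#'   distribution; defaults to (up to) 100 rows sampled from `X`.
#' @param n_perm Sampled covariate orderings per row (default 10).
#' @param seed Integer seed.
#' @return A list of class `shap_result`: `values` (matrix rows x
#'   covariates), `base` (background mean prediction), `prediction`
#'   (per-row model predictions).
#' @export
shap_values <- function(model, X, background = NULL, n_perm = 10L,
                        seed = 1L) {
  set.seed(seed)
  if (is.null(background)) {
    idx <- if (nrow(X) > 100L) sample.int(nrow(X), 100L) else seq_len(nrow(X))
    background <- X[idx, , drop = FALSE]
  }
  stopifnot(identical(names(background), names(X)))
  p <- ncol(X)
  nb <- nrow(background)
  perms <- lapply(seq_len(n_perm), function(i) sample.int(p))
  base <- mean(stats::predict(model, background))
  vals <- matrix(0, nrow(X), p, dimnames = list(NULL, names(X)))
  for (r in seq_len(nrow(X))) {
    contrib <- matrix(0, n_perm, p)
    # stack all stages of all orderings into one predict call
    stages <- vector("list", n_perm)
    for (q in seq_len(n_perm)) {
      ord <- perms[[q]]
      stage <- background
      blocks <- vector("list", p)
      for (s in seq_len(p)) {
        stage[[ord[s]]] <- rep(X[r, ord[s]], nb)
        blocks[[s]] <- stage
      }
      stages[[q]] <- do.call(rbind, blocks)
    }
    pred <- stats::predict(model, do.call(rbind, stages))
    pm <- colMeans(matrix(pred, nrow = nb))  # one mean per stage
    pm <- matrix(pm, nrow = p)               # stages x orderings
    for (q in seq_len(n_perm)) {
      ord <- perms[[q]]
      contrib[q, ord] <- diff(c(base, pm[, q]))
    }
    vals[r, ] <- colMeans(contrib)
  }
  structure(list(values = vals, base = base,
                 prediction = stats::predict(model, X)),
            class = "shap_result")
}

#' Shapley dependence of one covariate
#'
#' @param shap A `shap_result` from [shap_values()].
#' @param X The explained rows (same as passed to [shap_values()]).
#' @param feature Covariate name.
#' @param bins Number of equal-count bins for the binned-mean curve
#'   (default 10).
#' @return List with `points` (a `data.frame` `x`, `shap` sorted by `x`)
#'   and `curve` (binned means).
#' @export
shap_dependence <- function(shap, X, feature, bins = 10L) {
  stopifnot(inherits(shap, "shap_result"))
  if (!feature %in% colnames(shap$values))
    stop(sprintf("unknown feature '%s'", feature))
  d <- data.frame(x = X[[feature]], shap = shap$values[, feature])
  d <- d[order(d$x), ]
  grp <- cut(seq_len(nrow(d)), breaks = bins, labels = FALSE)
  curve <- data.frame(
    x = tapply(d$x, grp, mean),
    shap = tapply(d$shap, grp, mean))
  list(points = d, curve = curve)
}

#' Mean absolute Shapley value per covariate
#'
#' @param shap A `shap_result`.
#' @return Named numeric vector, usable as a global importance measure.
#' @export
shap_importance <- function(shap) {
  stopifnot(inherits(shap, "shap_result"))
  colMeans(abs(shap$values))
}

#' Kruskal-Wallis comparison of threshold groups
#'
#' Rank-based nonparametric test of differences between groups (biomes,
#' climate classes, crop types, ...), with the convention that a fully
#' tied sample yields H = 0 and p = 1.
#'
#' @param values Numeric values.
#' @param groups Group labels, same length.
#' @return List with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("each group needs at least 2 values")
  if (stats::var(values) == 0)
    return(list(H = 0, df = nlevels(groups) - 1L, p = 1))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Classify pixels by aridity index
#'
#' Assigns aridity classes from a threshold table over the aridity index
#' (potential evapotranspiration over precipitation; higher = drier),
#' using half-open intervals `[lower, upper)` so boundary values go to the
#' lower interval.
#'
#' @param ai Aridity-index values (PET/P).
#' @param class_table `data.frame` with columns `label`, `lower`, `upper`
#'   (required; see [unep_aridity_classes()] for a standard table).
#' @return Factor of labels, ordered as in the table; `NA` outside all
#'   intervals.
#' @export
aridity_classify <- function(ai, class_table) {
  if (missing(class_table) || is.null(class_table))
    stop("class_table is required configuration")
  stopifnot(all(c("label", "lower", "upper") %in% names(class_table)))
  lab <- rep(NA_character_, length(ai))
  for (i in seq_len(nrow(class_table))) {
    hit <- is.finite(ai) & ai >= class_table$lower[i] &
      ai < class_table$upper[i]
    lab[hit] <- as.character(class_table$label[i])
  }
  factor(lab, levels = as.character(class_table$label))
}

#' Standard five-class aridity table on the PET/P convention
#'
#' The conventional United Nations Environment Programme class boundaries
#' (defined on P/PET) converted to the package's PET/P convention:
#' humid < 1/0.65, dry sub-humid to 1/0.5, semi-arid to 1/0.2, arid to
#' 1/0.05, hyperarid above.
#'
#' @return A `data.frame` with `label`, `lower`, `upper`.
#' @export
unep_aridity_classes <- function() {
  data.frame(
    label = c("humid", "dry sub-humid", "semi-arid", "arid", "hyperarid"),
    lower = c(0, 1 / 0.65, 1 / 0.5, 1 / 0.2, 1 / 0.05),
    upper = c(1 / 0.65, 1 / 0.5, 1 / 0.2, 1 / 0.05, Inf))
}
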