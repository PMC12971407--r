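# Driver attribution: gradient-boosted tree regression of EHI / HAI / D
# on unit-level covariates with grid-search cross-validation, R2/RMSE/MAE
# evaluation, TreeSHAP attribution with importance shares, and extraction
# of nonlinear thresholds from SHAP dependence profiles.

#' Assemble a train/test design matrix
#'
#' Units with any missing feature or target are dropped (and counted);
#' the remainder get a seeded random 70/30 (by default) split.
#'
#' @param units Tibble with one row per unit.
#' @param features Feature column names.
#' @param target Target column name.
#' @param test_fraction Fraction held out (default 0.3).
#' @param seed Integer seed.
#' @return List of class `driver_matrix`: `X` (matrix), `y`, `split`
#'   (`"train"`/`"test"`), `features`, `target`, `n_dropped`, `seed`.
#' @export
assemble_design <- function(units, features, target, test_fraction = 0.3,
                            seed = 1) {
  stopifnot(all(c(features, target) %in% names(units)))
  cols <- units[c(features, target)]
  ok <- complete.cases(cols) &
    apply(as.matrix(cols), 1, function(r) all(is.finite(r)))
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message(n_dropped, " unit(s) dropped for missing features")
  kept <- cols[ok, ]
  n <- nrow(kept)
  if (n < 30)
    stop("fewer than 30 complete units; cannot fit drivers", call. = FALSE)
  set.seed(seed)
  n_test <- round(test_fraction * n)
  test_idx <- sample.int(n, n_test)
  split <- rep("train", n)
  split[test_idx] <- "test"
  structure(list(X = as.matrix(kept[features]),
                 y = kept[[target]],
                 split = split, features = features, target = target,
                 n_dropped = n_dropped, seed = seed),
            class = "driver_matrix")
}

#' Regression accuracy metrics
#'
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - ybar)^2)`, RMSE, MAE.
#'
#' @param y Observed values (length >= 2, non-constant).
#' @param yhat Predictions.
#' @return Named list `r2`, `rmse`, `mae`.
#' @export
eval_metrics <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot <= 0)
    stop("constant target: R-squared is undefined", call. = FALSE)
  list(r2 = 1 - sum((y - yhat)^2) / ss_tot,
       rmse = sqrt(mean((y - yhat)^2)),
       mae = mean(abs(y - yhat)))
}

#' Default hyperparameter grid
#' @return Data frame of depth / learning-rate / tree-count / L2 combos.
#' @export
default_param_grid <- function() {
  expand.grid(max_depth = c(3, 5), eta = c(0.05, 0.1),
              nrounds = c(200, 500), lambda = c(1, 5))
}

#' Fit a gradient-boosted tree regression with grid-search CV
#'
#' Every grid point is scored by mean cross-validated RMSE on the
#' training units; the best configuration is refit on the full training
#' set and evaluated on train and test.
#'
#' @param dm A `driver_matrix` from [assemble_design()].
#' @param param_grid Data frame with columns `max_depth`, `eta`,
#'   `nrounds`, `lambda`.
#' @param cv_folds Number of CV folds (default 5).
#' @param seed Integer seed (fold assignment and fitting).
#' @return List of class `gbt_fit`: `model` (xgb.Booster), `best_params`,
#'   `cv_table`, `report` (train/test r2, rmse, mae), `dm`.
#' @export
fit_gbt <- function(dm, param_grid = default_param_grid(), cv_folds = 5,
                    seed = 1) {
  stopifnot(inherits(dm, "driver_matrix"), nrow(param_grid) >= 1)
  if (var(dm$y) <= 0)
    stop("constant target: cannot fit", call. = FALSE)
  tr <- dm$split == "train"
  dtrain <- xgboost::xgb.DMatrix(dm$X[tr, , drop = FALSE],
                                 label = dm$y[tr])
  cv_rmse <- numeric(nrow(param_grid))
  for (k in seq_len(nrow(param_grid))) {
    g <- param_grid[k, ]
    set.seed(seed)
    cv <- xgboost::xgb.cv(
      params = list(max_depth = g$max_depth, eta = g$eta,
                    lambda = g$lambda, objective = "reg:squarederror",
                    nthread = 1),
      data = dtrain, nrounds = g$nrounds, nfold = cv_folds,
      metrics = "rmse", verbose = 0)
    log <- cv$evaluation_log
    cv_rmse[k] <- log$test_rmse_mean[nrow(log)]
  }
  best <- param_grid[which.min(cv_rmse), ]
  set.seed(seed)
  model <- xgboost::xgb.train(
    params = list(max_depth = best$max_depth, eta = best$eta,
                  lambda = best$lambda, objective = "reg:squarederror",
                  nthread = 1),
    data = dtrain, nrounds = best$nrounds, verbose = 0)
  pred_tr <- predict(model, dm$X[tr, , drop = FALSE])
  te <- !tr
  report <- list(train = eval_metrics(dm$y[tr], pred_tr))
  if (any(te)) {
    pred_te <- predict(model, dm$X[te, , drop = FALSE])
    report$test <- eval_metrics(dm$y[te], pred_te)
  }
  structure(list(model = model, best_params = as.list(best),
                 cv_table = cbind(param_grid, cv_rmse = cv_rmse),
                 report = report, dm = dm),
            class = "gbt_fit")
}

#' Shapley attribution of a fitted tree ensemble
#'
#' Exact tree-path Shapley values (TreeSHAP): per unit, the base value
#' plus the per-feature contributions reproduce the model prediction
#' (local accuracy). Importance shares are `mean |phi_j|` as a
#' percentage of the total.
#'
#' @param fit A `gbt_fit` (or bare `xgb.Booster` with `X` supplied).
#' @param X Matrix of units x features to attribute (default: the fit's
#'   full design).
#' @return List of class `shap_result`: `phi` (units x features),
#'   `base_value`, `prediction`, `importance_share` (named, sums to 100),
#'   `X`.
#' @export
shap_attribution <- function(fit, X = NULL) {
  model <- if (inherits(fit, "gbt_fit")) fit$model else fit
  if (is.null(X)) {
    stopifnot(inherits(fit, "gbt_fit"))
    X <- fit$dm$X
  }
  contrib <- predict(model, X, predcontrib = TRUE)
  base <- contrib[, ncol(contrib)]
  phi <- contrib[, -ncol(contrib), drop = FALSE]
  colnames(phi) <- colnames(X)
  imp <- colMeans(abs(phi))
  share <- 100 * imp / sum(imp)
  structure(list(phi = phi, base_value = base,
                 prediction = base + rowSums(phi),
                 importance_share = share, X = X),
            class = "shap_result")
}

rolling_median <- function(x, window) {
  n <- length(x)
  half <- floor(window / 2)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    median(x[lo:hi])
  }, numeric(1))
}

find_crossings <- function(xs, phis) {
  sgn <- sign(phis)
  nz <- which(sgn != 0)
  if (length(nz) < 2) return(NULL)
  ch <- which(diff(sgn[nz]) != 0)
  if (!length(ch)) return(NULL)
  data.frame(
    breakpoint = (xs[nz[ch]] + xs[nz[ch + 1]]) / 2,
    direction = ifelse(sgn[nz[ch]] > 0, "+ -> -", "- -> +")
  )
}

#' Nonlinear threshold from a SHAP dependence profile
#'
#' Sorts the (feature value, SHAP value) pairs, smooths the SHAP series
#' with a rolling median, and reports the feature value at each sign
#' change of the smoothed series (first crossing is primary). A bootstrap
#' over units gives an interval for the first crossing. A monotone-signed
#' profile yields a "no threshold" result.
#'
#' @param shap A `shap_result`.
#' @param feature Feature name.
#' @param smoothing_window Rolling-median window in observations
#'   (default: max(11, n/50)).
#' @param n_boot Bootstrap replicates (default 200).
#' @param seed Integer seed.
#' @return List of class `threshold_report`: `feature`, `threshold`,
#'   `direction`, `all_crossings`, `ci` (2.5/97.5% bootstrap),
#'   `smoothing_window`, `n_boot`, `seed`.
#' @export
dependence_threshold <- function(shap, feature, smoothing_window = NULL,
                                 n_boot = 200, seed = 1) {
  stopifnot(inherits(shap, "shap_result"),
            feature %in% colnames(shap$phi))
  xv <- shap$X[, feature]
  if (length(unique(xv)) < 50)
    stop("feature has fewer than 50 distinct values", call. = FALSE)
  phi <- shap$phi[, feature]
  n <- length(xv)
  if (is.null(smoothing_window))
    smoothing_window <- max(11, round(n / 50))
  one_pass <- function(x, p) {
    o <- order(x)
    find_crossings(x[o], rolling_median(p[o], smoothing_window))
  }
  cr <- one_pass(xv, phi)
  if (is.null(cr)) {
    return(structure(list(feature = feature, threshold = NA_real_,
                          direction = "no threshold",
                          all_crossings = NULL, ci = c(NA, NA),
                          smoothing_window = smoothing_window,
                          n_boot = n_boot, seed = seed),
                     class = "threshold_report"))
  }
  set.seed(seed)
  boot <- replicate(n_boot, {
    idx <- sample.int(n, n, replace = TRUE)
    b <- one_pass(xv[idx], phi[idx])
    if (is.null(b)) NA_real_ else b$breakpoint[1]
  })
  ci <- quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(list(feature = feature, threshold = cr$breakpoint[1],
                 direction = cr$direction[1], all_crossings = cr,
                 ci = ci, smoothing_window = smoothing_window,
                 n_boot = n_boot, seed = seed),
            class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  if (is.na(x$threshold)) {
    cat(sprintf("%s: no threshold (SHAP profile does not change sign)\n",
                x$feature))
  } else {
    cat(sprintf("%s: threshold %.4g (%s), 95%% bootstrap CI [%.4g, %.4g]\n",
                x$feature, x$threshold, x$direction, x$ci[1], x$ci[2]))
  }
  invisible(x)
}
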