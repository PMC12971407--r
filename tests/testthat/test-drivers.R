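make_units <- function(n = 200, seed = 1) {
  set.seed(seed)
  tibble::tibble(unit_id = seq_len(n),
                 x1 = runif(n, 0, 10),
                 x2 = rnorm(n),
                 y = NA_real_)
}

test_that("design assembly splits deterministically and drops incomplete units", {
  u <- make_units(100)
  u$y <- u$x1 + u$x2
  dm <- assemble_design(u, c("x1", "x2"), "y", seed = 5)
  expect_equal(sum(dm$split == "train"), 70)
  expect_equal(sum(dm$split == "test"), 30)
  dm2 <- assemble_design(u, c("x1", "x2"), "y", seed = 5)
  expect_identical(dm$split, dm2$split)

  u$x2[c(3, 14)] <- NA
  expect_message(dm3 <- assemble_design(u, c("x1", "x2"), "y", seed = 5),
                 "2 unit")
  expect_equal(nrow(dm3$X), 98)
  expect_equal(dm3$n_dropped, 2)

  expect_error(assemble_design(u[1:20, ], c("x1", "x2"), "y"),
               "fewer than 30")
})

test_that("accuracy metrics match hand evaluation", {
  y <- c(0, 1, 2); yhat <- c(0, 1, 4)
  m <- eval_metrics(y, yhat)
  expect_equal(m$r2, -1)
  expect_equal(m$rmse, sqrt(4 / 3))
  expect_equal(m$mae, 2 / 3)

  mp <- eval_metrics(y, y)
  expect_equal(unlist(mp), c(r2 = 1, rmse = 0, mae = 0))
  expect_equal(eval_metrics(y, rep(mean(y), 3))$r2, 0)
  expect_error(eval_metrics(rep(1, 5), rnorm(5)), "constant")

  set.seed(6)
  for (s in 1:5) {
    yy <- rnorm(50); hh <- yy + rnorm(50, sd = 0.3)
    m <- eval_metrics(yy, hh)
    expect_equal(m$r2, 1 - sum((yy - hh)^2) / sum((yy - mean(yy))^2),
                 tolerance = 1e-12)
    expect_lte(m$mae, m$rmse)
  }
})

small_grid <- expand.grid(max_depth = 3, eta = 0.3, nrounds = 60,
                          lambda = 1)

test_that("boosted trees recover a noiseless signal and not pure noise", {
  u <- make_units(300, seed = 7)
  u$y <- sin(u$x1) + 0.5 * u$x1
  fit <- fit_gbt(assemble_design(u, c("x1", "x2"), "y", seed = 1),
                 param_grid = small_grid, cv_folds = 3, seed = 1)
  expect_gt(fit$report$test$r2, 0.95)
  expect_lte(fit$report$test$mae, fit$report$test$rmse)

  # grid search picks the configuration with the lowest CV RMSE
  grid2 <- expand.grid(max_depth = c(1, 3), eta = 0.3, nrounds = c(10, 60),
                       lambda = 1)
  fit2 <- fit_gbt(assemble_design(u, c("x1", "x2"), "y", seed = 1),
                  param_grid = grid2, cv_folds = 3, seed = 1)
  expect_equal(which.min(fit2$cv_table$cv_rmse),
               which(fit2$cv_table$max_depth == fit2$best_params$max_depth &
                     fit2$cv_table$nrounds == fit2$best_params$nrounds))

  # pure-noise target: test R2 stays near zero
  r2s <- vapply(1:5, function(s) {
    un <- make_units(200, seed = 100 + s)
    set.seed(200 + s); un$y <- rnorm(200)
    fit_gbt(assemble_design(un, c("x1", "x2"), "y", seed = s),
            param_grid = small_grid, cv_folds = 3,
            seed = s)$report$test$r2
  }, numeric(1))
  expect_gte(sum(r2s < 0.2), 4)

  uc <- make_units(50); uc$y <- 1
  expect_error(fit_gbt(assemble_design(uc, c("x1", "x2"), "y")),
               "constant")
})

test_that("TreeSHAP attributions satisfy local accuracy and share bookkeeping", {
  u <- make_units(300, seed = 8)
  u$y <- u$x1^2 + 3 * u$x2
  fit <- fit_gbt(assemble_design(u, c("x1", "x2"), "y", seed = 2),
                 param_grid = small_grid, cv_folds = 3, seed = 2)
  sh <- shap_attribution(fit)
  expect_equal(sh$prediction,
               as.numeric(predict(fit$model, fit$dm$X)),
               tolerance = 1e-6)
  expect_equal(sum(sh$importance_share), 100, tolerance = 1e-9)

  # single informative feature on a flat co-feature: ~all share on x1
  u2 <- make_units(300, seed = 9)
  u2$x2 <- 0
  u2$y <- 2 * u2$x1
  fit2 <- fit_gbt(assemble_design(u2, c("x1", "x2"), "y", seed = 2),
                  param_grid = small_grid, cv_folds = 3, seed = 2)
  sh2 <- shap_attribution(fit2)
  expect_equal(unname(sh2$importance_share[["x1"]]), 100,
               tolerance = 1e-6)
})

test_that("depth-1 ensemble Shapley values match exhaustive enumeration", {
  u <- make_units(400, seed = 10)
  u$y <- 2 * u$x1 - 3 * u$x2          # additive, separable
  dm <- assemble_design(u, c("x1", "x2"), "y", test_fraction = 0,
                        seed = 3)
  fit <- fit_gbt(dm, param_grid = expand.grid(max_depth = 1, eta = 0.3,
                                              nrounds = 40, lambda = 0),
                 cv_folds = 3, seed = 3)
  trees <- extract_depth1_trees(fit$model)
  sh <- shap_attribution(fit)
  for (i in c(1, 50, 200)) {
    x <- setNames(as.numeric(dm$X[i, ]), colnames(dm$X))
    phi <- oracle_shapley_depth1(trees, x, c("x1", "x2"))
    expect_equal(unname(sh$phi[i, ]), unname(phi[colnames(sh$phi)]),
                 tolerance = 1e-4, label = sprintf("unit %d", i))
  }
})

test_that("dependence thresholds find planted sign changes and only those", {
  set.seed(11)
  n <- 1000
  x <- runif(n, 0, 100)
  phi <- ifelse(x < 60, 1, -1) * (0.2 + abs(x - 60) / 100) +
    rnorm(n, sd = 0.05)
  sh <- structure(list(phi = matrix(phi, ncol = 1,
                                    dimnames = list(NULL, "pet")),
                       X = matrix(x, ncol = 1,
                                  dimnames = list(NULL, "pet")),
                       base_value = rep(0, n),
                       prediction = phi,
                       importance_share = c(pet = 100)),
                  class = "shap_result")
  tr <- dependence_threshold(sh, "pet", n_boot = 50, seed = 4)
  expect_lt(abs(tr$threshold - 60), 10)
  expect_equal(tr$direction, "+ -> -")
  expect_true(tr$ci[1] <= tr$threshold & tr$threshold <= tr$ci[2])

  tr2 <- dependence_threshold(sh, "pet", n_boot = 50, seed = 4)
  expect_identical(tr$ci, tr2$ci)      # seeded bootstrap

  # strictly positive profile: no threshold, and that is not an error
  shp <- sh
  shp$phi[, 1] <- 0.5 + x / 200
  trp <- dependence_threshold(shp, "pet", n_boot = 20, seed = 4)
  expect_true(is.na(trp$threshold))
  expect_equal(trp$direction, "no threshold")

  expect_error(dependence_threshold(sh, "absent"))
})
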