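test_that("discovery/holdout splits are disjoint, exhaustive, reproducible", {
  sp <- split_discovery_holdout(399, 0.5, seed = 1)
  expect_length(sp$discovery, 199)
  expect_length(sp$holdout, 200)
  expect_identical(sort(c(sp$discovery, sp$holdout)), 1:399)
  expect_identical(sp, split_discovery_holdout(399, 0.5, seed = 1))
  expect_false(identical(sp, split_discovery_holdout(399, 0.5, seed = 2)))
  expect_error(split_discovery_holdout(5), "n >= 8")
  expect_error(split_discovery_holdout(100, 1.2), "fraction")
})

test_that("evaluate_predictions implements the variance-explained formula", {
  y <- c(1, 2, 3)
  expect_equal(evaluate_predictions(y, y)$r_squared, 1)
  expect_equal(evaluate_predictions(y, y)$pearson_r, 1)
  expect_equal(evaluate_predictions(y, rep(2, 3))$r_squared, 0)
  expect_true(is.nan(evaluate_predictions(y, rep(2, 3))$pearson_r))
  # direct evaluation: 1 - 8/2 = -3
  expect_equal(evaluate_predictions(y, c(3, 2, 1))$r_squared, -3)

  # R2 equals squared pearson exactly when yhat is the LS affine fit of y
  set.seed(2)
  yy <- rnorm(25); xx <- rnorm(25)
  yhat <- fitted(lm(yy ~ xx))
  ev <- evaluate_predictions(yy, yhat)
  expect_equal(ev$r_squared, ev$pearson_r^2, tolerance = 1e-12)
  # ... and differs otherwise
  ev2 <- evaluate_predictions(yy, yhat + 0.5)
  expect_false(isTRUE(all.equal(ev2$r_squared, ev2$pearson_r^2)))
})

test_that("lasso-pcr at vanishing penalty matches the OLS oracle", {
  set.seed(3)
  n <- 300; p <- 100
  X <- matrix(rnorm(n * p), n)
  beta <- rnorm(p, 0, 0.2)
  y <- drop(X %*% beta) + rnorm(n)
  model <- fit_lasso_pcr(X, y, lambda_grid = c(1e-6, 1e-5), seed = 1,
                         nested = FALSE)
  pred <- predict(model, X)
  ols <- fitted(lm(y ~ X))
  expect_lt(sqrt(mean((pred - ols)^2)), 1e-3)
})

test_that("permuted labels give a null model", {
  set.seed(4)
  b <- tiny_cohort(n = 80, seed = 41)
  y <- b$participants$sensitivity
  r2s <- vapply(1:5, function(i) {
    yp <- sample(y)
    fit_lasso_pcr(b$maps$pain, yp, lambda_grid = lambda_grid_default(30),
                  seed = i, nested = FALSE)$cv$r_squared
  }, numeric(1))
  expect_lt(mean(r2s), 0.05)
})

test_that("fitting is deterministic given the seed and free of holdout leakage", {
  b <- tiny_cohort(n = 100, seed = 43)
  sp <- split_discovery_holdout(100, 0.6, seed = 9)
  X <- b$maps$pain
  y <- b$participants$sensitivity
  g <- lambda_grid_default(20)
  m1 <- fit_lasso_pcr(X[sp$discovery, ], y[sp$discovery], g, seed = 5)
  m2 <- fit_lasso_pcr(X[sp$discovery, ], y[sp$discovery], g, seed = 5)
  expect_identical(m1$cv$r_squared, m2$cv$r_squared)
  expect_identical(m1$voxel_weights, m2$voxel_weights)
  # perturbing holdout rows cannot touch discovery CV metrics
  X_perturbed <- X
  X_perturbed[sp$holdout, ] <- 0
  m3 <- fit_lasso_pcr(X_perturbed[sp$discovery, ], y[sp$discovery], g,
                      seed = 5)
  expect_identical(m1$cv$r_squared, m3$cv$r_squared)
})

test_that("back-projected voxel weights reproduce component predictions", {
  b <- tiny_cohort(n = 90, seed = 47)
  y <- b$participants$sensitivity
  for (nested in c(TRUE, FALSE)) {
    m <- fit_lasso_pcr(b$maps$pain, y, lambda_grid_default(20), seed = 2,
                       nested = nested)
    # orthonormal basis
    VtV <- crossprod(m$component_basis)
    expect_lt(max(abs(VtV - diag(ncol(VtV)))), 1e-8)
    expect_true(m$lambda %in% m$lambda_grid)
    # identity on fresh random maps
    set.seed(101)
    newX <- matrix(rnorm(50 * ncol(b$maps$pain)), 50)
    expect_lt(max(abs(predict(m, newX) -
                        (drop(newX %*% m$voxel_weights) +
                           m$weight_constant))), 1e-8)
  }
})

test_that("learning_curve echoes its grid, audits reps, and guards sizes", {
  b <- tiny_cohort(n = 80, seed = 53)
  y <- b$participants$sensitivity
  expect_error(learning_curve(b$maps$pain, y, sizes = c(20, 70), reps = 2),
               "0.8")
  expect_message(
    lc <- learning_curve(b$maps$pain, y, sizes = c(5, 20, 40), reps = 3,
                         lambda_grid = lambda_grid_default(15), seed = 2),
    "skipping")
  expect_identical(lc$sizes, c(20, 40))
  expect_identical(lc$n_reps, c(3L, 3L))
  expect_identical(dim(lc$r2), c(3L, 2L))
  expect_true(all(lc$sd_r2 >= 0))
})

test_that("covariate adjustment removes injected site effects", {
  set.seed(6)
  b <- tiny_cohort(n = 120, seed = 59,
                   confounds = list(dataset_shift = 2, sex_effect = 0,
                                    age_slope = 0))
  y <- b$participants$sensitivity
  covs <- b$participants[, c("dataset", "sex", "age")]
  m_adj <- covariate_adjusted_fit(b$maps$pain, y, covs,
                                  lambda_grid_default(20), seed = 3,
                                  nested = FALSE)
  expect_identical(m_adj$covariates, c("dataset", "sex", "age"))
  # rank-deficient covariates refused
  bad <- cbind(covs, dup = as.integer(factor(covs$dataset)))
  expect_error(covariate_adjusted_fit(b$maps$pain, y, bad,
                                      lambda_grid_default(5)),
               "rank-deficient")
  # covariates that generate (almost) all of y leave nothing to predict
  y_conf <- 3 * (b$participants$dataset == "dataset2") + rnorm(120, 0, 0.05)
  m0 <- covariate_adjusted_fit(b$maps$pain, y_conf,
                               covs, lambda_grid_default(10), seed = 4,
                               nested = FALSE)
  expect_lt(m0$cv$r_squared, 0.1)
})

test_that("behavior-only lasso shrinks, predicts, and imputes", {
  set.seed(7)
  n <- 150
  f1 <- rnorm(n)
  y <- 0.9 * f1 + rnorm(n, 0, 0.4)
  feats <- data.frame(f1 = f1, noise1 = rnorm(n), noise2 = rnorm(n))
  m <- fit_behavior_lasso(feats, y, seed = 1)
  uni <- summary(lm(y ~ f1))$r.squared
  expect_gt(m$cv$r_squared, uni - 0.15)

  # giant penalty: all coefficients zero, prediction = training mean
  mbig <- fit_behavior_lasso(feats, y, lambda_grid = c(1e3, 2e3), seed = 1)
  expect_equal(unname(predict(mbig, feats)), rep(mean(y), n),
               tolerance = 1e-8)

  # all-noise features carry nothing
  m0 <- fit_behavior_lasso(feats[, 2:3], rnorm(n), seed = 2)
  expect_lt(m0$cv$r_squared, 0.05)

  # NA features are median-imputed, not fatal
  feats_na <- feats; feats_na$f1[1:10] <- NA
  m_na <- fit_behavior_lasso(feats_na, y, seed = 3)
  expect_false(anyNA(predict(m_na, feats_na)))
  expect_error(fit_behavior_lasso(data.frame(), y), "features")
})

test_that("stacking degrades gracefully to its better block", {
  set.seed(8)
  b <- tiny_cohort(n = 100, seed = 61)
  y <- b$participants$sensitivity
  # behavior block is pure noise: stacked tracks the fMRI-only model
  noise_feats <- matrix(rnorm(100 * 3), 100)
  st <- fit_stacking(b$maps$pain, noise_feats, y, n_folds = 5, seed = 2)
  fmri_only <- fit_lasso_pcr(b$maps$pain, y, lambda_grid_default(10),
                             seed = 2, nested = FALSE)
  expect_gt(st$cv$r_squared, fmri_only$cv$r_squared - 0.15)

  # fMRI block zeroed (degenerate): stacked falls back to behavior block
  good_feats <- cbind(y + rnorm(100, 0, 0.5), rnorm(100))
  w <- capture_warnings(
    st0 <- fit_stacking(matrix(0, 100, 20), good_feats, y, seed = 3))
  expect_true(any(grepl("degenerate", w)))
  behav_only <- fit_behavior_lasso(good_feats, y,
                                   lambda_grid_default(10), seed = 3)
  expect_gt(st0$cv$r_squared, behav_only$cv$r_squared - 0.15)
  pr <- predict(st0, matrix(0, 10, 20), good_feats[1:10, ])
  expect_length(pr, 10)
})
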