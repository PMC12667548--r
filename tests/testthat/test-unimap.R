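test_that("voxelwise correlation matches direct oracles and flags edge cases", {
  y <- c(2, 1, 4, 3, 6, 5)
  X <- cbind(ident = y, anti = -y, hand = c(1, 2, 3, 4, 5, 6),
             const = rep(2, 6))
  sm <- voxelwise_correlation(X, y)
  expect_equal(sm$statistic[1], 1)
  expect_lt(sm$p[1], 1e-10)
  expect_equal(sm$statistic[2], -1)
  expect_equal(sm$statistic[3], oracle_pearson(X[, 3], y), tolerance = 1e-12)
  # constant voxel: NaN statistic, p = 1, excluded from the FDR family
  expect_true(is.nan(sm$statistic[4]))
  expect_identical(sm$p[4], 1)
  expect_true(is.na(sm$q[4]))
  expect_false(sm$sig_mask[4])

  expect_error(voxelwise_correlation(X[1:5, ], y), "differ")
  expect_error(voxelwise_correlation(X, rep(1, 6)), "constant")
  expect_error(voxelwise_correlation(X[1:3, ], y[1:3]), "n >= 4")
})

test_that("spearman is invariant to monotone transforms and agrees in sign", {
  set.seed(4)
  y <- rnorm(30)
  X <- cbind(a = y + rnorm(30, sd = 0.5), b = -y + rnorm(30, sd = 0.5))
  s1 <- voxelwise_correlation(X, y, method = "spearman")
  s2 <- voxelwise_correlation(X, exp(3 * y), method = "spearman")
  expect_identical(s1$statistic, s2$statistic)
  p1 <- voxelwise_correlation(X, y, method = "pearson")
  expect_identical(sign(s1$statistic), sign(p1$statistic))
})

test_that("fdr_bh reproduces hand-computed BH decisions", {
  # largest k with p_(k) <= 0.05 k / 5 is k = 5: all significant
  res <- fdr_bh(c(0.01, 0.02, 0.03, 0.04, 0.05), 0.05)
  expect_true(all(res$sig))
  expect_true(all(fdr_bh(rep(1, 8))$q == 1) && !any(fdr_bh(rep(1, 8))$sig))
  expect_true(fdr_bh(0.04, 0.05)$sig)        # m = 1 reduces to raw alpha
  expect_identical(fdr_bh(numeric(0))$sig, logical(0))

  set.seed(9)
  p <- runif(200)^2
  res <- fdr_bh(p, 0.05)
  expect_identical(res$sig, oracle_bh_sig(p, 0.05))
  expect_true(all(res$q >= p))
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("partial correlation reduces to plain correlation and matches OLS", {
  set.seed(5)
  X <- matrix(rnorm(40 * 6), 40)
  y <- rnorm(40)
  plain <- voxelwise_correlation(X, y)
  nocov <- partial_correlation_map(X, y, covariates = NULL)
  expect_equal(nocov$statistic, plain$statistic, tolerance = 1e-12)

  # constant-only covariate = intercept-only reduction
  const <- partial_correlation_map(X, y,
                                   covariates = data.frame(one = rep(1, 40)))
  expect_equal(const$statistic, plain$statistic, tolerance = 1e-12)

  # small-n brute-force residualization oracle
  covs <- data.frame(age = rnorm(8))
  X8 <- matrix(rnorm(8 * 3), 8); y8 <- rnorm(8)
  pm <- partial_correlation_map(X8, y8, covariates = covs)
  for (j in 1:3)
    expect_equal(pm$statistic[j], oracle_partial_r(X8[, j], y8, covs),
                 tolerance = 1e-10)

  # behavior fully explained by a covariate
  expect_error(partial_correlation_map(X8, 2 * covs$age + 1,
                                       covariates = covs),
               "explained by covariates")

  # dataset-wise standardization path runs and imputes missing covariates
  ds <- rep(c("d1", "d2"), each = 20)
  covs2 <- data.frame(dataset = ds, age = c(NA, rnorm(39)))
  out <- partial_correlation_map(X, y, covariates = covs2, dataset = ds)
  expect_false(anyNA(out$statistic))
})

test_that("ROI reductions behave like means", {
  set.seed(6)
  X <- matrix(rnorm(20 * 5), 20)
  expect_equal(roi_mean_signal(X, c(TRUE, rep(FALSE, 4))), X[, 1])
  Xc <- matrix(3.5, 4, 4)
  expect_equal(roi_mean_signal(Xc, rep(TRUE, 4)), rep(3.5, 4))
  m3 <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  expect_equal(roi_mean_signal(X, m3), (X[, 1] + X[, 2] + X[, 3]) / 3)
  expect_error(roi_mean_signal(X, rep(FALSE, 5)), "empty ROI")

  y <- X[, 1] + rnorm(20, sd = 0.1)
  rc <- roi_correlation(X, y, m3)
  expect_equal(rc$r, cor(roi_mean_signal(X, m3), y), tolerance = 1e-12)
})

test_that("dice and conjunction follow their definitions", {
  a <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  b <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, !a), 0)
  expect_equal(dice(a, b), 2 * 2 / 6)        # |A|=3, |B|=3, overlap 2
  expect_identical(dice(a, b), dice(b, a))
  expect_warning(d0 <- dice(logical(3), logical(3)), "empty")
  expect_true(is.nan(d0))
  expect_error(dice(a, b[1:3]), "lengths differ")

  expect_identical(conjunction(a, a), a)
  expect_identical(conjunction(a, !a), rep(FALSE, 5))
  sub <- a & b
  expect_identical(conjunction(sub, b), sub)  # A subset of B gives A
})

test_that("steiger_z matches the formula oracle and its symmetries", {
  # equal correlations give z = 0, p = 1
  st <- steiger_z(0.4, 0.4, 0.2, 0.1, 0.15, 0.25, 50)
  expect_equal(st$z, 0)
  expect_equal(st$p, 1)

  # frozen reference case, oracle evaluated independently
  st <- steiger_z(0.5, 0.3, 0.2, 0.2, 0.2, 0.2, 100)
  or <- oracle_steiger(0.5, 0.3, 0.2, 0.2, 0.2, 0.2, 100)
  expect_equal(st$z, or$z, tolerance = 1e-12)
  expect_equal(st$p, or$p, tolerance = 1e-12)

  # antisymmetry under swapping the compared pair
  st2 <- steiger_z(0.3, 0.5, 0.2, 0.2, 0.2, 0.2, 100)
  expect_equal(st2$z, -st$z, tolerance = 1e-12)

  expect_error(steiger_z(0.5, 0.3, 0, 0, 0, 0, 3), "n > 3")
  expect_error(steiger_z(1, 0.3, 0, 0, 0, 0, 10), "Fisher")
  w <- capture_warnings(steiger_z(0.9, -0.9, 0.9, 0.9, 0.9, 0.9, 10))
  expect_true(any(grepl("positive semi-definite", w)))
})

test_that("mixed_effect_map recovers betas and degenerates to OLS", {
  set.seed(8)
  n <- 120
  x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  # all-singleton families: OLS fallback with identical slope
  expect_warning(mm <- mixed_effect_map(cbind(x), y, seq_len(n)),
                 "degenerate")
  ols <- coef(lm(scale(y) ~ scale(x)))[2]
  expect_equal(mm$statistic[1], unname(ols), tolerance = 1e-6)

  # parameter recovery with a real family structure (ICC 0.5, beta 0.3)
  set.seed(88)
  n <- 400; fam <- rep(1:200, each = 2)
  u <- rnorm(200, 0, sqrt(0.5))
  xs <- rnorm(n)
  ys <- 0.3 * xs + u[fam] + rnorm(n, 0, sqrt(0.5))
  mm <- mixed_effect_map(cbind(xs, const = rep(1, n)), ys, fam)
  expect_lt(abs(mm$statistic[1] - 0.3), 0.1)
  expect_lt(mm$p[1], 0.001)
  # constant voxel handled
  expect_true(is.nan(mm$statistic[2]))

  # covariate variant runs and keeps the BOLD beta
  mmc <- mixed_effect_map(cbind(xs), ys, fam,
                          covariates = data.frame(age = rnorm(n)))
  expect_lt(abs(mmc$statistic[1] - 0.3), 0.1)
})

test_that("mixed-model null p-values are approximately uniform", {
  set.seed(10)
  n <- 80; fam <- rep(1:40, each = 2)
  u <- rnorm(40, 0, 0.7)
  pvals <- replicate(200, {
    x <- rnorm(n)
    y <- u[fam] + rnorm(n, 0, 0.7)
    suppressMessages(mixed_effect_map(cbind(x), y, fam))$p[1]
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})
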