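test_that("apply_signature is a linear dot-product functional", {
  set.seed(1)
  p <- 40
  w <- rnorm(p)
  X <- matrix(rnorm(6 * p), 6)
  # indicator weight picks out one voxel
  ind <- numeric(p); ind[7] <- 1
  expect_equal(apply_signature(ind, X), X[, 7])
  # orthogonal map returns the constant
  w_unit <- w / sqrt(sum(w^2))
  x_orth <- rnorm(p); x_orth <- x_orth - sum(x_orth * w_unit) * w_unit
  expect_equal(apply_signature(w, x_orth, constant = 2.5), 2.5,
               tolerance = 1e-10)
  # exact linearity
  x1 <- rnorm(p); x2 <- rnorm(p)
  expect_equal(apply_signature(w, 2 * x1 + 3 * x2),
               2 * apply_signature(w, x1) + 3 * apply_signature(w, x2),
               tolerance = 1e-10)
  expect_error(apply_signature(w, X[, 1:10]), "differ")

  # agrees with the generating model's predictions
  b <- tiny_cohort(n = 70, seed = 3)
  m <- fit_lasso_pcr(b$maps$pain, b$participants$sensitivity,
                     lambda_grid_default(15), seed = 1, nested = FALSE)
  expect_lt(max(abs(apply_signature(m$voxel_weights, b$maps$pain,
                                    m$weight_constant) -
                      predict(m, b$maps$pain))), 1e-8)
})

test_that("compare_signatures handles identity, flips, and degeneracy", {
  set.seed(2)
  w <- rnorm(500)
  expect_equal(compare_signatures(w, w), 1)
  expect_equal(compare_signatures(w, -w), -1)
  expect_warning(cc <- compare_signatures(w, rep(1, 500)), "constant")
  expect_true(is.nan(cc))
  expect_error(compare_signatures(w, w[1:10]), "differ")
  # independent random maps at p = 1000 have near-zero spatial correlation
  set.seed(42)
  rs <- replicate(20, compare_signatures(rnorm(1000), rnorm(1000)))
  expect_lt(mean(abs(rs) < 0.08), 1.01)      # sanity on the vector itself
  expect_gt(mean(abs(rs) < 0.08), 0.7)
  expect_lt(max(abs(rs)), 0.15)
})

test_that("virtual lesion respects complements and accounts every voxel", {
  b <- tiny_cohort(n = 90, seed = 5)
  y <- b$participants$sensitivity
  p <- ncol(b$maps$pain)
  labels <- rep(1L, p); labels[seq_len(floor(p / 3))] <- 2L
  parc <- parcellation(labels)
  g <- lambda_grid_default(10)
  rem <- virtual_lesion(b$maps$pain, y, parc, "remove", g, seed = 4)
  kp <- virtual_lesion(b$maps$pain, y, parc, "keep", g, seed = 4)
  # keep(A) is the same refit as remove(B) for a two-region partition
  expect_equal(kp$r2_refit[kp$region == "region_1"],
               rem$r2_refit[rem$region == "region_2"], tolerance = 1e-12)
  expect_equal(kp$r2_refit[kp$region == "region_2"],
               rem$r2_refit[rem$region == "region_1"], tolerance = 1e-12)
  # no voxel lesioned twice; regions partition the labeled mask
  expect_identical(sum(rem$n_voxels), p)
  # delta accounting is exact
  expect_equal(rem$delta_r2, rem$r2_refit - attr(rem, "full_r2"))

  expect_error(parcellation(integer(10)), "no regions")
})

test_that("predict_reduction recovers coupling and degenerates cleanly", {
  b <- tiny_cohort(n = 300, seed = 7)
  bt <- simulate_treatment(b, 0.5, seed = 2)
  a <- bt$ground_truth$true_weights
  out <- predict_reduction(a, b$maps$pain, bt$treatment$post_maps,
                           bt$treatment$pre_ratings,
                           bt$treatment$post_ratings)
  expect_gt(out$r, 0.3)
  expect_lt(out$p, 1e-4)

  # family variant reports a standardized beta (twin-pair structure)
  bfam <- simulate_cohort(simulation_config(
    n_participants = 300, seed = 7,
    family = list(n_families = 150, icc = 0.4)))
  btf <- simulate_treatment(bfam, 0.5, seed = 2)
  outf <- predict_reduction(btf$ground_truth$true_weights, bfam$maps$pain,
                            btf$treatment$post_maps,
                            btf$treatment$pre_ratings,
                            btf$treatment$post_ratings,
                            family_ids = bfam$participants$family_id)
  expect_true(abs(outf$beta) <= 1.05)
  expect_lt(outf$beta_p, 0.01)

  # post identical to pre: zero reductions, NaN with a message
  expect_message(
    out0 <- predict_reduction(a, b$maps$pain, b$maps$pain,
                              bt$treatment$pre_ratings,
                              bt$treatment$pre_ratings),
    "degenerate")
  expect_true(is.nan(out0$r))
  expect_error(predict_reduction(a, b$maps$pain[1:10, ],
                                 bt$treatment$post_maps,
                                 bt$treatment$pre_ratings,
                                 bt$treatment$post_ratings),
               "paired")

  # invariance to a common constant added to all post ratings
  shifted <- predict_reduction(a, b$maps$pain, bt$treatment$post_maps,
                               bt$treatment$pre_ratings,
                               bt$treatment$post_ratings + 1)
  expect_equal(shifted$r, out$r, tolerance = 1e-12)
})

test_that("baseline adjustment matches the two-stage OLS oracle", {
  b <- tiny_cohort(n = 200, seed = 9)
  bt <- simulate_treatment(b, 0.5, seed = 3)
  a <- bt$ground_truth$true_weights
  base <- bt$treatment$pre_ratings

  # orthogonal baseline leaves r essentially unchanged
  set.seed(11)
  orth <- rnorm(200)
  raw <- predict_reduction(a, b$maps$pain, bt$treatment$post_maps,
                           bt$treatment$pre_ratings,
                           bt$treatment$post_ratings)
  adj <- baseline_adjusted_reduction(a, b$maps$pain, bt$treatment$post_maps,
                                     bt$treatment$pre_ratings,
                                     bt$treatment$post_ratings, orth)
  expect_lt(abs(adj$partial_r - raw$r), 0.1)

  # small-n case against explicit residualization
  idx <- 1:8
  adj8 <- baseline_adjusted_reduction(a, b$maps$pain[idx, ],
                                      bt$treatment$post_maps[idx, ],
                                      bt$treatment$pre_ratings[idx],
                                      bt$treatment$post_ratings[idx],
                                      base[idx])
  pred8 <- apply_signature(a, b$maps$pain[idx, ] -
                                bt$treatment$post_maps[idx, ])
  real8 <- bt$treatment$pre_ratings[idx] - bt$treatment$post_ratings[idx]
  expect_equal(adj8$partial_r,
               oracle_partial_r(pred8, real8, data.frame(b = base[idx])),
               tolerance = 1e-10)

  # reduction that is an exact copy of baseline adjusts to nothing
  copy <- baseline_adjusted_reduction(a, b$maps$pain, bt$treatment$post_maps,
                                      base, rep(0, 200), base)
  expect_lt(abs(copy$partial_r), 0.2)
})

test_that("single-trial prediction works within individuals", {
  set.seed(13)
  n <- 50L; n_tr <- 10; p <- 60
  a <- rnorm(p)
  ratings <- matrix(rnorm(n * n_tr, 5), n, n_tr)
  tm <- array(NA_real_, c(n, n_tr, p))
  for (i in 1:n) for (tt in 1:n_tr)
    tm[i, tt, ] <- (ratings[i, tt] - 5) * a + rnorm(p, sd = 2)
  out <- single_trial_prediction(a, tm, ratings)
  expect_gt(out$mean_r, 0.2)
  expect_lt(out$p, 1e-6)
  expect_gt(out$pooled_beta, 0)
  expect_identical(out$n_used, n)

  # shuffled ratings within participant destroy the coupling
  shuf <- t(apply(ratings, 1, sample))
  out0 <- single_trial_prediction(a, tm, shuf)
  expect_lt(abs(out0$mean_r), 0.1)

  # constant ratings for one participant: excluded with a message
  ratings2 <- ratings; ratings2[3, ] <- 4
  expect_message(out2 <- single_trial_prediction(a, tm, ratings2),
                 "excluded")
  expect_identical(out2$n_used, n - 1L)
  expect_true(is.na(out2$per_participant_r[3]))

  expect_error(single_trial_prediction(a, tm[, 1:2, ], ratings[, 1:2]),
               "3 trials")
})

test_that("simulator trial maps carry within-individual state signal", {
  b <- tiny_cohort(n = 40, seed = 15, trial_maps = TRUE)
  out <- single_trial_prediction(b$ground_truth$true_weights,
                                 b$trial_maps, b$trial_ratings)
  expect_gt(out$mean_r, 0)
  expect_lt(out$p, 0.05)
})
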