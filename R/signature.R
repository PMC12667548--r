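# LASSO principal-component regression signatures.
#
# Voxel features are standardized and decomposed by PCA (all components up
# to min(n_train - 1, p) retained); component scores enter an L1-penalized
# regression whose tuning parameter is picked from a log-uniform grid by
# cross-validated MSE. Performance is reported from out-of-fold predictions
# of an outer 5-fold CV ("nested": the inner lambda-selection CV refits
# standardization + PCA inside each inner fold so no statistic leaks across
# folds). Component coefficients back-project to a raw-space voxel weight
# map, so the deployable signature is a dot product plus a constant.

#' Log-uniform lambda grid
#'
#' @param n number of grid points (100 for signature fitting, 10 for the
#'   stacking grids).
#' @param lo,hi grid range (default `[1e-2, 1e2]`).
#' @return decreasing numeric vector (the order glmnet expects).
#' @export
lambda_grid_default <- function(n = 100, lo = 1e-2, hi = 1e2) {
  sort(exp(seq(log(lo), log(hi), length.out = n)), decreasing = TRUE)
}

# Standardize + PCA + glmnet path on one training set.
.pcr_core <- function(X, y, lambda) {
  mu <- colMeans(X)
  sdv <- sqrt(colMeans(sweep(X, 2L, mu)^2) * nrow(X) / max(nrow(X) - 1L, 1L))
  keep <- sdv > 0
  if (!all(keep))
    message(sum(!keep), " zero-variance voxel(s) dropped from fit")
  if (!any(keep)) {
    # fully degenerate features: intercept-only (mean) model
    return(list(mu = mu, sdv = sdv, keep = keep,
                V = matrix(0, 0, 0), fit = NULL, lambda = lambda,
                pad = FALSE, null_model = TRUE, ybar = mean(y)))
  }
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2L, mu[keep]), 2L,
              sdv[keep], "/")
  k <- min(nrow(X) - 1L, ncol(Xs))
  sv <- svd(Xs, nu = 0L, nv = k)
  V <- sv$v
  scores <- Xs %*% V
  pad <- ncol(scores) < 2L
  if (pad) scores <- cbind(scores, 0)
  fit <- glmnet::glmnet(scores, y, alpha = 1, lambda = lambda,
                        standardize = FALSE, intercept = TRUE,
                        thresh = 1e-10)
  list(mu = mu, sdv = sdv, keep = keep, V = V, fit = fit,
       lambda = lambda, pad = pad, null_model = FALSE, ybar = mean(y))
}

# Predict from a core fit; s = NULL gives the whole path (matrix).
.pcr_scores <- function(core, X) {
  Xs <- sweep(sweep(X[, core$keep, drop = FALSE], 2L, core$mu[core$keep]),
              2L, core$sdv[core$keep], "/")
  sc <- Xs %*% core$V
  if (core$pad) sc <- cbind(sc, 0)
  sc
}

.pcr_predict <- function(core, X, s = NULL) {
  if (isTRUE(core$null_model)) {
    if (is.null(s))
      return(matrix(core$ybar, nrow(X), length(core$lambda)))
    return(rep(core$ybar, nrow(X)))
  }
  pr <- stats::predict(core$fit, newx = .pcr_scores(core, X), s = s)
  if (is.null(s)) pr else drop(pr)
}

# Lambda with minimal k-fold CV MSE. nested = TRUE refits
# standardization + PCA inside every fold; nested = FALSE runs cv.glmnet on
# the PC scores of the full training set (faster; PCA is shared across the
# lambda-selection folds, outer-fold honesty is unaffected).
.select_lambda <- function(X, y, lambda, foldid, nested = TRUE) {
  if (nested) {
    folds <- sort(unique(foldid))
    mse <- matrix(NA_real_, length(folds), length(lambda))
    for (fi in seq_along(folds)) {
      tr <- foldid != folds[fi]
      core <- .pcr_core(X[tr, , drop = FALSE], y[tr], lambda)
      pred <- .pcr_predict(core, X[!tr, , drop = FALSE])
      mse[fi, ] <- colMeans((y[!tr] - pred)^2)
    }
    lambda[which.min(colMeans(mse))]
  } else {
    core <- .pcr_core(X, y, lambda)
    if (isTRUE(core$null_model)) return(lambda[1])
    cv <- glmnet::cv.glmnet(.pcr_scores(core, X), y, lambda = lambda,
                            foldid = foldid, standardize = FALSE,
                            thresh = 1e-10)
    cv$lambda.min
  }
}

.make_foldid <- function(n, n_folds) sample(rep(seq_len(n_folds), length.out = n))

#' Split a cohort into discovery and holdout sets
#'
#' @param n number of participants (or a `cohort_bundle`).
#' @param fraction discovery fraction in `(0,1)`; the discovery set gets
#'   `floor(fraction * n)` participants (n = 399, fraction = 0.5 gives
#'   199 / 200).
#' @param seed integer seed.
#' @return list with integer index vectors `discovery` and `holdout`
#'   (disjoint, exhaustive).
#' @export
split_discovery_holdout <- function(n, fraction = 0.5, seed = 1L) {
  if (inherits(n, "cohort_bundle")) n <- n$config$n_participants
  if (n < 8) stop("need n >= 8")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  set.seed(seed)
  n_disc <- floor(fraction * n)
  disc <- sort(sample.int(n, n_disc))
  list(discovery = disc, holdout = setdiff(seq_len(n), disc))
}

#' Evaluate predictions: Pearson r and variance explained
#'
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`; this is not the
#' square of Pearson's r and is negative when the model does worse than
#' predicting the mean.
#'
#' @param y observed values.
#' @param y_hat predicted values.
#' @return an `evaluation_report`: `pearson_r`, `p`, `r_squared`, `n`.
#' @export
evaluate_predictions <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat))
  r2 <- 1 - sum((y - y_hat)^2) / sum((y - mean(y))^2)
  if (stats::sd(y_hat) == 0) {
    r <- NaN; p <- NA_real_
  } else {
    ct <- stats::cor.test(y, y_hat)
    r <- unname(ct$estimate); p <- ct$p.value
  }
  structure(list(pearson_r = r, p = p, r_squared = r2, n = length(y)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> n = %d, r = %.3f (p = %.3g), R2 = %.3f\n",
              x$n, x$pearson_r, x$p, x$r_squared))
  invisible(x)
}

#' Fit a LASSO-PCR signature with nested cross-validation
#'
#' @param maps participants x voxels matrix.
#' @param y numeric outcome (pain sensitivity).
#' @param lambda_grid penalty grid (default 100 log-uniform values in
#'   `[1e-2, 1e2]`).
#' @param n_folds folds for both CV levels (default 5).
#' @param seed integer seed controlling fold assignment.
#' @param nested `TRUE` (default): lambda-selection CV refits
#'   standardization + PCA per inner fold. `FALSE`: lambda by `cv.glmnet` on
#'   the training fold's PC scores (faster; used by the learning-curve and
#'   virtual-lesion machinery).
#' @param folds optional explicit outer fold assignment (integer vector in
#'   `1..n_folds`), e.g. to share folds across virtual-lesion refits.
#' @return a `lasso_pcr` model: standardization vectors, orthonormal
#'   `component_basis`, sparse `component_coefs`, `intercept`, selected
#'   `lambda`, back-projected `voxel_weights` + `weight_constant`, the outer
#'   fold assignment, and `cv` (an `evaluation_report` from out-of-fold
#'   predictions, with `per_fold` details and `oof` predictions attached).
#' @export
fit_lasso_pcr <- function(maps, y, lambda_grid = lambda_grid_default(),
                          n_folds = 5, seed = 1L, nested = TRUE,
                          folds = NULL) {
  X <- as.matrix(maps)
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (n < 2 * n_folds) stop("need n >= 2 * n_folds")
  lambda <- sort(lambda_grid, decreasing = TRUE)
  if (any(lambda <= 0)) stop("lambda grid must be positive")
  set.seed(seed)
  foldid <- if (is.null(folds)) .make_foldid(n, n_folds) else as.integer(folds)

  oof <- rep(NA_real_, n)
  per_fold <- vector("list", n_folds)
  for (f in sort(unique(foldid))) {
    tr <- foldid != f
    inner_id <- .make_foldid(sum(tr), n_folds)
    lam_f <- .select_lambda(X[tr, , drop = FALSE], y[tr], lambda,
                            inner_id, nested = nested)
    core <- .pcr_core(X[tr, , drop = FALSE], y[tr], lambda)
    oof[!tr] <- .pcr_predict(core, X[!tr, , drop = FALSE], s = lam_f)
    per_fold[[f]] <- c(fold = f, lambda = lam_f,
                       r2 = evaluate_predictions(y[!tr], oof[!tr])$r_squared)
  }
  cv <- evaluate_predictions(y, oof)
  cv$per_fold <- do.call(rbind, per_fold)
  cv$oof <- oof

  final_id <- .make_foldid(n, n_folds)
  lambda_opt <- .select_lambda(X, y, lambda, final_id, nested = nested)
  core <- .pcr_core(X, y, lambda)
  if (isTRUE(core$null_model)) {
    warning("null model: no usable features; predicting the mean")
    coefs <- numeric(0)
    beta <- matrix(core$ybar, 1, 1)
  } else {
    beta <- as.matrix(stats::coef(core$fit, s = lambda_opt))
    if (max(abs(as.matrix(core$fit$beta))) == 0)
      warning("null model: all coefficients are zero at every lambda")
    coefs <- beta[-1L, 1L]
    if (core$pad) coefs <- coefs[-length(coefs)]
  }

  model <- structure(list(voxel_means = core$mu, voxel_sds = core$sdv,
                          keep = core$keep, component_basis = core$V,
                          component_coefs = coefs, intercept = beta[1L, 1L],
                          lambda = lambda_opt, lambda_grid = lambda,
                          cv = cv, folds = foldid, n = n, seed = seed,
                          nested = nested),
                     class = "lasso_pcr")
  bp <- backproject_weights(model)
  model$voxel_weights <- bp$weights
  model$weight_constant <- bp$constant
  model
}

#' @export
print.lasso_pcr <- function(x, ...) {
  cat(sprintf(paste0("<lasso_pcr> n = %d, p = %d, %d components, ",
                     "lambda = %.4g, %d nonzero coefs\n  CV: r = %.3f, ",
                     "R2 = %.3f\n"),
              x$n, length(x$voxel_means), ncol(x$component_basis),
              x$lambda, sum(x$component_coefs != 0),
              x$cv$pearson_r, x$cv$r_squared))
  invisible(x)
}

#' Predict sensitivity from maps with a fitted signature
#'
#' @param object a `lasso_pcr` model.
#' @param maps participants x voxels matrix on the training voxel grid.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.lasso_pcr <- function(object, maps, ...) {
  X <- as.matrix(maps)
  if (!any(object$keep)) return(rep(object$intercept, nrow(X)))
  Xs <- sweep(sweep(X[, object$keep, drop = FALSE], 2L,
                    object$voxel_means[object$keep]), 2L,
              object$voxel_sds[object$keep], "/")
  drop(Xs %*% object$component_basis %*% object$component_coefs) +
    object$intercept
}

#' Back-project component coefficients to voxel space
#'
#' `w_v = (basis coefs)_v / sd_v` on the kept voxels (dropped voxels get
#' weight 0) and `constant = intercept - sum(w_v * mean_v)`, so
#' `maps %*% weights + constant` reproduces [predict.lasso_pcr()] exactly.
#'
#' @param model a `lasso_pcr` model.
#' @return list with `weights` (length = all voxels) and `constant`.
#' @export
backproject_weights <- function(model) {
  stopifnot(inherits(model, "lasso_pcr"))
  w_kept <- drop(model$component_basis %*% model$component_coefs) /
    model$voxel_sds[model$keep]
  weights <- numeric(length(model$voxel_means))
  weights[model$keep] <- w_kept
  constant <- model$intercept -
    sum(w_kept * model$voxel_means[model$keep])
  list(weights = weights, constant = constant)
}

# Out-of-fold CV R2 of a LASSO-PCR fit; shared by learning_curve.
# fixed_lambda = NULL re-tunes lambda inside each training fold; a numeric
# value holds the penalty fixed (the behavior of refitting a final model
# with its tuned hyperparameter at a new sample size).
.cv_r2 <- function(X, y, lambda, n_folds, nested = FALSE,
                   fixed_lambda = NULL) {
  foldid <- .make_foldid(length(y), n_folds)
  oof <- rep(NA_real_, length(y))
  for (f in seq_len(n_folds)) {
    tr <- foldid != f
    lam_f <- if (is.null(fixed_lambda)) {
      .select_lambda(X[tr, , drop = FALSE], y[tr], lambda,
                     .make_foldid(sum(tr), n_folds), nested = nested)
    } else fixed_lambda
    core <- .pcr_core(X[tr, , drop = FALSE], y[tr], lambda)
    oof[!tr] <- .pcr_predict(core, X[!tr, , drop = FALSE], s = lam_f)
  }
  evaluate_predictions(y, oof)$r_squared
}

#' Learning curve: CV performance versus training-set size
#'
#' For each repetition the cohort is reshuffled; for each size the first
#' `size` participants of the shuffle are cross-validated and the
#' out-of-fold R2 recorded. By default the penalty is tuned once on the full
#' cohort and then held fixed across sizes -- the model (with its tuned
#' hyperparameter) is what gets refit at each size, which is why performance
#' collapses below the sample size the penalty was tuned for. Set
#' `retune = TRUE` to re-select lambda inside every training fold instead.
#'
#' @param maps participants x voxels matrix.
#' @param y numeric outcome.
#' @param sizes training sizes (default 20 to 300 in steps of 5); sizes
#'   below 10 are skipped with a message; `max(sizes)` must be at most
#'   `0.8 * n` (5-fold CV geometry).
#' @param reps repetitions (default 100).
#' @param seed integer seed.
#' @param lambda_grid penalty grid.
#' @param n_folds CV folds.
#' @param retune re-select lambda inside every training fold instead of
#'   holding the full-cohort tuned value fixed.
#' @param nested see [fit_lasso_pcr()]; default `FALSE` for speed.
#' @return a `learning_curve`: `sizes`, `mean_r2`, `sd_r2`, `n_reps` (audit
#'   count per size), the full `r2` matrix (reps x sizes), and `lambda`
#'   (the fixed penalty, NA when retuning).
#' @export
learning_curve <- function(maps, y, sizes = seq(20, 300, by = 5),
                           reps = 100, seed = 1L,
                           lambda_grid = lambda_grid_default(),
                           n_folds = 5, retune = FALSE, nested = FALSE) {
  X <- as.matrix(maps)
  n <- length(y)
  skip <- sizes < 10
  if (any(skip)) {
    message("skipping sizes < 10: ", paste(sizes[skip], collapse = ", "))
    sizes <- sizes[!skip]
  }
  if (max(sizes) > 0.8 * n)
    stop("max(sizes) must be <= 0.8 * n for 5-fold CV geometry")
  lambda <- sort(lambda_grid, decreasing = TRUE)
  fixed_lambda <- NULL
  if (!retune) {
    set.seed(seed)
    fixed_lambda <- .select_lambda(X, y, lambda, .make_foldid(n, n_folds),
                                   nested = nested)
  }
  r2 <- matrix(NA_real_, reps, length(sizes))
  for (rep_i in seq_len(reps)) {
    set.seed(seed + rep_i)
    perm <- sample.int(n)
    for (si in seq_along(sizes)) {
      idx <- perm[seq_len(sizes[si])]
      r2[rep_i, si] <- .cv_r2(X[idx, , drop = FALSE], y[idx], lambda,
                              n_folds, nested = nested,
                              fixed_lambda = fixed_lambda)
    }
  }
  structure(list(sizes = sizes, mean_r2 = colMeans(r2),
                 sd_r2 = apply(r2, 2L, stats::sd),
                 n_reps = as.integer(colSums(!is.na(r2))), r2 = r2,
                 seed = seed,
                 lambda = fixed_lambda %||% NA_real_),
            class = "learning_curve")
}

#' Covariate-adjusted signature fit
#'
#' Regresses the covariates out of both the maps and the outcome (full-data
#' residualization, the convention for site-effect removal; the maps are
#' deliberately not re-standardized within dataset to avoid leakage), then
#' fits the LASSO-PCR on the residuals.
#'
#' @inheritParams fit_lasso_pcr
#' @param covariates data.frame of covariates (dataset / sex / age or any
#'   subset); must be full rank after dummy coding.
#' @return a `lasso_pcr` model (fitted to residuals) with the covariate
#'   names recorded in `$covariates`.
#' @export
covariate_adjusted_fit <- function(maps, y, covariates,
                                   lambda_grid = lambda_grid_default(),
                                   n_folds = 5, seed = 1L, nested = TRUE) {
  covariates <- as.data.frame(covariates)
  design <- stats::model.matrix(~ ., data = covariates)
  if (qr(design)$rank < ncol(design))
    stop("rank-deficient covariates")
  X_res <- .residualize(as.matrix(maps), design)
  y_res <- drop(.residualize(matrix(y, ncol = 1), design))
  model <- fit_lasso_pcr(X_res, y_res, lambda_grid, n_folds, seed,
                         nested = nested)
  model$covariates <- names(covariates)
  model
}

#' Behavior-only LASSO model
#'
#' Plain LASSO on standardized behavioral features (no PCA step); missing
#' feature values are median-imputed with training medians; lambda is picked
#' from the grid by CV, and performance is reported from outer-fold
#' out-of-fold predictions.
#'
#' @param features participants x features matrix or data.frame (numeric).
#' @param y numeric outcome.
#' @param lambda_grid penalty grid (default 100 log-uniform values in
#'   `[1e-2, 1e2]`).
#' @param n_folds CV folds.
#' @param seed integer seed.
#' @return a `behavior_lasso` model with `fit` (glmnet path), `lambda`,
#'   `medians`, and `cv` evaluation report.
#' @export
fit_behavior_lasso <- function(features, y,
                               lambda_grid = lambda_grid_default(),
                               n_folds = 5, seed = 1L) {
  Fm <- as.matrix(as.data.frame(features))
  if (ncol(Fm) == 0) stop("no behavioral features")
  storage.mode(Fm) <- "double"
  medians <- apply(Fm, 2L, stats::median, na.rm = TRUE)
  for (j in seq_len(ncol(Fm)))
    Fm[is.na(Fm[, j]), j] <- medians[j]
  if (ncol(Fm) == 1L) Fm <- cbind(Fm, 0)
  lambda <- sort(lambda_grid, decreasing = TRUE)
  n <- length(y)
  set.seed(seed)
  foldid <- .make_foldid(n, n_folds)
  oof <- rep(NA_real_, n)
  for (f in seq_len(n_folds)) {
    tr <- foldid != f
    cvf <- glmnet::cv.glmnet(Fm[tr, , drop = FALSE], y[tr], lambda = lambda,
                             foldid = .make_foldid(sum(tr), n_folds),
                             standardize = TRUE)
    pred <- stats::predict(cvf$glmnet.fit, newx = Fm[!tr, , drop = FALSE],
                           s = cvf$lambda.min)
    oof[!tr] <- drop(pred)
  }
  cv <- evaluate_predictions(y, oof)
  cv$oof <- oof
  cvf <- glmnet::cv.glmnet(Fm, y, lambda = lambda,
                           foldid = .make_foldid(n, n_folds),
                           standardize = TRUE)
  structure(list(fit = cvf$glmnet.fit, lambda = cvf$lambda.min,
                 medians = medians, cv = cv, folds = foldid,
                 feature_names = colnames(Fm), seed = seed),
            class = "behavior_lasso")
}

#' @export
predict.behavior_lasso <- function(object, features, ...) {
  Fm <- as.matrix(as.data.frame(features))
  storage.mode(Fm) <- "double"
  if (isTRUE(object$null_model)) return(rep(object$ybar, nrow(Fm)))
  for (j in seq_len(ncol(Fm)))
    Fm[is.na(Fm[, j]), j] <- object$medians[j]
  if (ncol(Fm) == 1L) Fm <- cbind(Fm, 0)
  drop(stats::predict(object$fit, newx = Fm, s = object$lambda))
}

#' Stacking ensemble of the fMRI and behavior models
#'
#' Out-of-fold predictions of the LASSO-PCR (maps) and LASSO (behavior
#' features) base models feed a two-predictor + intercept least-squares
#' combiner. The two penalties are selected jointly: base-model prediction
#' paths are precomputed per outer fold for every grid value, and each
#' `(lambda_1, lambda_2)` pair is scored by the cross-validated MSE of its
#' stacked predictions.
#'
#' @param maps participants x voxels matrix.
#' @param features behavioral feature matrix / data.frame.
#' @param y numeric outcome.
#' @param grid_1,grid_2 penalty grids for the fMRI and behavior base models
#'   (default 10 log-uniform values in `[1e-2, 1e2]` each).
#' @param n_folds CV folds.
#' @param seed integer seed.
#' @return a `stacked_model` with the refit base models, combiner
#'   coefficients, chosen `lambda_1` / `lambda_2`, and `cv` evaluation
#'   report from out-of-fold stacked predictions.
#' @export
fit_stacking <- function(maps, features, y,
                         grid_1 = lambda_grid_default(10),
                         grid_2 = lambda_grid_default(10),
                         n_folds = 5, seed = 1L) {
  X <- as.matrix(maps)
  Fm <- as.matrix(as.data.frame(features))
  storage.mode(Fm) <- "double"
  medians <- apply(Fm, 2L, stats::median, na.rm = TRUE)
  for (j in seq_len(ncol(Fm)))
    Fm[is.na(Fm[, j]), j] <- medians[j]
  if (ncol(Fm) == 1L) Fm <- cbind(Fm, 0)
  n <- length(y)
  g1 <- sort(grid_1, decreasing = TRUE)
  g2 <- sort(grid_2, decreasing = TRUE)
  set.seed(seed)
  foldid <- .make_foldid(n, n_folds)

  fmri_null <- all(apply(X, 2L, stats::sd) == 0)
  behav_null <- all(apply(Fm, 2L, stats::sd) == 0)
  if (fmri_null)
    warning("fMRI base model is degenerate (no non-constant voxels); ",
            "the combiner will lean on the behavior block")
  if (behav_null)
    warning("behavior base model is degenerate (no non-constant features); ",
            "the combiner will lean on the fMRI block")

  P1 <- matrix(NA_real_, n, length(g1))
  P2 <- matrix(NA_real_, n, length(g2))
  for (f in seq_len(n_folds)) {
    tr <- foldid != f
    core <- .pcr_core(X[tr, , drop = FALSE], y[tr], g1)
    P1[!tr, ] <- .pcr_predict(core, X[!tr, , drop = FALSE])
    if (behav_null) {
      P2[!tr, ] <- mean(y[tr])
    } else {
      bf <- glmnet::glmnet(Fm[tr, , drop = FALSE], y[tr], lambda = g2,
                           standardize = TRUE)
      P2[!tr, ] <- as.matrix(stats::predict(bf,
                                            newx = Fm[!tr, , drop = FALSE]))
    }
  }

  comb_fold <- .make_foldid(n, n_folds)
  best <- c(NA_integer_, NA_integer_); best_mse <- Inf; best_oof <- NULL
  for (i in seq_along(g1)) {
    for (j in seq_along(g2)) {
      oof <- rep(NA_real_, n)
      for (f in seq_len(n_folds)) {
        tr <- comb_fold != f
        cf <- stats::lm.fit(cbind(1, P1[tr, i], P2[tr, j]), y[tr])
        co <- ifelse(is.na(cf$coefficients), 0, cf$coefficients)
        oof[!tr] <- drop(cbind(1, P1[!tr, i], P2[!tr, j]) %*% co)
      }
      mse <- mean((y - oof)^2)
      if (mse < best_mse) {
        best_mse <- mse; best <- c(i, j); best_oof <- oof
      }
    }
  }
  lambda_1 <- g1[best[1]]; lambda_2 <- g2[best[2]]
  cv <- evaluate_predictions(y, best_oof)
  cv$oof <- best_oof

  fmri_model <- fit_lasso_pcr(X, y, lambda_grid = g1, n_folds = n_folds,
                              seed = seed, nested = FALSE)
  fmri_model$lambda <- lambda_1
  core <- .pcr_core(X, y, g1)
  if (!isTRUE(core$null_model)) {
    beta <- as.matrix(stats::coef(core$fit, s = lambda_1))
    fmri_model$component_coefs <- if (core$pad) beta[-c(1L, nrow(beta)), 1L]
                                  else beta[-1L, 1L]
    fmri_model$intercept <- beta[1L, 1L]
    bp <- backproject_weights(fmri_model)
    fmri_model$voxel_weights <- bp$weights
    fmri_model$weight_constant <- bp$constant
  }

  behav_fit <- if (behav_null) NULL else
    glmnet::glmnet(Fm, y, lambda = g2, standardize = TRUE)
  behav_model <- structure(list(fit = behav_fit, lambda = lambda_2,
                                medians = medians, cv = NULL,
                                null_model = behav_null, ybar = mean(y),
                                feature_names = colnames(Fm), seed = seed),
                           class = "behavior_lasso")
  cmb <- stats::lm.fit(cbind(1, predict(fmri_model, X),
                             predict(behav_model, Fm)), y)
  combiner <- ifelse(is.na(cmb$coefficients), 0, cmb$coefficients)

  structure(list(fmri_model = fmri_model, behavior_model = behav_model,
                 combiner = combiner, lambda_1 = lambda_1,
                 lambda_2 = lambda_2, cv = cv, seed = seed),
            class = "stacked_model")
}

#' @export
predict.stacked_model <- function(object, maps, features, ...) {
  p1 <- predict(object$fmri_model, as.matrix(maps))
  p2 <- predict(object$behavior_model, features)
  drop(cbind(1, p1, p2) %*% object$combiner)
}
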