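# Model interpretation and transfer: virtual-lesion region importance,
# signature expression of arbitrary maps, signature comparison, treatment
# (pain-reduction) prediction with optional baseline adjustment and family
# random intercepts, and within-individual single-trial prediction.

#' Parcellation of the analysis mask
#'
#' @param labels integer vector over mask voxels (0 = background).
#' @param lookup data.frame with columns `code` and `name`; defaults to
#'   `region_<code>` names.
#' @return a `parcellation` object.
#' @export
parcellation <- function(labels, lookup = NULL) {
  labels <- as.integer(labels)
  codes <- sort(unique(labels[labels > 0L]))
  if (length(codes) == 0) stop("parcellation has no regions")
  if (is.null(lookup))
    lookup <- data.frame(code = codes, name = sprintf("region_%d", codes))
  stopifnot(all(c("code", "name") %in% names(lookup)))
  structure(list(labels = labels, lookup = lookup), class = "parcellation")
}

#' Virtual-lesion analysis of a signature
#'
#' For each region, either remove its voxels ("remove") or retain only its
#' voxels ("keep"), refit the full LASSO-PCR pipeline with the same outer
#' fold assignment and seed as the full model (so performance deltas are
#' not confounded by fold noise), and report the change in cross-validated
#' R2. Columns are genuinely deleted and the PCA re-run, not zeroed.
#'
#' @param maps participants x voxels matrix.
#' @param y numeric outcome.
#' @param parc a [parcellation()] aligned to the map columns.
#' @param mode `"remove"` or `"keep"`.
#' @param lambda_grid,n_folds,seed,nested passed to [fit_lasso_pcr()];
#'   `nested = FALSE` by default (one refit per region).
#' @param full_model optional pre-fitted full `lasso_pcr` (must carry the
#'   same seed/folds) to avoid refitting the baseline.
#' @return a `lesion_report` data.frame (region, mode, n_voxels, r2_refit,
#'   delta_r2) with the baseline full-model R2 as attribute `full_r2`.
#' @export
virtual_lesion <- function(maps, y, parc, mode = c("remove", "keep"),
                           lambda_grid = lambda_grid_default(),
                           n_folds = 5, seed = 1L, nested = FALSE,
                           full_model = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(parc, "parcellation"))
  X <- as.matrix(maps)
  if (length(parc$labels) != ncol(X))
    stop("parcellation is not aligned to the maps")
  if (is.null(full_model)) {
    set.seed(seed)
    folds <- .make_foldid(length(y), n_folds)
    full_model <- fit_lasso_pcr(X, y, lambda_grid, n_folds, seed,
                                nested = nested, folds = folds)
  }
  folds <- full_model$folds
  full_r2 <- full_model$cv$r_squared

  rows <- lapply(seq_len(nrow(parc$lookup)), function(ri) {
    code <- parc$lookup$code[ri]
    in_region <- parc$labels == code
    if (!any(in_region)) {
      message("region ", parc$lookup$name[ri], " has no in-mask voxels; skipped")
      return(NULL)
    }
    cols <- if (mode == "remove") !in_region else in_region
    if (sum(cols) < 2) {
      message("region ", parc$lookup$name[ri], ": fewer than 2 features after ",
              mode, "; skipped")
      return(NULL)
    }
    refit <- fit_lasso_pcr(X[, cols, drop = FALSE], y, lambda_grid,
                           n_folds, seed, nested = nested, folds = folds)
    data.frame(region = parc$lookup$name[ri], mode = mode,
               n_voxels = sum(in_region), r2_refit = refit$cv$r_squared,
               delta_r2 = refit$cv$r_squared - full_r2)
  })
  out <- do.call(rbind, rows)
  attr(out, "full_r2") <- full_r2
  class(out) <- c("lesion_report", class(out))
  out
}

#' Signature expression of maps (dot product + constant)
#'
#' @param weights voxel weight vector.
#' @param maps participants x voxels matrix (or a single map vector).
#' @param constant additive constant (default 0; external signatures often
#'   come without one, which is irrelevant for correlation metrics).
#' @return numeric vector of expressions.
#' @export
apply_signature <- function(weights, maps, constant = 0) {
  if (is.null(dim(maps))) maps <- matrix(maps, nrow = 1)
  maps <- as.matrix(maps)
  if (ncol(maps) != length(weights))
    stop("weight vector and map voxel count differ")
  drop(maps %*% weights) + constant
}

#' Spatial correlation between two signature weight maps
#'
#' @param weight_a,weight_b voxel weight vectors; `NA` voxels are excluded,
#'   the correlation runs over the shared (non-NA) support.
#' @return Pearson r; `NaN` with a warning when either map is constant.
#' @export
compare_signatures <- function(weight_a, weight_b) {
  if (length(weight_a) != length(weight_b)) stop("weight map lengths differ")
  ok <- !is.na(weight_a) & !is.na(weight_b)
  if (sum(ok) < 2) stop("need at least 2 shared voxels")
  a <- weight_a[ok]; b <- weight_b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant weight map; correlation undefined")
    return(NaN)
  }
  stats::cor(a, b)
}

#' Predict treatment-induced pain reduction from difference maps
#'
#' Computes the signature expression of the (pre - post) difference maps and
#' relates it to the (pre - post) rating reductions: Pearson r (+ p) and,
#' when family ids are supplied, the standardized fixed-effect beta of
#' `real ~ predicted + (1 | family)`.
#'
#' @param weights signature voxel weights.
#' @param pre_maps,post_maps paired participants x voxels matrices.
#' @param pre_ratings,post_ratings paired rating vectors.
#' @param family_ids optional family identifiers.
#' @param constant signature constant (cancels in the correlation).
#' @return list with `r`, `p`, `n`, `predicted`, `real`, and (with families)
#'   `beta`, `beta_p`.
#' @export
predict_reduction <- function(weights, pre_maps, post_maps,
                              pre_ratings, post_ratings,
                              family_ids = NULL, constant = 0) {
  pre_maps <- as.matrix(pre_maps); post_maps <- as.matrix(post_maps)
  n <- length(pre_ratings)
  if (nrow(pre_maps) != n || nrow(post_maps) != n ||
      length(post_ratings) != n)
    stop("pre/post maps and ratings must be paired per participant")
  predicted <- apply_signature(weights, pre_maps - post_maps, constant)
  real <- pre_ratings - post_ratings
  out <- list(predicted = predicted, real = real, n = n)
  if (stats::sd(real) == 0 || stats::sd(predicted) == 0) {
    message("degenerate reductions (zero variance); correlation undefined")
    out$r <- NaN; out$p <- NA_real_
    return(out)
  }
  ct <- stats::cor.test(predicted, real)
  out$r <- unname(ct$estimate); out$p <- ct$p.value
  if (!is.null(family_ids)) {
    dat <- data.frame(real = drop(scale(real)),
                      pred = drop(scale(predicted)),
                      fam = factor(family_ids))
    if (nlevels(dat$fam) >= n || nlevels(dat$fam) <= 1L) {
      warning("family structure is degenerate; using OLS for the beta")
      co <- summary(stats::lm(real ~ pred, data = dat))$coefficients["pred", ]
      out$beta <- co[["Estimate"]]
      out$beta_p <- co[["Pr(>|t|)"]]
    } else {
      fit <- lme4::lmer(real ~ pred + (1 | fam), data = dat, REML = TRUE,
                        control = lme4::lmerControl(
                          check.conv.singular = "ignore"))
      co <- stats::coef(summary(fit))["pred", ]
      out$beta <- co[["Estimate"]]
      out$beta_p <- 2 * stats::pnorm(-abs(co[["t value"]]))
    }
  }
  out
}

#' Baseline-adjusted reduction prediction
#'
#' Residualizes both the predicted and the real reductions on the baseline
#' ratings and correlates the residuals (partial r with n - 3 df); with
#' family ids, fits `real ~ predicted + baseline + (1 | family)` instead and
#' reports the standardized beta of the prediction.
#'
#' @inheritParams predict_reduction
#' @param baseline_ratings baseline (pre-treatment) ratings.
#' @return list with `partial_r`, `p`, `n` (and `beta`, `beta_p` with
#'   families).
#' @export
baseline_adjusted_reduction <- function(weights, pre_maps, post_maps,
                                        pre_ratings, post_ratings,
                                        baseline_ratings,
                                        family_ids = NULL, constant = 0) {
  base <- predict_reduction(weights, pre_maps, post_maps,
                            pre_ratings, post_ratings, constant = constant)
  design <- cbind(1, baseline_ratings)
  pr <- drop(.residualize(matrix(base$predicted, ncol = 1), design))
  re <- drop(.residualize(matrix(base$real, ncol = 1), design))
  n <- base$n
  out <- list(n = n)
  if (stats::sd(pr) == 0 || stats::sd(re) == 0) {
    out$partial_r <- NaN; out$p <- NA_real_
    return(out)
  }
  r <- stats::cor(pr, re)
  df <- n - 3
  t_stat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  out$partial_r <- r
  out$p <- 2 * stats::pt(-abs(t_stat), df)
  if (!is.null(family_ids)) {
    dat <- data.frame(real = drop(scale(base$real)),
                      pred = drop(scale(base$predicted)),
                      baseline = drop(scale(baseline_ratings)),
                      fam = factor(family_ids))
    fit <- lme4::lmer(real ~ pred + baseline + (1 | fam), data = dat,
                      REML = TRUE,
                      control = lme4::lmerControl(
                        check.conv.singular = "ignore"))
    co <- stats::coef(summary(fit))["pred", ]
    out$beta <- co[["Estimate"]]
    out$beta_p <- 2 * stats::pnorm(-abs(co[["t value"]]))
  }
  out
}

#' Within-individual single-trial prediction
#'
#' Signature expressions of single-trial maps are correlated with the trial
#' ratings within each participant; the group summary is the mean
#' within-participant r with a one-sample t test against zero. A pooled
#' mixed-model slope (`rating ~ expression + (1 | participant)`, both
#' standardized) is reported alongside.
#'
#' @param weights signature voxel weights.
#' @param trial_maps participants x trials x voxels array.
#' @param trial_ratings participants x trials matrix.
#' @param constant signature constant.
#' @return list with `per_participant_r`, `mean_r`, `t`, `p` (group test),
#'   `pooled_beta`, `pooled_p`, `n_used`.
#' @export
single_trial_prediction <- function(weights, trial_maps, trial_ratings,
                                    constant = 0) {
  stopifnot(length(dim(trial_maps)) == 3)
  n <- dim(trial_maps)[1]; n_tr <- dim(trial_maps)[2]
  if (n_tr < 3) stop("need at least 3 trials per participant")
  stopifnot(nrow(trial_ratings) == n, ncol(trial_ratings) == n_tr)
  expr <- matrix(NA_real_, n, n_tr)
  for (i in seq_len(n))
    expr[i, ] <- apply_signature(weights, trial_maps[i, , ], constant)
  r_i <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (stats::sd(trial_ratings[i, ]) == 0 || stats::sd(expr[i, ]) == 0) {
      message("participant ", i,
              ": constant trial ratings or expressions; excluded")
      next
    }
    r_i[i] <- stats::cor(expr[i, ], trial_ratings[i, ])
  }
  used <- !is.na(r_i)
  out <- list(per_participant_r = r_i, n_used = sum(used))
  if (sum(used) >= 2) {
    tt <- stats::t.test(r_i[used])
    out$mean_r <- mean(r_i[used])
    out$t <- unname(tt$statistic); out$p <- tt$p.value
  } else {
    out$mean_r <- if (any(used)) r_i[used] else NaN
    out$t <- NA_real_; out$p <- NA_real_
  }
  dat <- data.frame(rating = drop(scale(as.vector(trial_ratings))),
                    expr = drop(scale(as.vector(expr))),
                    id = factor(rep(seq_len(n), times = n_tr)))
  ok <- stats::complete.cases(dat)
  fit <- tryCatch(
    lme4::lmer(rating ~ expr + (1 | id), data = dat[ok, ], REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    error = function(e) NULL)
  if (!is.null(fit)) {
    co <- stats::coef(summary(fit))["expr", ]
    out$pooled_beta <- co[["Estimate"]]
    out$pooled_p <- 2 * stats::pnorm(-abs(co[["t value"]]))
  }
  out
}
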