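# Univariate brain-behavior mapping: voxelwise and ROI correlations,
# partial correlation with dataset-wise standardization, BH-FDR masking,
# Dice overlap, conjunctions, Steiger's z for dependent correlations, and
# family-aware mixed-effects maps.

new_stat_map <- function(statistic, p, q, sig_mask, meta) {
  structure(list(statistic = statistic, p = p, q = q, sig_mask = sig_mask,
                 meta = meta), class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  ok <- !is.na(x$statistic)
  cat("<stat_map>", x$meta$method, "| n =", x$meta$n, "|",
      length(x$statistic), "voxels (", sum(!ok), "constant ) |",
      sum(x$sig_mask, na.rm = TRUE), "significant at",
      x$meta$threshold_rule, "\n")
  invisible(x)
}

# Column-wise Pearson r of X against y, with two-sided p from the t
# transform on n-2 df. Zero-variance columns give NaN / p = 1.
.col_pearson <- function(X, y, df_loss = 2L) {
  n <- length(y)
  Xc <- sweep(X, 2L, colMeans(X))
  yc <- y - mean(y)
  sx <- sqrt(colSums(Xc^2))
  sy <- sqrt(sum(yc^2))
  r <- unname(drop(crossprod(Xc, yc)) / (sx * sy))
  r[sx == 0] <- NaN
  r <- pmin(pmax(r, -1), 1)
  df <- n - df_loss
  t_stat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t_stat), df)
  p[is.nan(r)] <- 1
  list(r = r, p = p)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up BH adjustment; `NA` p-values are excluded from the family (they
#' get `q = NA` and are never significant).
#'
#' @param p vector of p-values in `[0,1]` (NA allowed).
#' @param q_level FDR level for the significance mask.
#' @return list with `q` (adjusted values) and `sig` (logical mask).
#' @export
fdr_bh <- function(p, q_level = 0.05) {
  if (length(p) == 0) return(list(q = numeric(0), sig = logical(0)))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  sig <- !is.na(q) & q <= q_level
  list(q = q, sig = sig)
}

#' Voxelwise correlation between maps and behavior
#'
#' Pearson (or Spearman rank) correlation of every voxel's values across
#' participants with a behavioral score, with BH-FDR control across the
#' testable (non-constant) voxels.
#'
#' @param maps participants x voxels matrix.
#' @param behavior numeric vector, one value per participant.
#' @param method `"pearson"` or `"spearman"`.
#' @param q_level FDR level for the significance mask.
#' @return a `stat_map` with per-voxel `statistic`, `p`, `q`, `sig_mask`.
#'   Constant voxels get `statistic = NaN`, `p = 1`, `q = NA` and are
#'   excluded from the FDR family.
#' @export
voxelwise_correlation <- function(maps, behavior,
                                  method = c("pearson", "spearman"),
                                  q_level = 0.05) {
  method <- match.arg(method)
  maps <- as.matrix(maps)
  if (nrow(maps) != length(behavior))
    stop("maps rows and behavior length differ")
  if (length(behavior) < 4) stop("need n >= 4")
  if (stats::sd(behavior) == 0) stop("behavior is constant")
  if (method == "spearman") {
    maps <- apply(maps, 2L, rank)
    behavior <- rank(behavior)
  }
  res <- .col_pearson(maps, behavior)
  testable <- !is.nan(res$r)
  adj <- fdr_bh(ifelse(testable, res$p, NA_real_), q_level)
  new_stat_map(res$r, res$p, adj$q, adj$sig,
               list(method = method, n = length(behavior),
                    threshold_rule = sprintf("q(FDR) <= %g", q_level),
                    covariates = character(0)))
}

# Residualize columns of X (and y) on a covariate design matrix via QR
# (rank-deficient designs are fine: redundant columns drop out).
.residualize <- function(X, design) {
  qr.resid(qr(design), X)
}

#' Partial correlation map controlling for covariates
#'
#' Optionally standardizes maps (voxelwise) and behavior within each dataset
#' first, then regresses the covariates (dataset dummy, sex dummy, age, ...)
#' out of both sides and correlates the residuals. Missing numeric covariate
#' values are median-imputed. Inference uses n - 2 - k df.
#'
#' @param maps participants x voxels matrix.
#' @param behavior numeric vector.
#' @param covariates data.frame of covariates (factors/characters are dummy
#'   coded); may be NULL/empty, in which case the result equals
#'   [voxelwise_correlation()].
#' @param dataset optional dataset labels; triggers within-dataset
#'   standardization of maps and behavior before residualization.
#' @param q_level FDR level.
#' @return a `stat_map` of partial correlations.
#' @export
partial_correlation_map <- function(maps, behavior, covariates = NULL,
                                    dataset = NULL, q_level = 0.05) {
  maps <- as.matrix(maps)
  n <- length(behavior)
  if (nrow(maps) != n) stop("maps rows and behavior length differ")

  if (!is.null(dataset)) {
    for (d in unique(dataset)) {
      i <- dataset == d
      maps[i, ] <- scale(maps[i, , drop = FALSE])
      behavior[i] <- drop(scale(behavior[i]))
    }
    maps[is.nan(maps)] <- 0
  }

  k <- 0L
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    covariates <- as.data.frame(covariates)
    for (j in seq_along(covariates)) {
      if (is.numeric(covariates[[j]]) && anyNA(covariates[[j]]))
        covariates[[j]][is.na(covariates[[j]])] <-
          stats::median(covariates[[j]], na.rm = TRUE)
    }
    design <- stats::model.matrix(~ ., data = covariates)
    k <- ncol(design) - 1L
    y_res <- .residualize(matrix(behavior, ncol = 1), design)
    if (stats::sd(y_res) < 1e-12 * max(stats::sd(behavior), 1))
      stop("behavior explained by covariates: zero residual variance")
    maps <- .residualize(maps, design)
    behavior <- drop(y_res)
  }
  res <- .col_pearson(maps, behavior, df_loss = 2L + k)
  testable <- !is.nan(res$r)
  adj <- fdr_bh(ifelse(testable, res$p, NA_real_), q_level)
  new_stat_map(res$r, res$p, adj$q, adj$sig,
               list(method = "partial", n = n,
                    threshold_rule = sprintf("q(FDR) <= %g", q_level),
                    covariates = if (k) colnames(covariates) else character(0)))
}

#' Mean signal within a region of interest
#'
#' @param maps participants x voxels matrix.
#' @param roi_mask logical vector over voxels (or integer indices).
#' @return numeric vector, one mean per participant.
#' @export
roi_mean_signal <- function(maps, roi_mask) {
  maps <- as.matrix(maps)
  idx <- if (is.logical(roi_mask)) which(roi_mask) else as.integer(roi_mask)
  if (length(idx) == 0) stop("empty ROI mask")
  rowMeans(maps[, idx, drop = FALSE])
}

#' Correlate an ROI's mean signal with behavior
#'
#' @inheritParams roi_mean_signal
#' @param behavior numeric vector.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `r`, `p`, `n`.
#' @export
roi_correlation <- function(maps, behavior, roi_mask,
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ms <- roi_mean_signal(maps, roi_mask)
  ct <- stats::cor.test(ms, behavior, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(behavior))
}

#' Dice overlap between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; symmetric, in `[0,1]`.
#'
#' @param mask_a,mask_b logical vectors of equal length.
#' @return scalar; `NaN` (with a warning) when both masks are empty.
#' @export
dice <- function(mask_a, mask_b) {
  if (length(mask_a) != length(mask_b)) stop("mask lengths differ")
  na <- sum(mask_a); nb <- sum(mask_b)
  if (na + nb == 0) {
    warning("both masks are empty; Dice undefined")
    return(NaN)
  }
  2 * sum(mask_a & mask_b) / (na + nb)
}

#' Conjunction (elementwise AND) of two masks
#' @param mask_a,mask_b logical vectors of equal length.
#' @return logical vector.
#' @export
conjunction <- function(mask_a, mask_b) {
  if (length(mask_a) != length(mask_b)) stop("mask lengths differ")
  mask_a & mask_b
}

#' Steiger's z test for two dependent correlations (no shared variable)
#'
#' Tests whether `cor(j,k)` differs from `cor(h,m)` in the same sample of
#' `n` subjects, using Fisher transforms and the pooled Pearson-Filon
#' covariance evaluated at `rbar = (r_jk + r_hm)/2`:
#' `z = (Z_jk - Z_hm) / sqrt(2 (1 - c) / (n - 3))`.
#'
#' @param r_jk,r_hm the two correlations being compared.
#' @param r_jh,r_jm,r_kh,r_km cross-correlations among the four variables.
#' @param n sample size (> 3).
#' @return list with `z`, `p` (two-sided), `c` (pooled covariance term),
#'   `rbar`, `n`.
#' @export
steiger_z <- function(r_jk, r_hm, r_jh, r_jm, r_kh, r_km, n) {
  rs <- c(r_jk, r_hm, r_jh, r_jm, r_kh, r_km)
  if (any(abs(rs) > 1)) stop("correlations must be in [-1, 1]")
  if (abs(r_jk) == 1 || abs(r_hm) == 1)
    stop("|r| = 1: Fisher transform is infinite")
  if (n <= 3) stop("need n > 3")
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- r_jk
  R[1, 3] <- R[3, 1] <- r_jh
  R[1, 4] <- R[4, 1] <- r_jm
  R[2, 3] <- R[3, 2] <- r_kh
  R[2, 4] <- R[4, 2] <- r_km
  R[3, 4] <- R[4, 3] <- r_hm
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    warning("implied 4x4 correlation matrix is not positive semi-definite")

  zf <- function(r) atanh(r)
  rbar <- (r_jk + r_hm) / 2
  # pooled Pearson-Filon covariance with rbar in place of r_jk and r_hm
  psi <- 0.5 * rbar^2 * (r_jh^2 + r_jm^2 + r_kh^2 + r_km^2) +
    r_jh * r_km + r_jm * r_kh -
    rbar * (r_jh * r_jm + r_kh * r_km + r_jh * r_kh + r_jm * r_km)
  c_term <- psi / (1 - rbar^2)^2
  z <- (zf(r_jk) - zf(r_hm)) / sqrt(2 * (1 - c_term) / (n - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)), c = c_term, rbar = rbar, n = n)
}

#' Family-aware mixed-effects map
#'
#' Per voxel, fits `rating ~ bold (+ covariates) + (1 | family)` with both
#' sides standardized, so the fixed-effect coefficient is a standardized
#' beta. Significance is a Wald test on the BOLD fixed effect. When every
#' family is a singleton (or there is a single family) the model degenerates
#' and an OLS fit is used instead, with a warning.
#'
#' @param maps participants x voxels matrix.
#' @param behavior numeric vector.
#' @param family_ids family identifier per participant (no NAs).
#' @param covariates optional data.frame of fixed covariates.
#' @param q_level FDR level.
#' @return a `stat_map` of standardized betas; non-converged voxels are NaN.
#' @export
mixed_effect_map <- function(maps, behavior, family_ids, covariates = NULL,
                             q_level = 0.05) {
  maps <- as.matrix(maps)
  n <- length(behavior)
  if (nrow(maps) != n || length(family_ids) != n)
    stop("maps, behavior and family_ids must agree in length")
  if (anyNA(family_ids)) stop("every participant needs a family id")
  fam <- factor(family_ids)
  degenerate <- nlevels(fam) <= 1L || nlevels(fam) == n
  if (degenerate)
    warning("family structure is degenerate (all singletons or one family); ",
            "falling back to OLS")
  ys <- drop(scale(behavior))
  dat <- data.frame(y = ys, fam = fam)
  cov_terms <- ""
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    covariates <- as.data.frame(covariates)
    for (nmv in names(covariates)) {
      v <- covariates[[nmv]]
      dat[[nmv]] <- if (is.numeric(v)) drop(scale(v)) else factor(v)
    }
    cov_terms <- paste("+", paste(names(covariates), collapse = " + "))
  }
  p_vox <- ncol(maps)
  beta <- rep(NaN, p_vox); pval <- rep(NA_real_, p_vox)
  for (v in seq_len(p_vox)) {
    xv <- maps[, v]
    if (stats::sd(xv) == 0) { pval[v] <- 1; next }
    dat$x <- drop(scale(xv))
    res <- tryCatch({
      if (degenerate) {
        fit <- stats::lm(stats::as.formula(paste("y ~ x", cov_terms)),
                         data = dat)
        co <- summary(fit)$coefficients["x", ]
        list(b = co[["Estimate"]], p = co[["Pr(>|t|)"]])
      } else {
        fit <- lme4::lmer(
          stats::as.formula(paste("y ~ x", cov_terms, "+ (1 | fam)")),
          data = dat, REML = TRUE,
          control = lme4::lmerControl(calc.derivs = FALSE,
                                      check.conv.singular = "ignore"))
        co <- stats::coef(summary(fit))["x", ]
        list(b = co[["Estimate"]], p = 2 * stats::pnorm(-abs(co[["t value"]])))
      }
    }, error = function(e) {
      message("voxel ", v, ": mixed model failed (", conditionMessage(e), ")")
      NULL
    })
    if (!is.null(res)) { beta[v] <- res$b; pval[v] <- res$p }
  }
  testable <- !is.nan(beta)
  adj <- fdr_bh(ifelse(testable, pval, NA_real_), q_level)
  new_stat_map(beta, ifelse(is.na(pval), 1, pval), adj$q, adj$sig,
               list(method = if (degenerate) "ols" else "mixed", n = n,
                    threshold_rule = sprintf("q(FDR) <= %g", q_level),
                    covariates = if (is.null(covariates)) character(0)
                                 else names(covariates)))
}
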