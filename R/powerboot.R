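# Bootstrap estimation of detection probability across sample sizes and the
# minimal sample size reaching a target detection probability.
#
# For each subsample size, participants are drawn with replacement from the
# parent cohort (duplicates kept as-is), the voxelwise correlation is
# computed, and significance is assessed either by BH-FDR within the
# subsample (whole-brain rule) or by a raw alpha (ROI rule). Each
# (size, rep) cell uses its own RNG substream derived from the master seed,
# so any cell is independently reproducible.

.cell_seed <- function(seed, si, ri) {
  as.integer((as.double(seed) * 100003 + si * 7919 + ri) %% 2147483647)
}

#' Detection rule for bootstrap power estimation
#'
#' @param type `"fdr"` (whole-brain: BH within each subsample) or `"alpha"`
#'   (raw per-test threshold, the ROI rule).
#' @param level the q level (fdr) or alpha level.
#' @return a `detection_rule` list.
#' @export
detection_rule <- function(type = c("fdr", "alpha"), level = NULL) {
  type <- match.arg(type)
  if (is.null(level))
    stop("detection rule needs a level (q for 'fdr', alpha for 'alpha')")
  structure(list(type = type, level = level), class = "detection_rule")
}

#' Bootstrap detection probability over a sample-size grid
#'
#' @param maps participants x voxels matrix (voxels or ROI mean signals).
#' @param behavior numeric vector.
#' @param sizes ordered vector of subsample sizes; sizes above the parent n
#'   are permitted (with a warning) since sampling is with replacement.
#' @param reps bootstrap replicates per size.
#' @param rule a [detection_rule()].
#' @param seed master seed.
#' @param method correlation method.
#' @return a `power_surface`: `detect_prob` (voxels x sizes) in `[0,1]`,
#'   plus the grid, rule, reps and seed.
#' @export
bootstrap_detection <- function(maps, behavior, sizes, reps, rule,
                                seed = 1L, method = "pearson") {
  stopifnot(inherits(rule, "detection_rule"), reps >= 1)
  maps <- as.matrix(maps)
  n <- length(behavior)
  if (nrow(maps) != n) stop("maps rows and behavior length differ")
  sizes <- as.integer(sizes)
  if (is.unsorted(sizes)) stop("sizes must be sorted ascending")
  if (max(sizes) > n)
    warning("some subsample sizes exceed the parent n; ",
            "sampling with replacement permits this")
  # spearman ranks must be recomputed inside each subsample, see loop
  counts <- matrix(0, ncol(maps), length(sizes))
  skipped <- 0L
  for (si in seq_along(sizes)) {
    sz <- sizes[si]
    for (ri in seq_len(reps)) {
      set.seed(.cell_seed(seed, si, ri))
      idx <- sample.int(n, sz, replace = TRUE)
      yb <- behavior[idx]
      if (sz < 4 || stats::sd(yb) == 0) {
        skipped <- skipped + 1L
        message("skipping rep (size=", sz, "): fewer than 4 usable samples")
        next
      }
      Xb <- maps[idx, , drop = FALSE]
      if (method == "spearman") {
        Xb <- apply(Xb, 2L, rank); yb <- rank(yb)
      }
      res <- .col_pearson(Xb, yb)
      sig <- if (rule$type == "fdr") {
        fdr_bh(ifelse(is.nan(res$r), NA_real_, res$p), rule$level)$sig
      } else {
        !is.nan(res$r) & res$p <= rule$level
      }
      counts[, si] <- counts[, si] + sig
    }
  }
  structure(list(sizes = sizes, reps = reps,
                 detect_prob = counts / reps, rule = rule, seed = seed,
                 skipped = skipped),
            class = "power_surface")
}

#' Minimal sample size reaching a target detection probability
#'
#' For each voxel/ROI, the smallest tested size whose detection probability
#' reaches `target`; voxels never reaching it are censored (`NA`, flagged
#' `"> max size"`).
#'
#' @param surface a `power_surface`.
#' @param target detection probability in `(0,1)` (default 0.8).
#' @return a `min_sample_map`: `min_n` (NA = censored), `censored` logical,
#'   `target`, `sizes`.
#' @export
min_sample_size <- function(surface, target = 0.8) {
  stopifnot(inherits(surface, "power_surface"))
  if (target <= 0 || target >= 1) stop("target must be in (0, 1)")
  hit <- surface$detect_prob >= target
  first <- apply(hit, 1L, function(h) {
    w <- which(h)
    if (length(w)) w[1] else NA_integer_
  })
  min_n <- ifelse(is.na(first), NA_integer_, surface$sizes[first])
  structure(list(min_n = min_n, censored = is.na(min_n), target = target,
                 sizes = surface$sizes), class = "min_sample_map")
}

#' Summarize a minimal-sample-size map
#'
#' Median, SD and quartiles of `min_n`, computed over an optional subset
#' (typically the voxels significant in the full parent analysis) and
#' excluding censored voxels (flagged in the output).
#'
#' @param msm a `min_sample_map`.
#' @param subset optional logical vector selecting voxels.
#' @return list with `median`, `sd`, `q1`, `q2`, `q3`, `n_detected`,
#'   `n_censored`.
#' @export
min_sample_summary <- function(msm, subset = NULL) {
  stopifnot(inherits(msm, "min_sample_map"))
  v <- msm$min_n
  if (!is.null(subset)) v <- v[subset]
  det <- v[!is.na(v)]
  qs <- if (length(det)) stats::quantile(det, c(0.25, 0.5, 0.75), names = FALSE)
        else rep(NA_real_, 3)
  list(median = if (length(det)) stats::median(det) else NA_real_,
       sd = if (length(det) > 1) stats::sd(det) else NA_real_,
       q1 = qs[1], q2 = qs[2], q3 = qs[3],
       n_detected = length(det), n_censored = sum(is.na(v)))
}

#' Closed-form power of the correlation test (Fisher-z approximation)
#'
#' `Phi(|z(rho)| sqrt(n-3) - z_{1-alpha/2}) +
#'  Phi(-|z(rho)| sqrt(n-3) - z_{1-alpha/2})`; used as the analytic oracle
#' for the bootstrap machinery.
#'
#' @param rho population correlation, `|rho| < 1`.
#' @param n sample size (> 3).
#' @param alpha two-sided significance level.
#' @return detection probability.
#' @export
analytic_power <- function(rho, n, alpha = 0.05) {
  if (any(abs(rho) >= 1)) stop("|rho| must be < 1")
  if (any(n <= 3)) stop("need n > 3")
  zc <- stats::qnorm(1 - alpha / 2)
  zz <- abs(atanh(rho)) * sqrt(n - 3)
  stats::pnorm(zz - zc) + stats::pnorm(-zz - zc)
}

#' ROI power curves across sample sizes and alpha levels
#'
#' Reduces the maps to ROI mean signals, then runs [bootstrap_detection()]
#' with the raw-alpha rule for each requested level.
#'
#' @param maps participants x voxels matrix.
#' @param behavior numeric vector.
#' @param roi_set named list of logical ROI masks over voxels.
#' @param sizes subsample sizes.
#' @param reps replicates per size.
#' @param alphas vector of alpha levels (default the conventional
#'   0.01 and 0.001).
#' @param seed master seed.
#' @return list of `power_surface` objects, one per alpha, each with ROI
#'   rows; plus a long-format `curves` data.frame
#'   (roi, alpha, size, detect_prob).
#' @export
roi_power_curves <- function(maps, behavior, roi_set, sizes, reps,
                             alphas = c(0.01, 0.001), seed = 1L) {
  roi_signals <- vapply(roi_set, function(m) roi_mean_signal(maps, m),
                        numeric(length(behavior)))
  surfaces <- lapply(alphas, function(a)
    bootstrap_detection(roi_signals, behavior, sizes, reps,
                        detection_rule("alpha", a), seed = seed))
  names(surfaces) <- paste0("alpha_", alphas)
  curves <- do.call(rbind, lapply(seq_along(alphas), function(ai) {
    dp <- surfaces[[ai]]$detect_prob
    data.frame(roi = rep(names(roi_set), times = length(sizes)),
               alpha = alphas[ai],
               size = rep(sizes, each = length(roi_set)),
               detect_prob = as.vector(dp))
  }))
  list(surfaces = surfaces, curves = curves)
}
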