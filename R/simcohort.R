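# Synthetic cohort generator.
#
# Emulates a fixed-intensity stimulation design: every participant receives
# physically identical stimuli, so rating variance is between-individual
# ("pain sensitivity" = mean of the trial ratings). Participant contrast maps
# carry a spatially distributed weight pattern linking them to sensitivity,
# plus spatially smoothed Gaussian noise, optional dataset/sex/age confounds,
# twin-family random intercepts, weaker-coupled nonpain modalities, and a
# treatment arm whose rating reduction couples to pattern expression.
# The generative model is linear-Gaussian with clipping at the rating-scale
# bounds; full ground truth is retained for parameter-recovery tests.

#' Labeled Magnitude Scale anchors
#'
#' Verbal anchor positions of the 0-1 Labeled Magnitude Scale used when
#' `rating_scale = "zero_to_one_lms"`; `barely_detectable` (0.014) is the
#' conventional threshold for a barely detectable sensation.
#' @export
lms_anchors <- c(no_pain = 0, barely_detectable = 0.014, weak = 0.061,
                 moderate = 0.172, strong = 0.354, max = 1)

#' Rating-scale clip bounds
#' @param rating_scale `"zero_to_ten"` or `"zero_to_one_lms"`.
#' @return numeric length-2 vector `c(lower, upper)`.
#' @export
rating_bounds <- function(rating_scale) {
  switch(match.arg(rating_scale, c("zero_to_ten", "zero_to_one_lms")),
         zero_to_ten = c(0, 10),
         zero_to_one_lms = c(0, 1))
}

# Sparse Gaussian smoothing operator over a 3-D grid, rows rescaled so that
# smoothing unit-variance white noise yields unit variance at every voxel.
# fwhm in voxel units; fwhm = 0 gives the identity.
build_smoother <- function(grid_shape, fwhm) {
  n_grid <- prod(grid_shape)
  if (fwhm <= 0) return(Matrix::Diagonal(n_grid))
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(2.5 * sigma))
  off <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  w <- exp(-(off$dx^2 + off$dy^2 + off$dz^2) / (2 * sigma^2))
  keep <- w > 1e-4 * max(w)
  off <- off[keep, ]; w <- w[keep]

  d1 <- grid_shape[1]; d2 <- grid_shape[2]; d3 <- grid_shape[3]
  ix <- rep(seq_len(d1), times = d2 * d3)
  iy <- rep(rep(seq_len(d2), each = d1), times = d3)
  iz <- rep(seq_len(d3), each = d1 * d2)
  tri_i <- vector("list", nrow(off))
  tri_j <- vector("list", nrow(off))
  tri_x <- vector("list", nrow(off))
  for (k in seq_len(nrow(off))) {
    sx <- ix + off$dx[k]; sy <- iy + off$dy[k]; sz <- iz + off$dz[k]
    ok <- sx >= 1L & sx <= d1 & sy >= 1L & sy <= d2 & sz >= 1L & sz <= d3
    tri_i[[k]] <- which(ok)
    tri_j[[k]] <- (sz[ok] - 1L) * d1 * d2 + (sy[ok] - 1L) * d1 + sx[ok]
    tri_x[[k]] <- rep(w[k], sum(ok))
  }
  S <- Matrix::sparseMatrix(i = unlist(tri_i), j = unlist(tri_j),
                            x = unlist(tri_x), dims = c(n_grid, n_grid))
  rn <- sqrt(Matrix::rowSums(S^2))
  Matrix::Diagonal(x = 1 / rn) %*% S
}

# n x m matrix of spatially smoothed, unit-variance Gaussian noise restricted
# to the masked voxels; draws from the current RNG stream.
smoothed_noise <- function(n, smoother, mask_idx) {
  n_grid <- ncol(smoother)
  W <- matrix(stats::rnorm(n * n_grid), nrow = n)
  as.matrix(W %*% Matrix::t(smoother[mask_idx, , drop = FALSE]))
}

#' Default analysis mask: an ellipsoid inside the grid
#'
#' @param grid_shape integer 3-vector of voxel counts.
#' @return logical 3-D array.
#' @export
default_mask <- function(grid_shape) {
  ctr <- (grid_shape + 1) / 2
  semi <- 0.9 * (grid_shape / 2 - 0.5)
  ix <- slice.index(array(0, grid_shape), 1)
  iy <- slice.index(array(0, grid_shape), 2)
  iz <- slice.index(array(0, grid_shape), 3)
  d <- ((ix - ctr[1]) / semi[1])^2 + ((iy - ctr[2]) / semi[2])^2 +
    ((iz - ctr[3]) / semi[3])^2
  array(d <= 1, grid_shape)
}

#' Simulation configuration
#'
#' Assembles and validates the knobs of the synthetic-cohort generator.
#' Defaults describe a clean single-site cohort: confound effects and the
#' family intraclass correlation are zero (opt-in), sensitivity is
#' 4.5 +/- 1.7 on a 0-10 scale, 10 trials per condition, and the per-voxel
#' explainable variance at signal voxels is 0.16 (peak brain-behavior
#' correlations around 0.4).
#'
#' @param n_participants cohort size.
#' @param grid_shape 3-vector of voxel counts; maps live on the ellipsoidal
#'   mask inside it (see [default_mask()]).
#' @param n_trials stimuli per condition; sensitivity is the mean rating.
#' @param modalities named numeric vector of coupling strengths in `[0,1]`;
#'   the first entry is the pain condition and should be 1.
#' @param sensitivity_mean,sensitivity_sd population mean / SD of sensitivity
#'   in rating-scale units.
#' @param rating_scale `"zero_to_ten"` or `"zero_to_one_lms"`; ratings are
#'   clipped to the scale bounds.
#' @param pattern_density fraction of mask voxels with nonzero true weight.
#' @param smoothness_fwhm Gaussian FWHM (voxels) of the spatial noise and of
#'   the weight-pattern field.
#' @param explainable_r2 target fraction of map variance attributable to
#'   sensitivity at an RMS-weight signal voxel, in `[0,1)` (0.16 gives peak
#'   brain-behavior correlations around 0.4).
#' @param signature_r2 optional whole-map target: the R2 of the true-pattern
#'   expression (dot-product signature built from the generative weights) for
#'   sensitivity. Attained by adding pattern-expression nuisance -- the
#'   signal pattern's amplitude varies across individuals for reasons other
#'   than trait sensitivity (state effects), which caps multivariate
#'   performance below the aggregated per-voxel signal. The default 0.25
#'   pairs with `explainable_r2 = 0.16` to emulate cohorts whose peak voxel
#'   correlation is about 0.4 while a multivariate signature explains about
#'   a quarter of the sensitivity variance. `NULL` adds no expression
#'   nuisance (whole-map signal then aggregates far beyond the per-voxel
#'   level).
#' @param confounds list with `dataset_shift`, `sex_effect` (rating units) and
#'   `age_slope` (rating units per year), applied to sensitivity; the same
#'   strengths scale spatial confound patterns added to the maps via
#'   `map_confound_gain`.
#' @param map_confound_gain map-units amplitude of the spatial confound
#'   leakage pattern per rating-unit of confound strength.
#' @param family list with `n_families` (NULL = all singletons) and `icc`
#'   intraclass correlation in `[0,1)`; families share a random intercept on
#'   sensitivity.
#' @param treatment_coupling default correlation used by
#'   [simulate_treatment()], in `[-1,1]`.
#' @param trial_noise_sd SD of the trial-to-trial rating deviation
#'   (rating units).
#' @param trial_maps logical; also generate per-trial pain maps driven by the
#'   same trial-level state that perturbs the ratings.
#' @param seed integer master seed; identical config + seed gives
#'   bit-identical cohorts.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_participants = 200,
                              grid_shape = c(12L, 12L, 12L),
                              n_trials = 10,
                              modalities = c(pain = 1),
                              sensitivity_mean = 4.5,
                              sensitivity_sd = 1.7,
                              rating_scale = "zero_to_ten",
                              pattern_density = 0.2,
                              smoothness_fwhm = 2,
                              explainable_r2 = 0.16,
                              signature_r2 = 0.25,
                              confounds = list(dataset_shift = 0,
                                               sex_effect = 0,
                                               age_slope = 0),
                              map_confound_gain = 0.5,
                              family = list(n_families = NULL, icc = 0),
                              treatment_coupling = 0.5,
                              trial_noise_sd = 1,
                              trial_maps = FALSE,
                              seed = 1L) {
  stopifnot(n_participants >= 2, length(grid_shape) == 3, all(grid_shape >= 2),
            n_trials >= 1, sensitivity_sd > 0, trial_noise_sd >= 0)
  rating_scale <- match.arg(rating_scale, c("zero_to_ten", "zero_to_one_lms"))
  if (pattern_density <= 0 || pattern_density > 1)
    stop("pattern_density must be in (0, 1]")
  if (explainable_r2 < 0 || explainable_r2 >= 1)
    stop("explainable_r2 must be in [0, 1)")
  if (!is.null(signature_r2) && (signature_r2 <= 0 || signature_r2 >= 1))
    stop("signature_r2 must be in (0, 1)")
  if (!is.null(signature_r2) && signature_r2 <= explainable_r2)
    stop("signature_r2 must exceed explainable_r2 ",
         "(the whole-map signal cannot explain less than one voxel does)")
  icc <- family$icc %||% 0
  if (icc < 0 || icc >= 1) stop("family icc must be in [0, 1)")
  if (abs(treatment_coupling) > 1)
    stop("treatment_coupling must be in [-1, 1]")
  cf <- utils::modifyList(list(dataset_shift = 0, sex_effect = 0,
                               age_slope = 0), confounds)
  mask <- default_mask(grid_shape)
  n_signal <- round(pattern_density * sum(mask))
  if (prod(grid_shape) < 2 * n_signal)
    stop("grid too small for the requested pattern density")
  structure(list(n_participants = as.integer(n_participants),
                 grid_shape = as.integer(grid_shape),
                 n_trials = as.integer(n_trials),
                 modalities = modalities,
                 sensitivity_mean = sensitivity_mean,
                 sensitivity_sd = sensitivity_sd,
                 rating_scale = rating_scale,
                 pattern_density = pattern_density,
                 smoothness_fwhm = smoothness_fwhm,
                 explainable_r2 = explainable_r2,
                 signature_r2 = signature_r2,
                 confounds = cf,
                 map_confound_gain = map_confound_gain,
                 family = list(n_families = family$n_families, icc = icc),
                 treatment_coupling = treatment_coupling,
                 trial_noise_sd = trial_noise_sd,
                 trial_maps = isTRUE(trial_maps),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a spatially structured sparse weight pattern
#'
#' Smooths a white-noise field with a Gaussian kernel and keeps the
#' `density` fraction of voxels with the largest absolute field values, so
#' nonzero weights form smooth signed clusters. Nonzero weights are rescaled
#' to unit root-mean-square.
#'
#' @param grid_shape 3-vector of voxel counts.
#' @param pattern_density fraction of (masked) voxels with nonzero weight,
#'   in `(0,1]`.
#' @param smoothness_fwhm Gaussian FWHM in voxels; 0 gives spatially
#'   independent weights.
#' @param seed optional integer; if `NULL` the current RNG stream is used.
#' @param mask optional logical array; default: all grid voxels.
#' @return numeric vector of weights over the mask voxels.
#' @export
generate_weight_pattern <- function(grid_shape, pattern_density,
                                    smoothness_fwhm, seed = NULL,
                                    mask = NULL) {
  if (pattern_density <= 0 || pattern_density > 1)
    stop("pattern_density must be in (0, 1]")
  if (smoothness_fwhm < 0) stop("smoothness_fwhm must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(mask)) mask <- array(TRUE, grid_shape)
  mask_idx <- which(mask)
  m <- length(mask_idx)
  k <- round(pattern_density * m)
  if (k < 1) stop("empty pattern: pattern_density x n_voxels < 1")
  S <- build_smoother(grid_shape, smoothness_fwhm)
  field <- drop(smoothed_noise(1L, S, mask_idx))
  a <- numeric(m)
  sel <- order(abs(field), decreasing = TRUE)[seq_len(k)]
  a[sel] <- field[sel]
  a / sqrt(mean(a[sel]^2))
}

# Population SD of the sensitivity driver (base + confound contributions).
# Ages are uniform on [18, 60]; datasets and sexes are balanced.
.drive_sd <- function(config) {
  cf <- config$confounds
  sqrt(config$sensitivity_sd^2 + 0.25 * cf$dataset_shift^2 +
         0.25 * cf$sex_effect^2 + cf$age_slope^2 * (60 - 18)^2 / 12)
}

#' Simulate a synthetic cohort with ground truth
#'
#' Draws participant sensitivities (with optional dataset/sex/age confounds
#' and family random intercepts), per-trial ratings clipped to the scale
#' bounds, and per-modality contrast maps
#' `x_iv = a_v (t_i - mu) + confound patterns + sigma_n * smoothed noise`,
#' where the noise scale `sigma_n` is set from `explainable_r2` (see
#' [simulation_config()]). Nonpain modalities couple to sensitivity with
#' their configured strength.
#'
#' @param config a [simulation_config()].
#' @return object of class `cohort_bundle`: per-modality map matrices
#'   (participants x mask voxels), behavior tables (trial-level and
#'   participant-level), mask + affine, and a `ground_truth` list with
#'   `latent_sensitivity`, `true_weights`, `true_voxel_correlation`,
#'   `true_explainable_r2`, `expression_r2` (attained R2 of the true-pattern
#'   expression), `optimal_readout_r2` (R2 of the generalized-least-squares
#'   optimal readout), `noise_sd`, `expression_noise_sd`, `drive_sd`,
#'   `family_variance`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_participants
  mu <- config$sensitivity_mean
  sd_s <- config$sensitivity_sd
  bounds <- rating_bounds(config$rating_scale)
  mask <- default_mask(config$grid_shape)
  mask_idx <- which(mask)
  m <- length(mask_idx)

  a <- generate_weight_pattern(config$grid_shape, config$pattern_density,
                               config$smoothness_fwhm, seed = NULL,
                               mask = mask)

  # demographics and confounded sensitivity
  dataset <- rep(c("dataset1", "dataset2"), length.out = n)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  age <- round(stats::runif(n, 18, 60))
  icc <- config$family$icc
  n_fam <- config$family$n_families %||% n
  n_fam <- min(n_fam, n)
  family_id <- rep(seq_len(n_fam), length.out = n)
  u_f <- stats::rnorm(n_fam, 0, sqrt(icc) * sd_s)
  e_i <- stats::rnorm(n, 0, sqrt(1 - icc) * sd_s)
  cf <- config$confounds
  s <- mu + cf$dataset_shift * (dataset == "dataset2") +
    cf$sex_effect * (sex == "M") + cf$age_slope * (age - 39) +
    u_f[family_id] + e_i

  # noise scales from the explainable-variance targets
  drive_sd <- .drive_sd(config)
  S <- build_smoother(config$grid_shape, config$smoothness_fwhm)
  r2 <- config$explainable_r2
  signal_on <- r2 > 0 && any(a != 0)
  aCinva <- aCa <- 0
  if (signal_on) {
    C <- as.matrix(Matrix::tcrossprod(S[mask_idx, , drop = FALSE]))
    aCinva <- drop(crossprod(a, solve(C, a)))
    aCa <- drop(crossprod(a, C %*% a))
  }
  a_eff <- if (signal_on) a else numeric(m)
  # Solve for the voxel-noise SD sigma_n and the pattern-expression nuisance
  # SD gamma (amplitude of the signal pattern varying for reasons other than
  # trait sensitivity, e.g. state effects). At an RMS-weight signal voxel the
  # sensitivity-attributable variance share must equal explainable_r2:
  #   sd^2 / (sd^2 + gamma^2 + sigma_n^2) = r2
  # and, if requested, the true-pattern expression R2 must equal signature_r2:
  #   sd^2 / (sd^2 + gamma^2 + sigma_n^2 k) = rg,  k = a'Ca / (a'a)^2.
  gamma <- 0
  sigma_n <- if (signal_on) drive_sd * sqrt((1 - r2) / r2) else 1
  if (signal_on && !is.null(config$signature_r2)) {
    rg <- config$signature_r2
    k <- aCa / sum(a^2)^2
    T_tot <- drive_sd^2 * (1 - r2) / r2
    G_tot <- drive_sd^2 * (1 - rg) / rg
    sn2 <- (T_tot - G_tot) / (1 - k)
    g2 <- T_tot - sn2
    if (rg <= r2 || sn2 <= 0 || g2 < 0)
      stop("signature_r2 must exceed explainable_r2 and be attainable ",
           "given the noise smoothness (got explainable_r2 = ", r2,
           ", signature_r2 = ", rg, ")")
    sigma_n <- sqrt(sn2)
    gamma <- sqrt(g2)
  }
  var_amp <- drive_sd^2 + gamma^2            # variance of pattern amplitude
  q_opt <- if (signal_on)
    drive_sd^2 / (gamma^2 + 1 / pmax(aCinva / sigma_n^2, 1e-12)) else 0
  q_expr <- if (signal_on && aCa > 0)
    drive_sd^2 / (gamma^2 + sigma_n^2 * aCa / sum(a^2)^2) else 0
  rho_v <- a_eff * drive_sd / sqrt(a_eff^2 * var_amp + sigma_n^2)

  # confound leakage patterns on the maps
  conf_map <- matrix(0, n, m)
  if (cf$dataset_shift != 0) {
    g <- drop(smoothed_noise(1L, S, mask_idx))
    conf_map <- conf_map + outer((dataset == "dataset2") * 1,
                                 g * cf$dataset_shift * config$map_confound_gain)
  }
  if (cf$sex_effect != 0) {
    g <- drop(smoothed_noise(1L, S, mask_idx))
    conf_map <- conf_map + outer((sex == "M") * 1,
                                 g * cf$sex_effect * config$map_confound_gain)
  }
  if (cf$age_slope != 0) {
    g <- drop(smoothed_noise(1L, S, mask_idx))
    conf_map <- conf_map + outer((age - 39) / sqrt((60 - 18)^2 / 12),
                                 g * cf$age_slope * config$map_confound_gain)
  }

  clip <- function(x) pmin(pmax(x, bounds[1]), bounds[2])
  mods <- config$modalities
  maps <- vector("list", length(mods)); names(maps) <- names(mods)
  trial_ratings <- vector("list", length(mods)); names(trial_ratings) <- names(mods)
  mean_rating <- matrix(NA_real_, n, length(mods),
                        dimnames = list(NULL, names(mods)))
  trial_maps <- NULL
  for (j in seq_along(mods)) {
    cpl <- mods[j]
    t_m <- if (cpl == 1) s else
      mu + cpl * (s - mu) + sqrt(1 - cpl^2) * drive_sd * stats::rnorm(n)
    eps <- matrix(stats::rnorm(n * config$n_trials, 0, config$trial_noise_sd),
                  n, config$n_trials)
    tr <- clip(t_m + eps)
    trial_ratings[[j]] <- tr
    mean_rating[, j] <- rowMeans(tr)
    amp <- t_m - mu + gamma * stats::rnorm(n)
    maps[[j]] <- outer(amp, a_eff) + conf_map +
      sigma_n * smoothed_noise(n, S, mask_idx)
    if (j == 1L && config$trial_maps) {
      trial_maps <- array(NA_real_, c(n, config$n_trials, m))
      for (tt in seq_len(config$n_trials)) {
        trial_maps[, tt, ] <- outer(amp + eps[, tt], a_eff) +
          sigma_n * smoothed_noise(n, S, mask_idx)
      }
    }
  }

  behavior <- do.call(rbind, lapply(seq_along(mods), function(j) {
    data.frame(participant_id = rep(sprintf("sub-%04d", seq_len(n)),
                                    times = config$n_trials),
               dataset = rep(dataset, times = config$n_trials),
               sex = rep(sex, times = config$n_trials),
               age = rep(age, times = config$n_trials),
               family_id = rep(family_id, times = config$n_trials),
               condition = names(mods)[j],
               trial_index = rep(seq_len(config$n_trials), each = n),
               rating = as.vector(trial_ratings[[j]]))
  }))
  participants <- data.frame(participant_id = sprintf("sub-%04d", seq_len(n)),
                             dataset = dataset, sex = sex, age = age,
                             family_id = family_id)
  participants$sensitivity <- mean_rating[, 1]
  for (j in seq_along(mods))
    participants[[paste0("mean_", names(mods)[j])]] <- mean_rating[, j]

  ground_truth <- structure(list(
    latent_sensitivity = s,
    true_weights = a_eff,
    true_voxel_correlation = rho_v,
    true_explainable_r2 = if (signal_on) r2 else 0,
    expression_r2 = q_expr / (1 + q_expr),
    optimal_readout_r2 = q_opt / (1 + q_opt),
    noise_sd = sigma_n,
    expression_noise_sd = gamma,
    drive_sd = drive_sd,
    family_variance = icc * sd_s^2,
    treatment_coupling_true = NA_real_), class = "ground_truth")

  structure(list(maps = maps, trial_maps = trial_maps,
                 trial_ratings = trial_ratings[[1]],
                 behavior = behavior, participants = participants,
                 mask = mask, mask_idx = mask_idx, affine = diag(4),
                 grid_shape = config$grid_shape,
                 ground_truth = ground_truth, config = config),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("<cohort_bundle>", x$config$n_participants, "participants,",
      length(x$mask_idx), "mask voxels,",
      paste0(length(x$maps), " modalit",
             if (length(x$maps) == 1) "y" else "ies"),
      "\n  sensitivity:",
      sprintf("%.2f +/- %.2f", mean(x$participants$sensitivity),
              stats::sd(x$participants$sensitivity)),
      sprintf("(scale %s)\n", x$config$rating_scale))
  invisible(x)
}

#' Simulate a treatment arm
#'
#' Adds pre/post ratings and post-treatment maps to a cohort. The treatment
#' removes `m_i ~ N(effect_mean, effect_sd^2)` units of the true pattern from
#' each participant's map (plus fresh smoothed noise), and the rating
#' reduction is constructed to correlate with the realized true-pattern
#' expression of the difference maps at exactly `treatment_coupling` in the
#' population.
#'
#' @param bundle a `cohort_bundle`.
#' @param treatment_coupling correlation in `[-1,1]`; default from the
#'   bundle's config.
#' @param seed integer seed for the treatment draws.
#' @param effect_mean,effect_sd mean/SD of the map-pattern treatment effect;
#'   `effect_mean = 0, effect_sd = 0, treatment_coupling = 0` gives an
#'   untreated arm (post = pre + noise).
#' @param reduction_sd SD of the rating reduction (rating units).
#' @param modality which modality's maps to treat (default the first).
#' @return the bundle with a `treatment` element (`pre_ratings`,
#'   `post_ratings`, `reduction`, `post_maps`, `diff_maps`) and
#'   `treatment_coupling_true` filled in.
#' @export
simulate_treatment <- function(bundle, treatment_coupling = NULL, seed = 1L,
                               effect_mean = 1, effect_sd = 0.5,
                               reduction_sd = 0.5, modality = 1L) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  cpl <- treatment_coupling %||% bundle$config$treatment_coupling
  if (abs(cpl) > 1) stop("treatment_coupling must be in [-1, 1]")
  set.seed(seed)
  cfg <- bundle$config
  n <- cfg$n_participants
  m <- length(bundle$mask_idx)
  a <- bundle$ground_truth$true_weights
  sigma_n <- bundle$ground_truth$noise_sd
  S <- build_smoother(cfg$grid_shape, cfg$smoothness_fwhm)

  m_i <- stats::rnorm(n, effect_mean, effect_sd)
  D <- outer(m_i, a) + sigma_n * smoothed_noise(n, S, bundle$mask_idx)
  expr <- drop(D %*% a)
  red_z <- if (cpl != 0 && stats::sd(expr) > 0) {
    cpl * drop(scale(expr)) + sqrt(1 - cpl^2) * stats::rnorm(n)
  } else {
    stats::rnorm(n)
  }
  reduction <- effect_mean + reduction_sd * red_z
  bounds <- rating_bounds(cfg$rating_scale)
  pre <- bundle$participants[[paste0("mean_", names(cfg$modalities)[modality])]]
  post <- pmin(pmax(pre - reduction, bounds[1]), bounds[2])

  bundle$treatment <- list(pre_ratings = pre, post_ratings = post,
                           reduction = pre - post,
                           post_maps = bundle$maps[[modality]] - D,
                           diff_maps = D, coupling = cpl, seed = seed)
  bundle$ground_truth$treatment_coupling_true <- cpl
  bundle
}

#' Write a cohort to disk as NIfTI + CSV + JSON
#'
#' One float32 NIfTI volume per participant per modality
#' (`sub-0001_pain.nii`), a uint8 mask sharing the affine, trial-level
#' `behavior.csv`, participant-level `participants.csv`, the true-weight
#' volume (float64, bit-exact round trip), and JSON sidecars for the
#' ground-truth scalars and the config.
#'
#' @param bundle a `cohort_bundle`.
#' @param dir output directory (created if needed).
#' @param overwrite overwrite an existing fixture directory?
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(bundle, dir, overwrite = FALSE) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite)
    stop("fixture directory ", dir, " exists; use overwrite = TRUE")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- bundle$grid_shape
  embed <- function(v) {
    vol <- array(0, grid); vol[bundle$mask_idx] <- v; vol
  }
  for (mod in names(bundle$maps)) {
    X <- bundle$maps[[mod]]
    for (i in seq_len(nrow(X)))
      write_nifti(embed(X[i, ]),
                  file.path(dir, sprintf("sub-%04d_%s.nii", i, mod)),
                  affine = bundle$affine, datatype = "float32")
  }
  write_nifti(bundle$mask, file.path(dir, "mask.nii"),
              affine = bundle$affine, datatype = "uint8")
  write_nifti(embed(bundle$ground_truth$true_weights),
              file.path(dir, "true_weights.nii"),
              affine = bundle$affine, datatype = "float64")
  utils::write.csv(bundle$behavior, file.path(dir, "behavior.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$participants, file.path(dir, "participants.csv"),
                   row.names = FALSE)
  gt <- bundle$ground_truth
  scalars <- gt[setdiff(names(gt), c("true_weights", "true_voxel_correlation",
                                     "latent_sensitivity"))]
  jsonlite::write_json(scalars, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- unclass(bundle$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort fixture written by [write_fixture()]
#'
#' @param dir fixture directory.
#' @return list with `maps` (per-modality matrices), `behavior`,
#'   `participants`, `mask`, `mask_idx`, `affine`, `true_weights`,
#'   `ground_truth` scalars, and the stored `config` list.
#' @export
read_fixture <- function(dir) {
  mask_img <- read_nifti(file.path(dir, "mask.nii"))
  mask <- mask_img$data != 0
  mask_idx <- which(mask)
  files <- list.files(dir, pattern = "^sub-.*\\.nii$")
  mods <- unique(sub("^sub-[0-9]+_(.*)\\.nii$", "\\1", files))
  maps <- lapply(mods, function(mod) {
    fs <- sort(list.files(dir, pattern = sprintf("^sub-[0-9]+_%s\\.nii$", mod),
                          full.names = TRUE))
    st <- read_map_stack(fs, mask = mask)
    st$maps
  })
  names(maps) <- mods
  tw <- read_nifti(file.path(dir, "true_weights.nii"))$data[mask_idx]
  list(maps = maps,
       behavior = utils::read.csv(file.path(dir, "behavior.csv")),
       participants = utils::read.csv(file.path(dir, "participants.csv")),
       mask = mask, mask_idx = mask_idx, affine = mask_img$affine,
       true_weights = tw,
       ground_truth = jsonlite::read_json(file.path(dir, "ground_truth.json"),
                                          simplifyVector = TRUE),
       config = jsonlite::read_json(file.path(dir, "config.json"),
                                    simplifyVector = TRUE))
}
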