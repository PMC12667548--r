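# I/O and pipeline plumbing: NIfTI map stacks, stat-map serialization,
# behavior tables, and a manifest-writing pipeline runner.
#
# Voxel ordering convention: masked vectorization follows R's column-major
# array order (first axis fastest-varying), i.e. `volume[mask_idx]` with
# `mask_idx = which(mask)`. All voxel indices are 1-based internally (R
# convention); world coordinates only ever come from the affine.

#' Read a stack of NIfTI maps into a participants x voxels matrix
#'
#' @param paths character vector of NIfTI files, one per participant, in
#'   row order.
#' @param mask optional logical array; defaults to all voxels. All files
#'   must share the mask's grid and affine (tolerance 1e-4 on affine
#'   entries).
#' @return list with `maps` (matrix), `mask`, `mask_idx`, `affine`, `paths`.
#' @export
read_map_stack <- function(paths, mask = NULL) {
  if (length(paths) == 0) stop("no map files given")
  first <- read_nifti(paths[1])
  if (is.null(mask)) mask <- array(TRUE, dim(first$data))
  if (!all(dim(mask) == dim(first$data)))
    stop("mask grid does not match ", paths[1])
  mask_idx <- which(mask)
  maps <- matrix(NA_real_, length(paths), length(mask_idx))
  affine <- first$affine
  maps[1, ] <- first$data[mask_idx]
  for (i in seq_along(paths)[-1]) {
    img <- read_nifti(paths[i])
    if (!all(dim(img$data) == dim(mask)))
      stop("grid mismatch in ", paths[i])
    if (max(abs(img$affine - affine)) > 1e-4)
      stop("affine mismatch in ", paths[i])
    maps[i, ] <- img$data[mask_idx]
  }
  list(maps = maps, mask = mask, mask_idx = mask_idx, affine = affine,
       paths = paths)
}

#' Write a masked statistic vector as a NIfTI volume
#'
#' Out-of-mask voxels are written as 0 (or `NA` as NaN inside the mask,
#' e.g. censored minimal-sample-size voxels).
#'
#' @param values numeric vector over mask voxels.
#' @param mask logical array.
#' @param affine 4x4 matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stat_map <- function(values, mask, affine, path) {
  mask_idx <- which(mask)
  if (length(values) != length(mask_idx))
    stop("value vector length does not match mask voxel count")
  vol <- array(0, dim(mask))
  vol[mask_idx] <- ifelse(is.na(values), NaN, values)
  write_nifti(vol, path, affine = affine, datatype = "float32")
}

#' Validate and summarize a trial-level behavior table
#'
#' Checks the (participant_id, condition, trial_index) key for uniqueness,
#' flags missing sex/age before imputation, and returns the per-condition
#' mean ratings ("sensitivity" for the pain condition).
#'
#' @param behavior data.frame with columns participant_id, dataset, sex,
#'   age, family_id, condition, trial_index, rating.
#' @return list with `behavior` (validated table), `participants`
#'   (one row per participant with per-condition mean ratings), and
#'   `n_missing` (count of missing sex/age values).
#' @export
behavior_table <- function(behavior) {
  need <- c("participant_id", "dataset", "sex", "age", "family_id",
            "condition", "trial_index", "rating")
  miss <- setdiff(need, names(behavior))
  if (length(miss)) stop("behavior table lacks columns: ",
                         paste(miss, collapse = ", "))
  key <- paste(behavior$participant_id, behavior$condition,
               behavior$trial_index)
  if (anyDuplicated(key)) stop("duplicate (participant, condition, trial) keys")
  if (anyNA(behavior$family_id)) stop("every participant needs a family id")
  n_missing <- sum(is.na(behavior$sex)) + sum(is.na(behavior$age))
  agg <- stats::aggregate(rating ~ participant_id + condition,
                          data = behavior, FUN = mean)
  wide <- stats::reshape(agg, idvar = "participant_id",
                         timevar = "condition", direction = "wide")
  names(wide) <- sub("^rating\\.", "mean_", names(wide))
  demo <- unique(behavior[, c("participant_id", "dataset", "sex", "age",
                              "family_id")])
  participants <- merge(demo, wide, by = "participant_id", sort = TRUE)
  list(behavior = behavior, participants = participants,
       n_missing = n_missing)
}

.stage_seed <- function(master, stage) {
  as.integer((as.double(master) * 48271 +
                sum(utf8ToInt(stage))) %% 2147483647)
}

#' Run a simulate / map / power / fit pipeline and write a manifest
#'
#' Executes the requested stages on a synthetic cohort and writes all
#' outputs plus `manifest.json` (config snapshot, master seed, per-stage
#' substream seeds, package version, output file digests, timestamps) to
#' `out_dir`. Rerunning with the same config and seed reproduces every
#' output bit-identically.
#'
#' @param config a [simulation_config()] (its `seed` is the master seed).
#' @param out_dir output directory.
#' @param stages subset of `c("simulate", "map", "power", "fit")`; stages
#'   build on the simulated cohort.
#' @param q_level FDR level for the map stage.
#' @param power_sizes,power_reps grid for the power stage (kept small by
#'   default; the conventional whole-brain grid is 100:400 step 10 with 100
#'   reps).
#' @param lambda_grid,n_folds settings for the fit stage.
#' @param overwrite overwrite an existing output directory?
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "map"),
                         q_level = 0.05,
                         power_sizes = seq(50, 200, by = 50),
                         power_reps = 20,
                         lambda_grid = lambda_grid_default(20),
                         n_folds = 5, overwrite = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  known <- c("simulate", "map", "power", "fit")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage name(s): ", paste(bad, collapse = ", "))
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite)
    stop("output directory ", out_dir, " exists; use overwrite = TRUE")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(package = "painsig",
                   version = as.character(utils::packageVersion("painsig")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   master_seed = config$seed,
                   stage_seeds = lapply(stats::setNames(known, known),
                                        function(s) .stage_seed(config$seed, s)),
                   config = unclass(config),
                   stages = stages, outputs = character(0))
  flush_manifest <- function(partial = FALSE) {
    manifest$partial <<- partial
    manifest$finished <<- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    files <- manifest$outputs
    manifest$digests <<- as.list(tools::md5sum(file.path(out_dir, files)))
    names(manifest$digests) <<- files
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  add_output <- function(f) manifest$outputs <<- c(manifest$outputs, f)

  bundle <- NULL
  result <- tryCatch({
    message("[painsig] stage simulate")
    bundle <- simulate_cohort(config)
    if ("simulate" %in% stages) {
      write_fixture(bundle, file.path(out_dir, "cohort"), overwrite = TRUE)
      for (f in list.files(file.path(out_dir, "cohort")))
        add_output(file.path("cohort", f))
    }
    if ("map" %in% stages) {
      message("[painsig] stage map")
      sm <- voxelwise_correlation(bundle$maps[[1]],
                                  bundle$participants$sensitivity,
                                  q_level = q_level)
      write_stat_map(sm$statistic, bundle$mask, bundle$affine,
                     file.path(out_dir, "map_r.nii"))
      write_stat_map(sm$p, bundle$mask, bundle$affine,
                     file.path(out_dir, "map_p.nii"))
      write_stat_map(ifelse(is.na(sm$q), 1, sm$q), bundle$mask,
                     bundle$affine, file.path(out_dir, "map_q.nii"))
      write_stat_map(as.numeric(sm$sig_mask), bundle$mask, bundle$affine,
                     file.path(out_dir, "map_sig.nii"))
      for (f in c("map_r.nii", "map_p.nii", "map_q.nii", "map_sig.nii"))
        add_output(f)
    }
    if ("power" %in% stages) {
      message("[painsig] stage power")
      surf <- bootstrap_detection(bundle$maps[[1]],
                                  bundle$participants$sensitivity,
                                  power_sizes, power_reps,
                                  detection_rule("fdr", q_level),
                                  seed = .stage_seed(config$seed, "power"))
      msm <- min_sample_size(surf)
      write_stat_map(ifelse(is.na(msm$min_n), NA, msm$min_n), bundle$mask,
                     bundle$affine, file.path(out_dir, "min_sample_size.nii"))
      jsonlite::write_json(min_sample_summary(msm),
                           file.path(out_dir, "power_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      add_output("min_sample_size.nii"); add_output("power_summary.json")
    }
    if ("fit" %in% stages) {
      message("[painsig] stage fit")
      model <- fit_lasso_pcr(bundle$maps[[1]],
                             bundle$participants$sensitivity,
                             lambda_grid = lambda_grid, n_folds = n_folds,
                             seed = .stage_seed(config$seed, "fit"),
                             nested = FALSE)
      write_stat_map(model$voxel_weights, bundle$mask, bundle$affine,
                     file.path(out_dir, "signature_weights.nii"))
      jsonlite::write_json(
        list(constant = model$weight_constant, lambda = model$lambda,
             n = model$n, seed = model$seed, format_version = 1L,
             cv_r = model$cv$pearson_r, cv_r2 = model$cv$r_squared,
             voxel_means = model$voxel_means, voxel_sds = model$voxel_sds),
        file.path(out_dir, "signature.json"), auto_unbox = TRUE, digits = NA)
      add_output("signature_weights.nii"); add_output("signature.json")
    }
    flush_manifest(partial = FALSE)
    manifest
  }, error = function(e) {
    flush_manifest(partial = TRUE)
    stop("pipeline aborted (partial manifest flushed): ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(result)
}
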