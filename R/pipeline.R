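#' Pipeline configuration
#'
#' A single configuration object tying the pipeline stages together:
#' frame rate, autocorrelation lag grid, OKS constants, test settings,
#' missing-data policy, cohort size and master seed. Round-trips
#' losslessly through YAML via [write_pipeline_config()] /
#' [read_pipeline_config()].
#'
#' @param fps Frames per second (default 30).
#' @param lags_s Autocorrelation lag grid in seconds
#'   (default 1, 2, 3, 5, 7, 11, 13).
#' @param oks_s,oks_k,oks_variant,oks_normalize OKS settings (see
#'   [oks_config()]).
#' @param alpha Per-cell significance level (default 0.05).
#' @param var_equal Pooled Student t if `TRUE` (default), Welch otherwise.
#' @param min_confidence,max_gap Missing-data policy (see
#'   [angle_timeseries()]).
#' @param n_per_group Cohort size per class for simulation (default 5).
#' @param master_seed Master seed for simulation (default 1).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(fps = 30, lags_s = c(1, 2, 3, 5, 7, 11, 13),
                            oks_s = 1, oks_k = 0.001,
                            oks_variant = "paper", oks_normalize = "none",
                            alpha = 0.05, var_equal = TRUE,
                            min_confidence = 0, max_gap = 5,
                            n_per_group = 5, master_seed = 1) {
  cfg <- list(fps = fps, lags_s = lags_s,
              oks_s = oks_s, oks_k = oks_k, oks_variant = oks_variant,
              oks_normalize = oks_normalize,
              alpha = alpha, var_equal = var_equal,
              min_confidence = min_confidence, max_gap = max_gap,
              n_per_group = n_per_group, master_seed = master_seed)
  stopifnot(cfg$fps > 0, all(cfg$lags_s >= 0), cfg$alpha > 0, cfg$alpha < 1)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Simulate a cohort and write it to disk
#'
#' Stage-one entry point: generates a labelled synthetic cohort under the
#' configuration and writes one time-series CSV per subject plus a
#' `manifest.csv` recording labels, per-subject seeds and jittered
#' parameters.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return The [generate_cohort()] result, invisibly; files on disk as a
#'   side effect.
#' @export
run_simulate <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$n_per_group < 1)
    stop("n_per_group must be >= 1", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  cohort <- generate_cohort(
    n_per_group = config$n_per_group,
    params_normal = movement_params("normal", fps = config$fps),
    params_cs = movement_params("cramped_synchronized", fps = config$fps),
    master_seed = config$master_seed)
  for (s in cohort$sequences)
    write_timeseries_csv(s, file.path(out_dir, paste0(s$subject_id, ".csv")))
  utils::write.csv(cohort$manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  write_pipeline_config(config, file.path(out_dir, "config.yaml"))
  invisible(cohort)
}

#' Extract angle and autocorrelation features from sequence files
#'
#' Stage-two entry point: reads pose-sequence CSVs (optionally resolving
#' labels from a cohort `manifest.csv` in the same directory), computes the
#' eight joint-angle series and their autocorrelation profiles, and writes
#' `angles.csv` and `acf_features.csv` in tidy long format.
#'
#' @param config A [pipeline_config()].
#' @param inputs Character vector of sequence CSV paths, or a directory
#'   containing them (with an optional `manifest.csv`).
#' @param out_dir Output directory.
#' @return List with the two data frames (`angles`, `features`), invisibly.
#' @export
run_features <- function(config = pipeline_config(), inputs, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- NULL
  if (length(inputs) == 1L && dir.exists(inputs)) {
    mf <- file.path(inputs, "manifest.csv")
    if (file.exists(mf)) manifest <- utils::read.csv(mf)
    inputs <- list.files(inputs, pattern = "\\.csv$", full.names = TRUE)
    inputs <- inputs[!basename(inputs) %in% "manifest.csv"]
  }
  if (!length(inputs)) stop("no input sequences given", call. = FALSE)
  seqs <- lapply(inputs, function(p) {
    sid <- sub("\\.csv$", "", basename(p))
    lab <- "unknown"
    if (!is.null(manifest) && sid %in% manifest$subject)
      lab <- manifest$gma_label[match(sid, manifest$subject)]
    read_timeseries_csv(p, fps = config$fps, subject_id = sid,
                        gma_label = lab)
  })
  angles <- angle_table(seqs, config$min_confidence, config$max_gap)
  features <- extract_features(seqs, config$lags_s,
                               config$min_confidence, config$max_gap)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(angles, file.path(out_dir, "angles.csv"),
                   row.names = FALSE)
  utils::write.csv(features, file.path(out_dir, "acf_features.csv"),
                   row.names = FALSE)
  invisible(list(angles = angles, features = features))
}

#' Compare labelled cohorts from a feature table
#'
#' Stage-three entry point: runs the per-joint, per-lag t-tests on a tidy
#' feature table (file or data frame), writes the lag-by-joint `"t (p)"`
#' grid (`comparison_grid.csv`), the raw cell table
#' (`comparison_cells.csv`) and the list of significant cells
#' (`significant_cells.csv`), and optionally a per-lag MANOVA summary.
#'
#' @param config A [pipeline_config()].
#' @param features Path to an `acf_features.csv` or the data frame itself.
#' @param out_dir Output directory.
#' @param manova Joints for an additional per-lag MANOVA (`NULL` to skip;
#'   e.g. `c("r_hip", "l_hip", "r_knee", "l_knee")`).
#' @return List with `table` (the `gm_comparison`), `summary` and
#'   optionally `manova`, invisibly.
#' @export
run_compare <- function(config = pipeline_config(), features, out_dir,
                        manova = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(features)) features <- utils::read.csv(features)
  labs <- unique(features$gma_label)
  if (length(intersect(c("normal", "cramped_synchronized"), labs)) < 2L)
    stop("feature table must contain both 'normal' and ",
         "'cramped_synchronized' subjects", call. = FALSE)
  table <- ttest_by_joint_lag(features, alpha = config$alpha,
                              var_equal = config$var_equal)
  summ <- summarize_comparison(table)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(summ$grid, file.path(out_dir, "comparison_grid.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(table),
                   file.path(out_dir, "comparison_cells.csv"),
                   row.names = FALSE)
  utils::write.csv(summ$significant,
                   file.path(out_dir, "significant_cells.csv"),
                   row.names = FALSE)
  out <- list(table = table, summary = summ)
  if (!is.null(manova)) {
    mv <- do.call(rbind, lapply(sort(unique(features$lag_s)), function(l) {
      m <- manova_across_joints(features, l, joints = manova)
      data.frame(lag_s = l, lambda = m$lambda, F = m$F, p = m$p)
    }))
    utils::write.csv(mv, file.path(out_dir, "manova_by_lag.csv"),
                     row.names = FALSE)
    out$manova <- mv
  }
  invisible(out)
}

#' Score predictions against ground truth and write the report
#'
#' OKS-evaluation entry point: reads a COCO keypoint ground-truth file and
#' a predictions file, scores them under the configured OKS constants and
#' writes `oks_report.csv` (rows = the 17 keypoints plus Mean and stdev).
#'
#' @param config A [pipeline_config()].
#' @param truth_json Path to the COCO keypoint ground-truth JSON.
#' @param pred_json Path to the predictions JSON (results format).
#' @param out_dir Output directory.
#' @return The [evaluate_model()] report, invisibly.
#' @export
run_evaluate_oks <- function(config = pipeline_config(), truth_json,
                             pred_json, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  ann <- read_coco_keypoints(truth_json)
  ann <- read_coco_predictions(ann, pred_json)
  cfg <- oks_config(config$oks_s, config$oks_k, config$oks_variant,
                    config$oks_normalize)
  rep_ <- evaluate_model(ann, cfg)
  out <- rbind(
    data.frame(row = rep_$per_keypoint$keypoint,
               value = rep_$per_keypoint$mean_oks),
    data.frame(row = c("Mean", "stdev_sample", "stdev_population"),
               value = c(rep_$mean, rep_$sd_sample, rep_$sd_population)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(out, file.path(out_dir, "oks_report.csv"),
                   row.names = FALSE)
  invisible(rep_)
}
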