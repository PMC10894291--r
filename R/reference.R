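#' Reference per-keypoint OKS benchmark values
#'
#' Bundled per-keypoint mean OKS values for two pose models evaluated on
#' the same annotated NICU test frames: a generic model pretrained on a
#' broad person-keypoint corpus, and the same architecture fine-tuned on
#' NICU images. Used by the validation suite and by
#' [run_evaluate_oks()] examples to exercise the aggregation and
#' model-comparison arithmetic ([aggregate_report()], [compare_models()]).
#'
#' @return Data frame with columns `keypoint`, `generic_model`,
#'   `nicu_model` (17 rows, COCO keypoint order).
#' @export
#' @examples
#' b <- oks_keypoint_benchmark()
#' aggregate_report(b$nicu_model)$mean   # about 0.91
#' aggregate_report(b$generic_model)$mean  # about 0.83
oks_keypoint_benchmark <- function() {
  data.frame(
    keypoint = keypoint_names(),
    generic_model = c(0.83, 0.85, 0.87, 0.80, 0.80, 0.86, 0.87, 0.87, 0.86,
                      0.83, 0.85, 0.81, 0.80, 0.80, 0.78, 0.80, 0.79),
    nicu_model = c(0.91, 0.92, 0.92, 0.89, 0.91, 0.92, 0.92, 0.91, 0.92,
                   0.91, 0.92, 0.91, 0.90, 0.91, 0.92, 0.91, 0.91),
    stringsAsFactors = FALSE)
}

#' Reference normal-vs-CS autocorrelation t statistics
#'
#' Bundled per-joint, per-lag Student t statistics (with the two-sided
#' p-values as printed, at their visible precision) from an independent
#' two-sample comparison of autocorrelation values between five normal and
#' five cramped-synchronized recordings (pooled test, df = 8; sign is
#' normal minus CS). Used by the validation suite to check the t-to-p
#' arithmetic of [two_sided_p_from_t()] and the report formatting.
#'
#' @return Data frame with columns `lag_s`, `joint`, `t`, `p_printed`.
#' @export
acf_ttest_benchmark <- function() {
  joints <- canonical_anchors()$joint
  lags <- c(1, 2, 3, 5, 7, 11, 13)
  t_vals <- c(
    0.82, -0.98, -1.36, -0.62, -2.04, -1.89, -1.91, -0.93,
    0.42, -1.65, -1.26, -0.38, -2.36, -1.89, -2.39, -1.23,
    0.50, -1.83, -1.16, -0.29, -2.59, -2.04, -2.83, -1.61,
    0.43, -1.51, -0.91, -0.40, -3.16, -2.49, -3.46, -2.32,
    0.75, -1.30, -0.98, -0.16, -3.61, -2.72, -3.65, -2.34,
    0.49, -0.86, -1.10,  0.00, -3.56, -2.60, -4.20, -2.46,
    0.72, -0.56, -1.02,  0.04, -3.60, -2.45, -4.27, -2.21)
  p_vals <- c(
    0.44, 0.35, 0.21, 0.55, 0.08, 0.10, 0.09, 0.38,
    0.68, 0.14, 0.24, 0.71, 0.05, 0.10, 0.04, 0.25,
    0.63, 0.11, 0.28, 0.78, 0.03, 0.08, 0.02, 0.15,
    0.68, 0.17, 0.39, 0.70, 0.01, 0.04, 0.01, 0.05,
    0.47, 0.23, 0.35, 0.88, 0.01, 0.03, 0.01, 0.05,
    0.64, 0.41, 0.30, 1.00, 0.01, 0.03, 0.00, 0.04,
    0.49, 0.59, 0.34, 0.97, 0.01, 0.03, 0.00, 0.06)
  data.frame(lag_s = rep(lags, each = length(joints)),
             joint = rep(joints, times = length(lags)),
             t = t_vals, p_printed = p_vals,
             stringsAsFactors = FALSE)
}

#' Reference clinical recording length statistics
#'
#' Mean and standard deviation of the frame counts of the clinical GMA
#' recordings the package's defaults are modelled on, at 30 fps (the
#' recordings were stopped once at least three general movements had been
#' observed). Dividing by the frame rate gives durations of about
#' 179 +/- 45 s, which motivates the 180 s default of
#' [movement_params()].
#'
#' @return List with `mean_frames`, `sd_frames`, `fps`.
#' @export
#' @examples
#' with(video_frame_stats(), frames_to_seconds(c(mean_frames, sd_frames), fps))
video_frame_stats <- function() {
  list(mean_frames = 5370.93, sd_frames = 1353.28, fps = 30)
}
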