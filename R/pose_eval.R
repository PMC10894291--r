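#' OKS scoring configuration
#'
#' Bundles the constants of the object keypoint similarity (OKS) metric:
#' the scale `s`, the 17 per-keypoint fall-off constants `k`, the formula
#' variant and the distance normalization.
#'
#' Two variants are supported. `"paper"` scores
#' \eqn{\exp(-d^2 / (s^2 k^2))}; `"coco_standard"` keeps the conventional
#' factor 2 of the COCO ecosystem, \eqn{\exp(-d^2 / (2 s^2 k^2))}. With the
#' tight default constants (`s = 1`, `k = 0.001`) and distances in raw
#' pixels, any displacement beyond a few hundredths of a pixel scores
#' essentially 0; for pixel-scale evaluation either supply larger constants
#' or set `normalize = "diagonal"` to divide distances by the image diagonal.
#'
#' @param s Scale constant, > 0 (default 1).
#' @param k Fall-off constant(s): a single value recycled to all 17
#'   keypoints or a vector of 17 positive values (default 0.001).
#' @param variant `"paper"` or `"coco_standard"`.
#' @param normalize `"none"` (distances in raw pixels) or `"diagonal"`
#'   (distances divided by the image diagonal before scoring).
#' @return An object of class `oks_config`.
#' @export
oks_config <- function(s = 1, k = 0.001,
                       variant = c("paper", "coco_standard"),
                       normalize = c("none", "diagonal")) {
  variant <- match.arg(variant)
  normalize <- match.arg(normalize)
  if (!is.numeric(s) || length(s) != 1L || s <= 0)
    stop("s must be a single positive number", call. = FALSE)
  if (length(k) == 1L) k <- rep(k, .N_KEYPOINTS)
  if (length(k) != .N_KEYPOINTS || any(k <= 0))
    stop("k must be 1 or 17 positive fall-off constants", call. = FALSE)
  structure(list(s = s, k = as.numeric(k), variant = variant,
                 normalize = normalize),
            class = "oks_config")
}

#' Object keypoint similarity for a single distance
#'
#' Computes \eqn{\exp(-d^2 / (s^2 k^2))} (variant `"paper"`) or
#' \eqn{\exp(-d^2 / (2 s^2 k^2))} (variant `"coco_standard"`) for a
#' ground-truth-to-prediction distance `d`. The score is 1 exactly when
#' `d = 0` and decreases strictly and continuously with `d`; scaling `d` and
#' `s` by the same factor leaves it unchanged.
#'
#' @param d Non-negative distance(s), in the same units as `s * k`.
#' @param s Scale constant, > 0.
#' @param k Fall-off constant, > 0.
#' @param variant `"paper"` or `"coco_standard"`.
#' @return Similarity value(s) in `(0, 1]`.
#' @export
#' @examples
#' oks_single(0, 1, 0.001)              # 1: perfect localization
#' oks_single(1, 1, 1)                  # exp(-1)
#' oks_single(1, 1, 1, "coco_standard") # exp(-0.5)
oks_single <- function(d, s, k, variant = c("paper", "coco_standard")) {
  variant <- match.arg(variant)
  if (any(d < 0)) stop("d must be non-negative", call. = FALSE)
  if (any(s <= 0) || any(k <= 0)) stop("s and k must be positive", call. = FALSE)
  denom <- s^2 * k^2
  if (variant == "coco_standard") denom <- 2 * denom
  exp(-d^2 / denom)
}

#' Evaluate a pose model against ground truth with OKS
#'
#' Scores every predicted keypoint against its ground-truth location with
#' [oks_single()] and averages per keypoint over the frames where the ground
#' truth is visible (confidence > 0). Keypoints never visible in the ground
#' truth are excluded from the per-keypoint means and flagged, rather than
#' scored 0, so annotation gaps are not conflated with model error.
#'
#' @param ann An [annotation_set()] carrying both ground truth and
#'   predictions.
#' @param config An [oks_config()].
#' @return An object of class `oks_report`: a list with `per_keypoint`
#'   (data frame of keypoint, mean OKS and number of frames evaluated),
#'   `mean` (arithmetic mean of the 17 per-keypoint means), `sd_sample` and
#'   `sd_population` (both standard-deviation conventions across the 17
#'   per-keypoint means), and `excluded` (keypoints with no visible ground
#'   truth).
#' @export
evaluate_model <- function(ann, config = oks_config()) {
  stopifnot(inherits(ann, "annotation_set"), inherits(config, "oks_config"))
  if (is.null(ann$pred))
    stop("annotation set carries no predictions; attach them first",
         call. = FALSE)
  if (length(ann$image_id) < 1L)
    stop("annotation set has no images to evaluate", call. = FALSE)
  d <- sqrt((ann$gt$x - ann$pred$x)^2 + (ann$gt$y - ann$pred$y)^2)
  if (config$normalize == "diagonal")
    d <- d / sqrt(ann$width^2 + ann$height^2)
  visible <- ann$gt$conf > 0
  if (!any(visible))
    stop("no visible ground-truth keypoints to evaluate", call. = FALSE)
  oks <- oks_single(ifelse(visible, d, 0),
                    config$s, rep(config$k, each = nrow(d)),
                    config$variant)
  oks[!visible] <- NA_real_
  per_kp <- colMeans(oks, na.rm = TRUE)
  n_eval <- colSums(visible)
  per_kp[n_eval == 0L] <- NA_real_
  report <- list(
    per_keypoint = data.frame(keypoint = keypoint_names(),
                              mean_oks = unname(per_kp),
                              n_frames = unname(n_eval),
                              stringsAsFactors = FALSE),
    mean = mean(per_kp, na.rm = TRUE),
    sd_sample = stats::sd(per_kp, na.rm = TRUE),
    sd_population = .pop_sd(per_kp[!is.na(per_kp)]),
    excluded = keypoint_names()[n_eval == 0L],
    config = config)
  structure(report, class = "oks_report")
}

.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Aggregate 17 per-keypoint accuracy values
#'
#' Arithmetic mean and standard deviation (both the sample, n - 1, and the
#' population, n, conventions) of a vector of 17 per-keypoint scores --
#' the summary printed at the foot of a per-keypoint accuracy table.
#'
#' @param per_keypoint_values Numeric vector of exactly 17 finite values.
#' @return List with `mean`, `sd_sample`, `sd_population`.
#' @export
aggregate_report <- function(per_keypoint_values) {
  v <- as.numeric(per_keypoint_values)
  if (length(v) != .N_KEYPOINTS || any(!is.finite(v)))
    stop("expected exactly 17 finite per-keypoint values", call. = FALSE)
  list(mean = mean(v), sd_sample = stats::sd(v), sd_population = .pop_sd(v))
}

#' Compare two keypoint-accuracy reports
#'
#' Pairs the 17 per-keypoint mean OKS values of two models and reports the
#' per-keypoint differences, a paired two-sided t-test across the 17
#' keypoints (df = 16) and the relative improvement of model A over model B,
#' `(mean_A - mean_B) / mean_B`. Only the per-keypoint summaries enter, so
#' pairing on keypoints is the natural test.
#'
#' @param report_a,report_b Either `oks_report` objects from
#'   [evaluate_model()] or bare numeric vectors of 17 per-keypoint means.
#' @return List with `delta` (per-keypoint A - B), `t`, `df`, `p` and
#'   `relative_improvement`.
#' @export
compare_models <- function(report_a, report_b) {
  get_vals <- function(r) {
    if (inherits(r, "oks_report")) r$per_keypoint$mean_oks else as.numeric(r)
  }
  a <- get_vals(report_a); b <- get_vals(report_b)
  if (length(a) != .N_KEYPOINTS || length(b) != .N_KEYPOINTS)
    stop("both reports must cover the same 17 keypoints", call. = FALSE)
  if (any(is.na(a)) || any(is.na(b)))
    stop("per-keypoint means contain missing values; keypoint sets differ",
         call. = FALSE)
  delta <- a - b
  if (all(delta == 0)) {
    tt <- list(statistic = c(t = 0), parameter = c(df = 16), p.value = 1)
  } else {
    tt <- stats::t.test(a, b, paired = TRUE)
  }
  list(delta = stats::setNames(delta, keypoint_names()),
       t = unname(tt$statistic),
       df = unname(tt$parameter),
       p = tt$p.value,
       relative_improvement = (mean(a) - mean(b)) / mean(b))
}

#' @export
print.oks_report <- function(x, ...) {
  cat(sprintf("<oks_report> mean OKS %.4f (sd %.4f sample / %.4f population)\n",
              x$mean, x$sd_sample, x$sd_population))
  if (length(x$excluded))
    cat("  excluded (no visible ground truth):",
        paste(x$excluded, collapse = ", "), "\n")
  print(x$per_keypoint, row.names = FALSE)
  invisible(x)
}
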