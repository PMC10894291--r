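#' The eight canonical joint anchors
#'
#' Each joint angle is defined at an anchor keypoint by two limb-segment
#' vectors rooted there: vector A from the anchor to `endpoint_a` and vector
#' B from the anchor to `endpoint_b`. The eight canonical anchors are the
#' elbows (shoulder, wrist), shoulders (elbow, hip), hips (knee, shoulder)
#' and knees (hip, ankle), on each side, in the fixed reporting order
#' r_elbow, l_elbow, r_shoulder, l_shoulder, r_hip, l_hip, r_knee, l_knee.
#'
#' @return A data frame with columns `joint`, `anchor`, `endpoint_a`,
#'   `endpoint_b`.
#' @export
#' @examples
#' canonical_anchors()
canonical_anchors <- function() {
  data.frame(
    joint = c("r_elbow", "l_elbow", "r_shoulder", "l_shoulder",
              "r_hip", "l_hip", "r_knee", "l_knee"),
    anchor = c("right_elbow", "left_elbow", "right_shoulder", "left_shoulder",
               "right_hip", "left_hip", "right_knee", "left_knee"),
    endpoint_a = c("right_shoulder", "left_shoulder", "right_elbow", "left_elbow",
                   "right_knee", "left_knee", "right_hip", "left_hip"),
    endpoint_b = c("right_wrist", "left_wrist", "right_hip", "left_hip",
                   "right_shoulder", "left_shoulder", "right_ankle", "left_ankle"),
    stringsAsFactors = FALSE)
}

#' Cosine similarity of two 2D vectors
#'
#' The standard Euclidean cosine \eqn{A \cdot B / (\|A\| \|B\|)}, clamped to
#' `[-1, 1]` against floating-point overshoot. For limb-segment vectors
#' rooted at a joint, +1 means the segments are folded onto each other
#' (full flexion), 0 means perpendicular segments and -1 means opposite
#' directions (full extension).
#'
#' @param a,b Numeric vectors of length 2.
#' @return Cosine similarity in `[-1, 1]`.
#' @export
#' @examples
#' cosine_similarity(c(1, 0), c(0, 1))   # perpendicular: 0
#' cosine_similarity(c(2, 3), c(4, 6))   # same direction: 1
#' cosine_similarity(c(1, 0), c(-5, 0))  # opposite: -1
cosine_similarity <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == 2L, length(b) == 2L)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("degenerate geometry: zero-length limb vector (coincident keypoints)",
         call. = FALSE)
  min(1, max(-1, sum(a * b) / (na * nb)))
}

#' Construct an angle series
#'
#' @param joint Joint name (one of the canonical eight, or free-form).
#' @param values Numeric vector of cosine-similarity values in `[-1, 1]`,
#'   `NA` marking missing frames.
#' @param fps Frames per second.
#' @return An object of class `angle_series`.
#' @export
angle_series <- function(joint, values, fps) {
  values <- as.numeric(values)
  if (any(values < -1 - 1e-9 | values > 1 + 1e-9, na.rm = TRUE))
    stop("angle_series values must lie in [-1, 1]", call. = FALSE)
  stopifnot(fps > 0)
  structure(list(joint = joint, values = pmin(1, pmax(-1, values)),
                 fps = as.numeric(fps)),
            class = "angle_series")
}

#' @export
print.angle_series <- function(x, ...) {
  cat(sprintf("<angle_series> %s: %d frames @ %g fps, %d missing\n",
              x$joint, length(x$values), x$fps, sum(is.na(x$values))))
  invisible(x)
}

# Linear interpolation of interior NA runs no longer than max_gap frames.
.fill_short_gaps <- function(v, max_gap) {
  if (max_gap < 1 || !anyNA(v) || sum(!is.na(v)) < 2L) return(v)
  filled <- stats::approx(seq_along(v), v, xout = seq_along(v),
                          method = "linear", rule = 1)$y
  r <- rle(is.na(v))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in which(r$values & r$lengths <= max_gap)) {
    idx <- starts[i]:ends[i]
    v[idx] <- filled[idx]  # stays NA at the edges (rule = 1)
  }
  v
}

#' Joint-angle cosine-similarity time series of a pose sequence
#'
#' For every frame, forms the two limb-segment vectors rooted at the anchor
#' keypoint (A = endpoint_a - anchor, B = endpoint_b - anchor) and records
#' their cosine similarity. Frames where any of the three keypoints falls
#' below the confidence threshold, or where a segment has zero length, are
#' marked missing; interior missing runs of at most `max_gap` frames are
#' then linearly interpolated, longer runs stay missing. The result is
#' invariant under translation, rotation and uniform scaling of the frame
#' coordinates.
#'
#' @param seq A [pose_sequence()].
#' @param anchor One row of [canonical_anchors()] (or a list with `joint`,
#'   `anchor`, `endpoint_a`, `endpoint_b`), or a canonical joint name.
#' @param min_confidence Frames with any involved keypoint confidence
#'   strictly below this are treated as missing (default 0, i.e. only
#'   confidence-0 keypoints are dropped).
#' @param max_gap Longest missing run, in frames, to bridge by linear
#'   interpolation (default 5).
#' @return An [angle_series()] of the same length as the sequence.
#' @export
angle_timeseries <- function(seq, anchor, min_confidence = 0, max_gap = 5) {
  validate_pose_sequence(seq)
  if (is.character(anchor) && length(anchor) == 1L) {
    ca <- canonical_anchors()
    row <- match(anchor, ca$joint)
    if (is.na(row)) stop("unknown canonical joint: ", anchor, call. = FALSE)
    anchor <- ca[row, ]
  }
  if (n_frames(seq) == 0L)
    stop("empty pose sequence: no frames to convert", call. = FALSE)
  kp <- keypoint_names()
  ia <- match(anchor$anchor, kp)
  i1 <- match(anchor$endpoint_a, kp)
  i2 <- match(anchor$endpoint_b, kp)
  if (anyNA(c(ia, i1, i2)))
    stop("anchor refers to unknown keypoint names", call. = FALSE)
  ax <- seq$x[, i1] - seq$x[, ia]; ay <- seq$y[, i1] - seq$y[, ia]
  bx <- seq$x[, i2] - seq$x[, ia]; by <- seq$y[, i2] - seq$y[, ia]
  na_ <- sqrt(ax^2 + ay^2); nb <- sqrt(bx^2 + by^2)
  v <- (ax * bx + ay * by) / (na_ * nb)
  low_conf <- seq$conf[, ia] < min_confidence |
    seq$conf[, i1] < min_confidence | seq$conf[, i2] < min_confidence
  v[low_conf | na_ == 0 | nb == 0 | !is.finite(v)] <- NA_real_
  v <- .fill_short_gaps(v, max_gap)
  if (all(is.na(v)))
    stop("all frames missing for joint '", anchor$joint,
         "' after confidence masking", call. = FALSE)
  angle_series(anchor$joint, pmin(1, pmax(-1, v)), seq$fps)
}

#' Normalized autocorrelation at a single lag
#'
#' The sample estimator
#' \deqn{r(k) = \frac{\sum_{t=1}^{T-k} (y_t - \bar y)(y_{t+k} - \bar y)}
#'                   {\sum_{t=1}^{T} (y_t - \bar y)^2}}
#' with \eqn{\bar y} the full-series mean. By the Cauchy-Schwarz inequality
#' \eqn{|r(k)| \le 1} for every lag, and \eqn{r(0) = 1} exactly. Missing
#' values are tolerated: the mean and denominator use all observed values
#' and the numerator sums over the lag-k pairs where both ends are observed
#' (which preserves the bound).
#'
#' @param series An [angle_series()] or a bare numeric vector (`NA` =
#'   missing).
#' @param lag_frames Non-negative integer lag, in frames; must be smaller
#'   than the series length, with at least `lag_frames + 2` observed values.
#' @return The autocorrelation value, in `[-1, 1]`.
#' @export
#' @examples
#' normalized_autocorrelation(sin(1:100), 0)   # 1 by construction
normalized_autocorrelation <- function(series, lag_frames) {
  y <- if (inherits(series, "angle_series")) series$values else as.numeric(series)
  if (!is.numeric(lag_frames) || length(lag_frames) != 1L || lag_frames < 0 ||
      lag_frames != round(lag_frames))
    stop("lag_frames must be a single non-negative integer", call. = FALSE)
  k <- as.integer(lag_frames)
  T_ <- length(y)
  if (k >= T_)
    stop("lag (", k, " frames) must be smaller than the series length (",
         T_, ")", call. = FALSE)
  obs <- !is.na(y)
  if (sum(obs) < k + 2L)
    stop("need at least lag_frames + 2 observed values", call. = FALSE)
  ybar <- mean(y[obs])
  dev <- y - ybar
  den <- sum(dev[obs]^2)
  if (den == 0)
    stop("degenerate series: constant values give a zero denominator",
         call. = FALSE)
  if (k == 0L) return(1)
  t0 <- seq_len(T_ - k)
  pair <- obs[t0] & obs[t0 + k]
  num <- sum(dev[t0][pair] * dev[t0 + k][pair])
  num / den
}

# round-half-away-from-zero (base round() rounds half to even)
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Autocorrelation profile over a lag grid in seconds
#'
#' Evaluates [normalized_autocorrelation()] at each requested lag, given in
#' seconds and converted to frames by `round(lag * fps)` with half-values
#' rounded away from zero. The default grid is 1, 2, 3, 5, 7, 11, 13
#' seconds; at 30 fps this corresponds to frame lags 30, 60, 90, 150, 210,
#' 330, 390.
#'
#' @param series An [angle_series()] (or numeric vector if `fps` is given).
#' @param lags_seconds Numeric vector of lags in seconds.
#' @param fps Frames per second; taken from the series when omitted.
#' @return An object of class `acf_profile`: list with `joint`, `lags_s`,
#'   `lag_frames`, `r`, `n_obs` and `mean` (the series mean used in the
#'   estimator).
#' @export
acf_profile <- function(series, lags_seconds = c(1, 2, 3, 5, 7, 11, 13),
                        fps = NULL) {
  if (inherits(series, "angle_series")) {
    if (is.null(fps)) fps <- series$fps
    joint <- series$joint
    y <- series$values
  } else {
    if (is.null(fps)) stop("fps must be given for a bare numeric series",
                           call. = FALSE)
    joint <- NA_character_
    y <- as.numeric(series)
  }
  stopifnot(fps > 0)
  lag_frames <- as.integer(.round_half_away(lags_seconds * fps))
  r <- vapply(lag_frames, function(k) normalized_autocorrelation(y, k), 0)
  structure(list(joint = joint, lags_s = as.numeric(lags_seconds),
                 lag_frames = lag_frames, r = r,
                 n_obs = sum(!is.na(y)), mean = mean(y, na.rm = TRUE)),
            class = "acf_profile")
}

#' @export
print.acf_profile <- function(x, ...) {
  cat(sprintf("<acf_profile> %s (T = %d):\n", x$joint, x$n_obs))
  print(data.frame(lag_s = x$lags_s, lag_frames = x$lag_frames,
                   r = round(x$r, 4)), row.names = FALSE)
  invisible(x)
}

#' Autocorrelation features for a set of pose sequences
#'
#' Runs the full feature pipeline -- joint-angle extraction for each of the
#' eight canonical anchors followed by the autocorrelation profile -- over a
#' list of pose sequences and returns one tidy row per (subject, joint,
#' lag).
#'
#' @param seqs A list of [pose_sequence()] objects (or a `synthetic_cohort`).
#' @param lags_seconds Lag grid in seconds (default 1, 2, 3, 5, 7, 11, 13).
#' @param min_confidence,max_gap Missing-data policy passed to
#'   [angle_timeseries()].
#' @return A data frame with columns `subject`, `gma_label`, `joint`,
#'   `lag_s`, `r`.
#' @export
extract_features <- function(seqs, lags_seconds = c(1, 2, 3, 5, 7, 11, 13),
                             min_confidence = 0, max_gap = 5) {
  if (inherits(seqs, "synthetic_cohort")) seqs <- seqs$sequences
  if (inherits(seqs, "pose_sequence")) seqs <- list(seqs)
  anchors <- canonical_anchors()
  out <- lapply(seqs, function(s) {
    rows <- lapply(seq_len(nrow(anchors)), function(j) {
      ang <- angle_timeseries(s, anchors[j, ], min_confidence, max_gap)
      prof <- acf_profile(ang, lags_seconds)
      data.frame(subject = s$subject_id, gma_label = s$gma_label,
                 joint = anchors$joint[j], lag_s = prof$lags_s, r = prof$r,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-frame angle table for a set of pose sequences
#'
#' Tidy long-format export of the eight joint-angle cosine-similarity
#' signals (one row per subject, joint and frame), suitable for plotting or
#' downstream analysis outside the package.
#'
#' @inheritParams extract_features
#' @return A data frame with columns `subject`, `gma_label`, `joint`,
#'   `frame`, `value`.
#' @export
angle_table <- function(seqs, min_confidence = 0, max_gap = 5) {
  if (inherits(seqs, "synthetic_cohort")) seqs <- seqs$sequences
  if (inherits(seqs, "pose_sequence")) seqs <- list(seqs)
  anchors <- canonical_anchors()
  out <- lapply(seqs, function(s) {
    rows <- lapply(seq_len(nrow(anchors)), function(j) {
      ang <- angle_timeseries(s, anchors[j, ], min_confidence, max_gap)
      data.frame(subject = s$subject_id, gma_label = s$gma_label,
                 joint = anchors$joint[j], frame = s$frame_index,
                 value = ang$values, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
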