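#' The 17 COCO anatomical keypoint names
#'
#' Returns the canonical, ordered names of the 17 anatomical keypoints used
#' throughout the package: nose, eyes, ears, shoulders, elbows, wrists, hips,
#' knees and ankles. The ordering is the COCO keypoint ordering and is
#' identical in every serialized representation (JSON and CSV) the package
#' reads or writes.
#'
#' @return Character vector of length 17.
#' @export
#' @examples
#' keypoint_names()
keypoint_names <- function() {
  c("nose",
    "left_eye", "right_eye",
    "left_ear", "right_ear",
    "left_shoulder", "right_shoulder",
    "left_elbow", "right_elbow",
    "left_wrist", "right_wrist",
    "left_hip", "right_hip",
    "left_knee", "right_knee",
    "left_ankle", "right_ankle")
}

#' @keywords internal
.N_KEYPOINTS <- 17L

.gma_labels <- c("normal", "poor_repertoire", "cramped_synchronized", "unknown")

#' Construct a pose sequence
#'
#' A pose sequence holds an ordered per-frame record of the 17 keypoint
#' locations for one subject, together with the frame rate and the clinical
#' general-movement (GMA) label. Coordinates are 0-based pixel positions in
#' image convention (x rightward, y downward); frame indices are 0-based and
#' strictly increasing.
#'
#' @param x,y Numeric matrices, frames x 17, of pixel coordinates. Column
#'   order must follow [keypoint_names()].
#' @param conf Per-keypoint confidence in `[0, 1]`; either a single value
#'   recycled to all entries (default 1, i.e. ground truth) or a frames x 17
#'   matrix. Coordinates need only be finite where `conf > 0`.
#' @param frame_index Integer vector of 0-based frame indices, strictly
#'   increasing. Defaults to `0:(nrow(x) - 1)`.
#' @param fps Frames per second (positive; clinical recordings default to 30).
#' @param subject_id Opaque subject/video identifier.
#' @param gma_label One of `"normal"`, `"poor_repertoire"`,
#'   `"cramped_synchronized"`, `"unknown"`.
#' @return An object of class `pose_sequence`.
#' @export
pose_sequence <- function(x, y, conf = 1, frame_index = NULL, fps = 30,
                          subject_id = "subject", gma_label = "unknown") {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  if (length(conf) == 1L) conf <- matrix(conf, n, .N_KEYPOINTS)
  conf <- as.matrix(conf)
  if (is.null(frame_index)) frame_index <- seq_len(n) - 1L
  obj <- structure(
    list(subject_id = as.character(subject_id),
         fps = as.numeric(fps),
         gma_label = match.arg(gma_label, .gma_labels),
         frame_index = as.integer(frame_index),
         x = x, y = y, conf = conf),
    class = "pose_sequence")
  validate_pose_sequence(obj)
}

#' Validate a pose sequence
#'
#' Checks the structural invariants of a [pose_sequence()]: 17 keypoint
#' columns, positive fps, strictly increasing frame indices, confidences in
#' `[0, 1]` and finite coordinates wherever confidence is positive.
#'
#' @param seq A `pose_sequence`.
#' @return The validated object, invisibly usable in pipelines.
#' @export
validate_pose_sequence <- function(seq) {
  stopifnot(inherits(seq, "pose_sequence"))
  n <- nrow(seq$x)
  if (ncol(seq$x) != .N_KEYPOINTS || ncol(seq$y) != .N_KEYPOINTS ||
      ncol(seq$conf) != .N_KEYPOINTS)
    stop("pose_sequence: expected 17 keypoint columns", call. = FALSE)
  if (nrow(seq$y) != n || nrow(seq$conf) != n || length(seq$frame_index) != n)
    stop("pose_sequence: inconsistent frame counts across fields", call. = FALSE)
  if (!is.finite(seq$fps) || seq$fps <= 0)
    stop("pose_sequence: fps must be a positive number", call. = FALSE)
  if (n > 1 && any(diff(seq$frame_index) <= 0))
    stop("pose_sequence: frame_index must be strictly increasing (duplicate or out-of-order frames)",
         call. = FALSE)
  if (any(seq$frame_index < 0))
    stop("pose_sequence: frame_index must be non-negative", call. = FALSE)
  if (any(seq$conf < 0 | seq$conf > 1, na.rm = TRUE))
    stop("pose_sequence: confidence values must lie in [0, 1]", call. = FALSE)
  vis <- seq$conf > 0
  if (any(!is.finite(seq$x[vis])) || any(!is.finite(seq$y[vis])))
    stop("pose_sequence: coordinates must be finite where confidence > 0",
         call. = FALSE)
  colnames(seq$x) <- colnames(seq$y) <- colnames(seq$conf) <- keypoint_names()
  seq
}

#' Number of frames in a pose sequence
#' @param x A `pose_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) nrow(x$x)

#' Extract one keypoint frame
#'
#' Returns the i-th frame of a sequence as a list with the frame index, a
#' 17 x 2 coordinate matrix and the 17 confidence values.
#'
#' @param seq A `pose_sequence`.
#' @param i Frame position (1-based within the stored frames).
#' @return A list of class `keypoint_frame`.
#' @export
keypoint_frame <- function(seq, i) {
  stopifnot(i >= 1, i <= n_frames(seq))
  structure(
    list(frame_index = seq$frame_index[i],
         coordinates = cbind(x = seq$x[i, ], y = seq$y[i, ]),
         confidence = seq$conf[i, ]),
    class = "keypoint_frame")
}

#' Subsample frames for annotation
#'
#' Deterministically picks every `step`-th stored frame (positions 1,
#' 1 + step, 1 + 2 step, ...), optionally capped at `max_frames`, mirroring
#' the common practice of annotating every 10th frame of a 30 fps recording.
#' A 100-frame sequence with `step = 10` yields the 10 frames at indices
#' 0, 10, ..., 90; without a cap a T-frame sequence yields `ceiling(T / step)`
#' frames.
#'
#' @param seq A `pose_sequence`.
#' @param step Positive integer sampling stride.
#' @param max_frames Optional cap on the number of returned frames.
#' @return A list of `keypoint_frame` objects.
#' @export
sample_annotation_frames <- function(seq, step, max_frames = NULL) {
  if (!is.numeric(step) || length(step) != 1L || step < 1)
    stop("step must be a positive integer >= 1", call. = FALSE)
  step <- as.integer(step)
  pos <- seq.int(1L, n_frames(seq), by = step)
  if (!is.null(max_frames)) {
    if (max_frames < 1) stop("max_frames must be a positive integer", call. = FALSE)
    pos <- pos[seq_len(min(length(pos), as.integer(max_frames)))]
  }
  lapply(pos, function(i) keypoint_frame(seq, i))
}

#' @export
print.pose_sequence <- function(x, ...) {
  cat(sprintf("<pose_sequence> subject '%s': %d frames @ %g fps (%.1f s), label: %s\n",
              x$subject_id, n_frames(x), x$fps, n_frames(x) / x$fps, x$gma_label))
  invisible(x)
}

#' Convert frame counts to seconds
#'
#' @param frames Numeric vector of frame counts.
#' @param fps Frames per second.
#' @return Duration(s) in seconds.
#' @export
#' @examples
#' frames_to_seconds(5400, 30)  # a 3-minute recording
frames_to_seconds <- function(frames, fps = 30) {
  stopifnot(fps > 0)
  frames / fps
}
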