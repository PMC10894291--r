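.ts_columns <- function() {
  kp <- keypoint_names()
  c("frame", paste0(rep(kp, each = 3L), c("_x", "_y", "_conf")))
}

#' Read a pose time series from CSV
#'
#' The CSV dialect is UTF-8, comma-separated with '.' decimal, one row per
#' frame, and columns `frame` followed by `<keypoint>_x`, `<keypoint>_y`,
#' `<keypoint>_conf` for each of the 17 keypoint names in COCO order.
#'
#' @param path Path to the CSV file.
#' @param fps Frames per second to attach to the sequence (default 30).
#' @param subject_id Subject identifier (defaults to the file name).
#' @param gma_label GMA label to attach (default `"unknown"`).
#' @return A [pose_sequence()].
#' @export
read_timeseries_csv <- function(path, fps = 30,
                                subject_id = NULL, gma_label = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  want <- .ts_columns()
  missing <- setdiff(want, names(df))
  if (length(missing))
    stop("time-series CSV is missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  df <- df[order(df$frame), , drop = FALSE]
  if (anyDuplicated(df$frame))
    stop("time-series CSV has duplicate frame indices: ",
         paste(unique(df$frame[duplicated(df$frame)]), collapse = ", "),
         call. = FALSE)
  kp <- keypoint_names()
  pose_sequence(
    x = as.matrix(df[paste0(kp, "_x")]),
    y = as.matrix(df[paste0(kp, "_y")]),
    conf = as.matrix(df[paste0(kp, "_conf")]),
    frame_index = df$frame,
    fps = fps,
    subject_id = if (is.null(subject_id)) basename(path) else subject_id,
    gma_label = gma_label)
}

#' Write a pose time series to CSV
#'
#' Inverse of [read_timeseries_csv()]. Coordinates and confidences are
#' written with 6 decimal places, enough for a stable round trip at that
#' precision; an empty sequence yields a header-only file.
#'
#' @param seq A [pose_sequence()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(seq, path) {
  validate_pose_sequence(seq)
  kp <- keypoint_names()
  n <- n_frames(seq)
  cols <- vector("list", 1L + 3L * .N_KEYPOINTS)
  names(cols) <- .ts_columns()
  cols[["frame"]] <- seq$frame_index
  fmt <- function(v) sprintf("%.6f", v)
  for (j in seq_len(.N_KEYPOINTS)) {
    cols[[paste0(kp[j], "_x")]] <- fmt(seq$x[, j])
    cols[[paste0(kp[j], "_y")]] <- fmt(seq$y[, j])
    cols[[paste0(kp[j], "_conf")]] <- fmt(seq$conf[, j])
  }
  df <- if (n == 0L) {
    as.data.frame(sapply(names(cols), function(nm) character(0),
                         simplify = FALSE), check.names = FALSE)
  } else {
    as.data.frame(cols, check.names = FALSE)
  }
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop("could not write time-series CSV to '", path, "': ",
         conditionMessage(ok), call. = FALSE)
  invisible(path)
}
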