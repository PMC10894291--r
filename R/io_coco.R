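#' Construct an annotation set
#'
#' An annotation set pairs per-image ground-truth keypoint locations with
#' (optionally) the predictions of a pose model on the same images, as needed
#' for OKS evaluation. Ground-truth confidence encodes COCO visibility
#' (0 = unlabelled, 0.5 = labelled but occluded, 1 = visible).
#'
#' @param image_id Character or integer vector of image identifiers.
#' @param width,height Image dimensions in pixels (recycled if length 1).
#' @param gt List with `x`, `y`, `conf`: n_images x 17 matrices of ground
#'   truth (column order [keypoint_names()]).
#' @param pred Optional list of the same shape holding model predictions,
#'   with `conf` carrying per-keypoint prediction confidence.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(image_id, width, height, gt, pred = NULL) {
  image_id <- as.character(image_id)
  n <- length(image_id)
  chk <- function(m, what) {
    m <- lapply(m, as.matrix)
    if (!all(vapply(m, nrow, 0L) == n) ||
        !all(vapply(m, ncol, 0L) == .N_KEYPOINTS))
      stop(sprintf("annotation_set: %s matrices must be n_images x 17", what),
           call. = FALSE)
    for (f in c("x", "y", "conf"))
      colnames(m[[f]]) <- keypoint_names()
    m
  }
  gt <- chk(gt, "ground-truth")
  if (!is.null(pred)) pred <- chk(pred, "prediction")
  structure(
    list(image_id = image_id,
         width = rep_len(as.numeric(width), n),
         height = rep_len(as.numeric(height), n),
         gt = gt, pred = pred),
    class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d images, 17 keypoints, predictions: %s\n",
              length(x$image_id), if (is.null(x$pred)) "absent" else "present"))
  invisible(x)
}

# COCO visibility flag (0/1/2) <-> confidence channel (0/0.5/1)
.vis_to_conf <- function(v) c(0, 0.5, 1)[pmin(pmax(as.integer(v), 0L), 2L) + 1L]
.conf_to_vis <- function(conf) ifelse(conf <= 0, 0L, ifelse(conf < 1, 1L, 2L))

.parse_kp_triplets <- function(kp, where) {
  kp <- as.numeric(unlist(kp))
  if (length(kp) != 3L * .N_KEYPOINTS)
    stop(sprintf("%s: expected 51 keypoint values (17 x/y/v triplets), got %d",
                 where, length(kp)), call. = FALSE)
  idx <- seq(1L, by = 3L, length.out = .N_KEYPOINTS)
  list(x = kp[idx], y = kp[idx + 1L], v = kp[idx + 2L])
}

#' Read ground-truth keypoints from a COCO keypoint JSON file
#'
#' Parses a COCO-style keypoint annotation file (`images`, `annotations`
#' and `categories` arrays, 51-value keypoint vectors) into an
#' [annotation_set()]. One annotation per image is expected (one infant per
#' frame). COCO visibility flags 0/1/2 are mapped to confidence 0/0.5/1.
#'
#' @param path Path to the JSON file.
#' @return An `annotation_set` with ground truth only.
#' @export
read_coco_keypoints <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("malformed COCO JSON in '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (is.null(doc$images) || is.null(doc$annotations))
    stop("malformed COCO JSON: missing 'images' or 'annotations' array",
         call. = FALSE)
  imgs <- doc$images
  img_id <- vapply(imgs, function(i) as.character(i$id), "")
  width <- vapply(imgs, function(i) as.numeric(i$width), 0)
  height <- vapply(imgs, function(i) as.numeric(i$height), 0)
  n <- length(img_id)
  x <- y <- conf <- matrix(NA_real_, n, .N_KEYPOINTS)
  seen <- logical(n)
  for (a in doc$annotations) {
    id <- as.character(a$image_id)
    i <- match(id, img_id)
    if (is.na(i))
      stop("annotation ", deparse(a$id),
           " refers to unknown image_id ", id, call. = FALSE)
    tri <- .parse_kp_triplets(a$keypoints,
                              paste0("annotation id ", deparse(a$id)))
    x[i, ] <- tri$x; y[i, ] <- tri$y
    conf[i, ] <- .vis_to_conf(tri$v)
    seen[i] <- TRUE
  }
  if (!all(seen))
    stop("images without annotations: ",
         paste(img_id[!seen], collapse = ", "), call. = FALSE)
  annotation_set(img_id, width, height,
                 gt = list(x = x, y = y, conf = conf))
}

#' Write an annotation set's ground truth as COCO keypoint JSON
#'
#' Inverse of [read_coco_keypoints()]: confidence 0/0.5/1 maps back to COCO
#' visibility 0/1/2, so a write/read cycle reproduces the annotation set.
#'
#' @param ann An `annotation_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coco_keypoints <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  n <- length(ann$image_id)
  images <- lapply(seq_len(n), function(i)
    list(id = ann$image_id[i], width = ann$width[i], height = ann$height[i],
         file_name = paste0(ann$image_id[i], ".png")))
  annotations <- lapply(seq_len(n), function(i) {
    v <- .conf_to_vis(ann$gt$conf[i, ])
    kp <- as.vector(rbind(ann$gt$x[i, ], ann$gt$y[i, ], v))
    list(id = i, image_id = ann$image_id[i], category_id = 1L,
         keypoints = kp, num_keypoints = sum(v > 0))
  })
  doc <- list(
    images = images,
    annotations = annotations,
    categories = list(list(id = 1L, name = "infant",
                           keypoints = as.list(keypoint_names()),
                           skeleton = list())))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Attach model predictions to an annotation set
#'
#' Reads a COCO results-style JSON array (objects with `image_id`,
#' `keypoints` and optionally `score`) and attaches the predicted locations
#' to an existing annotation set. The third element of each keypoint triplet
#' is taken as the per-keypoint prediction confidence. Every prediction must
#' refer to an image present in the ground truth.
#'
#' @param ann An `annotation_set` holding the ground truth.
#' @param path Path to the predictions JSON file.
#' @return The `annotation_set` with `pred` populated.
#' @export
read_coco_predictions <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  recs <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                   error = function(e)
                     stop("malformed predictions JSON in '", path, "': ",
                          conditionMessage(e), call. = FALSE))
  n <- length(ann$image_id)
  x <- y <- conf <- matrix(NA_real_, n, .N_KEYPOINTS)
  for (r in recs) {
    id <- as.character(r$image_id)
    i <- match(id, ann$image_id)
    if (is.na(i))
      stop("prediction refers to image_id ", id,
           " absent from the ground truth", call. = FALSE)
    tri <- .parse_kp_triplets(r$keypoints, paste0("prediction for image ", id))
    x[i, ] <- tri$x; y[i, ] <- tri$y; conf[i, ] <- tri$v
  }
  ann$pred <- list(x = x, y = y, conf = conf)
  for (f in c("x", "y", "conf")) colnames(ann$pred[[f]]) <- keypoint_names()
  ann
}
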