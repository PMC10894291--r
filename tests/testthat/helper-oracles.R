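# Independent oracles and fixture builders used across the suite.

# Brute-force normalized autocorrelation: direct summation, written
# independently of the package implementation.
acf_oracle <- function(y, k) {
  T_ <- length(y)
  ybar <- sum(y) / T_
  num <- 0
  for (t in seq_len(T_ - k)) num <- num + (y[t] - ybar) * (y[t + k] - ybar)
  den <- 0
  for (t in seq_len(T_)) den <- den + (y[t] - ybar)^2
  num / den
}

# Exact two-sample permutation p-value on the difference of means
# (all choose(n1 + n2, n1) relabelings).
perm_p_two_sample <- function(x, y) {
  v <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(v), n1)
  obs <- abs(mean(x) - mean(y))
  d <- apply(idx, 2, function(i) abs(mean(v[i]) - mean(v[-i])))
  mean(d >= obs - 1e-12)
}

# Exact paired sign-flip p-value over all 2^n sign patterns.
signflip_p_paired <- function(d) {
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  obs <- abs(sum(d))
  stat <- abs(signs %*% d)
  mean(stat >= obs - 1e-12)
}

# A minimal valid pose sequence whose frames repeat one static posture.
make_static_seq <- function(n = 3, fps = 30, gma_label = "unknown") {
  kp <- keypoint_names()
  x <- matrix(rep(seq(100, 260, by = 10), each = n), n, 17)
  y <- matrix(rep(seq(50, 210, by = 10), each = n), n, 17)
  colnames(x) <- colnames(y) <- kp
  pose_sequence(x, y, fps = fps, subject_id = "static", gma_label = gma_label)
}

# Write a COCO ground-truth JSON from raw coordinate matrices,
# independently of write_coco_keypoints().
write_coco_fixture <- function(path, x, y, vis, width = 640, height = 480) {
  n <- nrow(x)
  images <- lapply(seq_len(n), function(i)
    list(id = i, width = width, height = height,
         file_name = sprintf("img%03d.png", i)))
  annotations <- lapply(seq_len(n), function(i)
    list(id = i, image_id = i, category_id = 1,
         keypoints = as.vector(rbind(x[i, ], y[i, ], vis[i, ])),
         num_keypoints = sum(vis[i, ] > 0)))
  doc <- list(images = images, annotations = annotations,
              categories = list(list(id = 1, name = "infant",
                                     keypoints = as.list(keypoint_names()),
                                     skeleton = list())))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  path
}

# Write a COCO results-format predictions JSON.
write_pred_fixture <- function(path, image_ids, x, y, conf = 1) {
  n <- nrow(x)
  if (length(conf) == 1) conf <- matrix(conf, n, ncol(x))
  recs <- lapply(seq_len(n), function(i)
    list(image_id = image_ids[i],
         keypoints = as.vector(rbind(x[i, ], y[i, ], conf[i, ])),
         score = 1))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  path
}

expect_seq_equal <- function(a, b, tol = 1e-9) {
  expect_equal(a$frame_index, b$frame_index)
  expect_equal(a$fps, b$fps)
  expect_equal(a$subject_id, b$subject_id)
  expect_equal(a$gma_label, b$gma_label)
  expect_lt(max(abs(a$x - b$x)), tol)
  expect_lt(max(abs(a$y - b$y)), tol)
  expect_lt(max(abs(a$conf - b$conf)), tol)
}

lower_joints <- c("r_hip", "l_hip", "r_knee", "l_knee")
upper_joints <- c("r_elbow", "l_elbow", "r_shoulder", "l_shoulder")
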