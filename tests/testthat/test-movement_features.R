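test_that("the eight canonical anchors follow anatomical adjacency", {
  ca <- canonical_anchors()
  expect_equal(nrow(ca), 8)
  expect_equal(ca$joint, c("r_elbow", "l_elbow", "r_shoulder", "l_shoulder",
                           "r_hip", "l_hip", "r_knee", "l_knee"))
  le <- ca[ca$joint == "l_elbow", ]
  expect_equal(le$anchor, "left_elbow")
  expect_setequal(c(le$endpoint_a, le$endpoint_b),
                  c("left_shoulder", "left_wrist"))
  rk <- ca[ca$joint == "r_knee", ]
  expect_equal(rk$anchor, "right_knee")
  expect_setequal(c(rk$endpoint_a, rk$endpoint_b),
                  c("right_hip", "right_ankle"))
  # anchor and endpoints pairwise distinct in every row
  for (i in 1:8)
    expect_length(unique(unlist(ca[i, c("anchor", "endpoint_a", "endpoint_b")])), 3)
})

test_that("cosine similarity reproduces the cardinal geometries", {
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(2, 3), c(4, 6)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(-5, 0)), -1)
  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), sqrt(2) / 2,
               tolerance = 1e-12)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "degenerate")
})

test_that("angle extraction recovers constructed joint geometries", {
  s <- make_static_seq(2)
  kp <- keypoint_names()
  # left arm: shoulder (0,0), elbow (0,10), wrist (10,10) -> right angle
  s$x[, kp == "left_shoulder"] <- 0;  s$y[, kp == "left_shoulder"] <- 0
  s$x[, kp == "left_elbow"] <- 0;     s$y[, kp == "left_elbow"] <- 10
  s$x[, kp == "left_wrist"] <- 10;    s$y[, kp == "left_wrist"] <- 10
  ang <- angle_timeseries(s, "l_elbow")
  expect_equal(ang$values, c(0, 0))

  # fully extended arm: elbow between shoulder and wrist, collinear
  s$x[, kp == "left_wrist"] <- 0; s$y[, kp == "left_wrist"] <- 20
  ang <- angle_timeseries(s, "l_elbow")
  expect_equal(ang$values, c(-1, -1))
})

test_that("angle series are invariant under similarity transforms and mirroring", {
  set.seed(5)
  co <- generate_cohort(1, params_normal = movement_params("normal", duration_s = 4),
                        params_cs = movement_params("cramped_synchronized", duration_s = 4),
                        master_seed = 8)
  s <- co$sequences[[1]]
  base <- sapply(canonical_anchors()$joint,
                 function(j) angle_timeseries(s, j)$values)
  for (i in 1:5) {
    th <- runif(1, 0, 2 * pi); sc <- runif(1, 0.2, 5)
    tx <- runif(1, -200, 200); ty <- runif(1, -200, 200)
    s2 <- s
    s2$x <- sc * (cos(th) * s$x - sin(th) * s$y) + tx
    s2$y <- sc * (sin(th) * s$x + cos(th) * s$y) + ty
    trans <- sapply(canonical_anchors()$joint,
                    function(j) angle_timeseries(s2, j)$values)
    expect_lt(max(abs(trans - base)), 1e-9)
  }
  # reflection of all x-coordinates leaves every cosine unchanged, so the
  # mirrored skeleton's right-joint series equals the original left series
  s3 <- s
  s3$x <- -s$x
  mirr <- sapply(canonical_anchors()$joint,
                 function(j) angle_timeseries(s3, j)$values)
  expect_lt(max(abs(mirr - base)), 1e-12)
})

test_that("low-confidence frames are masked and short gaps interpolated", {
  s <- make_static_seq(12)
  kp <- keypoint_names()
  # a moving wrist so interpolation is observable
  s$x[, kp == "left_shoulder"] <- 0; s$y[, kp == "left_shoulder"] <- 0
  s$x[, kp == "left_elbow"] <- 0;    s$y[, kp == "left_elbow"] <- 10
  s$x[, kp == "left_wrist"] <- seq(0, 22, by = 2)
  s$y[, kp == "left_wrist"] <- 10
  full <- angle_timeseries(s, "l_elbow")$values
  s$conf[5:6, kp == "left_wrist"] <- 0.1
  masked <- angle_timeseries(s, "l_elbow", min_confidence = 0.5, max_gap = 5)
  interp <- approx(c(4, 7), full[c(4, 7)], xout = 5:6)$y
  expect_equal(masked$values[5:6], interp, tolerance = 1e-12)
  # a gap longer than max_gap stays missing
  masked2 <- angle_timeseries(s, "l_elbow", min_confidence = 0.5, max_gap = 1)
  expect_true(all(is.na(masked2$values[5:6])))
  # everything masked -> error
  s$conf[, kp == "left_wrist"] <- 0.1
  expect_error(angle_timeseries(s, "l_elbow", min_confidence = 0.5),
               "all frames missing")
})

test_that("normalized autocorrelation matches the brute-force oracle to 1e-12", {
  set.seed(21)
  for (i in 1:12) {
    T_ <- sample(50:2000, 1)
    y <- switch(1 + i %% 3,
                rnorm(T_),
                as.numeric(arima.sim(list(ar = 0.8), T_)),
                runif(T_, -1, 1))
    for (k in unique(c(0L, 1L, sample(1:(T_ - 2), 3)))) {
      expect_equal(normalized_autocorrelation(y, k), acf_oracle(y, k),
                   tolerance = 1e-12)
    }
  }
})

test_that("autocorrelation identities: lag 0, alternating series, sinusoid at its period", {
  set.seed(3)
  expect_identical(normalized_autocorrelation(rnorm(50), 0), 1)

  alt <- rep(c(1, -1), 50)
  expect_equal(normalized_autocorrelation(alt, 1), -99 / 100, tolerance = 1e-12)
  expect_equal(acf_oracle(alt, 1), -0.99, tolerance = 1e-12)

  T_ <- 9000; P <- 30
  y <- sin(2 * pi * seq_len(T_) / P)
  r <- normalized_autocorrelation(y, P)
  expect_equal(r, 1 - P / T_, tolerance = 1e-3)
  expect_equal(r, acf_oracle(y, P), tolerance = 1e-12)
})

test_that("autocorrelation estimator rejects degenerate inputs", {
  expect_error(normalized_autocorrelation(rep(0.3, 100), 5), "constant")
  expect_error(normalized_autocorrelation(rnorm(10), 10), "smaller than")
  y <- c(1, 2, rep(NA, 50), 3)
  expect_error(normalized_autocorrelation(y, 2), "at least")
})

test_that("|r| <= 1 holds across random series and lags, with NA holes", {
  set.seed(77)
  for (i in 1:200) {
    T_ <- sample(20:300, 1)
    y <- switch(1 + i %% 4,
                rnorm(T_),
                cumsum(rnorm(T_)),
                rep_len(c(5, -5, 2), T_) + rnorm(T_, 0, 0.01),
                runif(T_))
    if (i %% 5 == 0) y[sample(T_, T_ %/% 10)] <- NA
    k <- sample(0:(T_ %/% 2), 1)
    r <- tryCatch(normalized_autocorrelation(y, k), error = function(e) NULL)
    if (!is.null(r)) expect_lte(abs(r), 1)
  }
})

test_that("sample ACF recovers AR(1) dynamics and stays in the white-noise band", {
  set.seed(42)
  phi <- 0.8
  y <- as.numeric(arima.sim(list(ar = phi), 9000))
  for (k in 1:3)
    expect_lt(abs(normalized_autocorrelation(y, k) - phi^k), 0.04)

  wn <- rnorm(5400)
  prof <- acf_profile(wn, fps = 30)
  expect_true(all(abs(prof$r) < 0.05))  # 2.58 / sqrt(T) band with margin
})

test_that("acf_profile converts second lags to frame lags by rounding", {
  s <- angle_series("l_knee",
                    0.8 * sin(seq_len(1200) / 7) + 0.15 * sin(seq_len(1200) / 3),
                    30)
  prof <- acf_profile(s)
  expect_equal(prof$lag_frames, c(30L, 60L, 90L, 150L, 210L, 330L, 390L))
  expect_equal(prof$lags_s, c(1, 2, 3, 5, 7, 11, 13))

  expect_equal(acf_profile(s, lags_seconds = 0)$r, 1)
  # half-frame lags round away from zero: 0.05 s at 30 fps -> 2 frames
  expect_equal(acf_profile(s, lags_seconds = 0.05)$lag_frames, 2L)
  # fps carried on the series governs the conversion
  s2 <- angle_series("l_knee", s$values, 10)
  expect_equal(acf_profile(s2, lags_seconds = 2)$lag_frames, 20L)
})

test_that("extract_features emits one tidy row per subject, joint and lag", {
  co <- generate_cohort(1, params_normal = movement_params("normal", duration_s = 20),
                        params_cs = movement_params("cramped_synchronized", duration_s = 20),
                        master_seed = 4)
  f <- extract_features(co, lags_seconds = c(1, 2))
  expect_equal(nrow(f), 2 * 8 * 2)
  expect_setequal(unique(f$joint), canonical_anchors()$joint)
  expect_setequal(unique(f$gma_label), c("normal", "cramped_synchronized"))
  expect_true(all(abs(f$r) <= 1))
})
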