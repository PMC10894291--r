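# Run code with a locally seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Stationary Ornstein-Uhlenbeck sample path as an AR(1) recursion.
.ou_path <- function(n, tau_frames, sd_stat) {
  if (sd_stat <= 0 || n == 0L) return(numeric(n))
  a <- exp(-1 / tau_frames)
  innov <- stats::rnorm(n, 0, sd_stat * sqrt(1 - a^2))
  as.numeric(stats::filter(innov, a, method = "recursive",
                           init = stats::rnorm(1, 0, sd_stat)))
}

.upper_joints <- c("r_elbow", "l_elbow", "r_shoulder", "l_shoulder")

#' Movement simulation parameters
#'
#' Parameter set for one simulated subject's angle dynamics. The two
#' classes emulate the contrast the analysis is built to detect:
#'
#' * **normal**: irregular, weakly coupled movement -- each joint follows a
#'   mean-reverting colored-noise (Ornstein-Uhlenbeck) process with
#'   correlation time `1 / (2 * pi * smoothness_bandwidth)`, sharing only a
#'   small common component (`inter_limb_phase_coupling`) across joints.
#'   Upper limbs get twice the bandwidth (more degrees of freedom).
#' * **cramped_synchronized**: stereotyped, inter-limb-synchronized
#'   flexion-extension. The lower limbs share a common drive made of an
#'   oscillation of period `oscillation_period_s`, a slow tonus modulation
#'   (`slow_period_s`, `slow_amplitude`) with a random drift
#'   (`drift_sd`, `drift_tau_s`), and a constant `extension_bias` pushing
#'   the cosine baseline toward -1 (extension). Per-joint phase offsets
#'   shrink to zero as the coupling approaches 1. Upper limbs couple (at
#'   `upper_limb_coupling`, defaulting to the normal-class coupling) to the
#'   shared oscillation only, not to the slow stereotypy -- arms
#'   participate in the synchronized bursts but their slow posture wanders
#'   freely, which reproduces the empirical pattern that autocorrelation
#'   separates the classes in the lower limbs only.
#'
#' All components are summed, white measurement noise (`noise_sd`) is
#' added, and the result is clamped to the valid cosine range `[-1, 1]`.
#'
#' @param gma_class `"normal"` or `"cramped_synchronized"`.
#' @param duration_s Recording length in seconds (default 180, the typical
#'   clinical recording of roughly 3 minutes).
#' @param fps Frames per second (default 30).
#' @param oscillation_period_s Period of the synchronized flexion-extension
#'   oscillation, seconds (default 3).
#' @param amplitude Oscillation amplitude in cosine units (default 0.22).
#' @param slow_period_s Period of the slow tonus modulation, seconds
#'   (default 75).
#' @param slow_amplitude Amplitude of the slow tonus modulation (default
#'   0.5 for the CS class, 0 for normal).
#' @param drift_sd,drift_tau_s Stationary sd and correlation time (s) of
#'   the random stereotypy drift (defaults 0.25 and 12 for CS, 0 drift for
#'   normal).
#' @param inter_limb_phase_coupling Coupling of each joint to the shared
#'   drive, in `[0, 1]` (default 0.95 for CS lower limbs, 0.15 for normal).
#' @param upper_limb_coupling Coupling of the upper limbs (default 0.15,
#'   the normal-class value, for both classes).
#' @param extension_bias Constant shift of the cosine baseline, in
#'   `[-1, 0]` (default -0.35 for CS, 0 for normal).
#' @param noise_sd Additive white measurement noise, cosine units
#'   (default 0.04).
#' @param process_sd Stationary sd of the per-joint colored-noise process
#'   (default 0.25).
#' @param smoothness_bandwidth Bandwidth (Hz) of the colored noise; the
#'   correlation time is `1 / (2 * pi * bandwidth)` (default 0.23 Hz,
#'   i.e. about 0.7 s).
#' @param seed Integer seed making the subject's series reproducible.
#' @return An object of class `movement_params`.
#' @export
movement_params <- function(gma_class = c("normal", "cramped_synchronized"),
                            duration_s = 180, fps = 30,
                            oscillation_period_s = 3, amplitude = 0.22,
                            slow_period_s = 75,
                            slow_amplitude = if (gma_class == "cramped_synchronized") 0.5 else 0,
                            drift_sd = if (gma_class == "cramped_synchronized") 0.25 else 0,
                            drift_tau_s = 12,
                            inter_limb_phase_coupling =
                              if (gma_class == "cramped_synchronized") 0.95 else 0.15,
                            upper_limb_coupling = 0.15,
                            extension_bias =
                              if (gma_class == "cramped_synchronized") -0.35 else 0,
                            noise_sd = 0.04, process_sd = 0.25,
                            smoothness_bandwidth = 0.23, seed = 1L) {
  gma_class <- match.arg(gma_class)
  stopifnot(duration_s > 0, fps > 0, oscillation_period_s > 0,
            slow_period_s > 0, drift_tau_s > 0,
            inter_limb_phase_coupling >= 0, inter_limb_phase_coupling <= 1,
            upper_limb_coupling >= 0, upper_limb_coupling <= 1,
            extension_bias <= 0, extension_bias >= -1,
            noise_sd >= 0, process_sd >= 0, smoothness_bandwidth > 0)
  structure(list(gma_class = gma_class, duration_s = duration_s, fps = fps,
                 oscillation_period_s = oscillation_period_s,
                 amplitude = amplitude, slow_period_s = slow_period_s,
                 slow_amplitude = slow_amplitude, drift_sd = drift_sd,
                 drift_tau_s = drift_tau_s,
                 inter_limb_phase_coupling = inter_limb_phase_coupling,
                 upper_limb_coupling = upper_limb_coupling,
                 extension_bias = extension_bias, noise_sd = noise_sd,
                 process_sd = process_sd,
                 smoothness_bandwidth = smoothness_bandwidth,
                 seed = as.integer(seed)),
            class = "movement_params")
}

#' Simulate the eight joint-angle series of one subject
#'
#' Generates the full frames x 8 matrix of cosine-similarity angle values
#' for one subject under a [movement_params()] setting. The output is a
#' pure function of the parameters (including the seed): the shared drive
#' and every per-joint component are drawn in a fixed order from a
#' locally-seeded RNG.
#'
#' @param params A [movement_params()].
#' @return Numeric matrix, frames x 8, with the canonical joint names
#'   (see [canonical_anchors()]) as columns, values in `[-1, 1]`.
#' @export
simulate_angle_set <- function(params) {
  stopifnot(inherits(params, "movement_params"))
  p <- params
  n <- as.integer(round(p$duration_s * p$fps))
  tau_frames <- p$fps / (2 * pi * p$smoothness_bandwidth)
  joints <- canonical_anchors()$joint
  .with_seed(p$seed, {
    t_ <- seq_len(n)
    ph0 <- stats::runif(1, 0, 2 * pi)
    ph2 <- stats::runif(1, 0, 2 * pi)
    slow <- p$slow_amplitude *
      sin(2 * pi * t_ / (p$slow_period_s * p$fps) + ph2) +
      .ou_path(n, p$drift_tau_s * p$fps, p$drift_sd)
    shared_ou <- .ou_path(n, tau_frames, p$process_sd)
    out <- matrix(NA_real_, n, length(joints),
                  dimnames = list(NULL, joints))
    for (j in joints) {
      upper <- j %in% .upper_joints
      tau_j <- if (upper) tau_frames / 2 else tau_frames
      if (p$gma_class == "cramped_synchronized") {
        w <- if (upper) p$upper_limb_coupling else p$inter_limb_phase_coupling
        phase_off <- (1 - w) * stats::runif(1, -1, 1) * pi
        osc <- p$amplitude *
          sin(2 * pi * t_ / (p$oscillation_period_s * p$fps) + ph0 + phase_off)
        drive <- if (upper) osc else osc + slow
        y <- w * p$extension_bias + w * drive +
          sqrt(1 - w^2) * .ou_path(n, tau_j, p$process_sd)
      } else {
        w <- p$inter_limb_phase_coupling
        y <- p$extension_bias * w + w * shared_ou +
          sqrt(1 - w^2) * .ou_path(n, tau_j, p$process_sd)
      }
      y <- y + stats::rnorm(n, 0, p$noise_sd)
      out[, j] <- pmin(1, pmax(-1, y))
    }
    out
  })
}

#' Simulate one joint-angle series
#'
#' Convenience wrapper around [simulate_angle_set()] returning a single
#' joint's series as an [angle_series()]. Because the whole subject is
#' generated at once, series of different joints requested under the same
#' parameters are mutually consistent (they share the common drive).
#'
#' @param params A [movement_params()].
#' @param joint One of the canonical joint names.
#' @return An [angle_series()].
#' @export
simulate_angle_series <- function(params, joint) {
  m <- simulate_angle_set(params)
  if (!joint %in% colnames(m))
    stop("unknown joint: ", joint, call. = FALSE)
  angle_series(joint, m[, joint], params$fps)
}

#' Planar infant skeleton layout
#'
#' Fixed geometry of the synthetic supine infant used by
#' [angles_to_keypoints()]: torso keypoints (shoulders, hips) and head
#' keypoints sit at constant pixel positions; limb segment lengths bound
#' the forward-kinematic reach so that every generated keypoint stays
#' inside the image. `side` mirrors the layout in x for symmetry checks.
#'
#' @param image_width,image_height Image size in pixels.
#' @param shoulder_center,hip_center Midpoints of the shoulder/hip lines,
#'   `c(x, y)` pixels.
#' @param shoulder_halfwidth,hip_halfwidth Half the shoulder/hip widths.
#' @param upper_arm,forearm,thigh,shank Limb segment lengths in pixels.
#' @param side `+1` for the standard layout (subject's left on larger x),
#'   `-1` for the mirror image.
#' @return An object of class `infant_layout`.
#' @export
infant_layout <- function(image_width = 640, image_height = 480,
                          shoulder_center = c(320, 160),
                          hip_center = c(320, 280),
                          shoulder_halfwidth = 60, hip_halfwidth = 45,
                          upper_arm = 70, forearm = 60,
                          thigh = 85, shank = 75, side = 1) {
  stopifnot(all(c(shoulder_halfwidth, hip_halfwidth, upper_arm, forearm,
                  thigh, shank) > 0),
            side %in% c(-1, 1))
  structure(list(image_width = image_width, image_height = image_height,
                 shoulder_center = shoulder_center, hip_center = hip_center,
                 shoulder_halfwidth = shoulder_halfwidth,
                 hip_halfwidth = hip_halfwidth,
                 upper_arm = upper_arm, forearm = forearm,
                 thigh = thigh, shank = shank, side = side),
            class = "infant_layout")
}

.rot_apply <- function(theta, v, s) {
  # rotate constant unit vector v by s * theta (theta vectorized)
  ct <- cos(s * theta); st <- sin(s * theta)
  cbind(ct * v[1] - st * v[2], st * v[1] + ct * v[2])
}

#' Forward kinematics: angle series to keypoint sequence
#'
#' Places a planar infant skeleton so that, at every frame, the cosine of
#' the angle at each of the eight canonical anchors equals the requested
#' series value. Shoulders, hips and head keypoints sit at the fixed layout
#' positions; elbows/wrists and knees/ankles are placed by rotating the
#' fixed torso-reference direction by `acos(value)` about the anchor (the
#' left side rotates one way, the right side the other). Running
#' [angle_timeseries()] on the output recovers each input series to within
#' floating-point error.
#'
#' @param angles A frames x 8 matrix with canonical joint columns (as from
#'   [simulate_angle_set()]), or a list of eight [angle_series()].
#' @param layout An [infant_layout()].
#' @param fps Frames per second (required when `angles` is a bare matrix;
#'   otherwise taken from the series).
#' @param subject_id,gma_label Metadata for the resulting sequence.
#' @return A [pose_sequence()] with confidence 1 everywhere.
#' @export
angles_to_keypoints <- function(angles, layout = infant_layout(), fps = NULL,
                                subject_id = "synthetic",
                                gma_label = "unknown") {
  joints <- canonical_anchors()$joint
  if (is.list(angles) && !is.matrix(angles)) {
    if (length(angles) != 8L)
      stop("need exactly eight angle series", call. = FALSE)
    lens <- vapply(angles, function(a) length(a$values), 0L)
    fpss <- vapply(angles, function(a) a$fps, 0)
    if (length(unique(lens)) != 1L || length(unique(fpss)) != 1L)
      stop("angle series have inconsistent lengths or fps", call. = FALSE)
    if (is.null(fps)) fps <- fpss[1]
    m <- do.call(cbind, lapply(angles, function(a) a$values))
    colnames(m) <- vapply(angles, function(a) a$joint, "")
    angles <- m
  }
  if (is.null(fps))
    stop("fps must be given when angles is a bare matrix", call. = FALSE)
  if (!all(joints %in% colnames(angles)))
    stop("angle matrix must have the eight canonical joint columns",
         call. = FALSE)
  angles <- angles[, joints, drop = FALSE]
  if (anyNA(angles))
    stop("angle matrix contains missing values; fill gaps first", call. = FALSE)
  n <- nrow(angles)
  L <- layout
  kp <- keypoint_names()
  X <- matrix(NA_real_, n, .N_KEYPOINTS, dimnames = list(NULL, kp))
  Y <- matrix(NA_real_, n, .N_KEYPOINTS, dimnames = list(NULL, kp))
  setkp <- function(name, px, py) {
    X[, name] <<- px; Y[, name] <<- py
  }
  sc <- L$shoulder_center; hc <- L$hip_center; sgn <- L$side
  # fixed head and torso keypoints
  setkp("nose", sc[1], sc[2] - 50)
  setkp("left_eye",  sc[1] + sgn * 18, sc[2] - 62)
  setkp("right_eye", sc[1] - sgn * 18, sc[2] - 62)
  setkp("left_ear",  sc[1] + sgn * 34, sc[2] - 54)
  setkp("right_ear", sc[1] - sgn * 34, sc[2] - 54)
  torso <- list(
    left  = list(sh = c(sc[1] + sgn * L$shoulder_halfwidth, sc[2]),
                 hp = c(hc[1] + sgn * L$hip_halfwidth, hc[2]), s = +1),
    right = list(sh = c(sc[1] - sgn * L$shoulder_halfwidth, sc[2]),
                 hp = c(hc[1] - sgn * L$hip_halfwidth, hc[2]), s = -1))
  unit <- function(v) v / sqrt(sum(v^2))
  for (sd_ in names(torso)) {
    tg <- torso[[sd_]]
    pre <- if (sd_ == "left") "l_" else "r_"
    kpre <- paste0(sd_, "_")
    setkp(paste0(kpre, "shoulder"), tg$sh[1], tg$sh[2])
    setkp(paste0(kpre, "hip"), tg$hp[1], tg$hp[2])
    s <- tg$s * sgn
    # arm: shoulder anchor references the shoulder->hip direction
    th_sh <- acos(pmin(1, pmax(-1, angles[, paste0(pre, "shoulder")])))
    u <- unit(tg$hp - tg$sh)
    elb <- .rot_apply(th_sh, u, s) * L$upper_arm
    ex <- tg$sh[1] + elb[, 1]; ey <- tg$sh[2] + elb[, 2]
    setkp(paste0(kpre, "elbow"), ex, ey)
    # elbow anchor references the elbow->shoulder direction
    th_el <- acos(pmin(1, pmax(-1, angles[, paste0(pre, "elbow")])))
    vx <- (tg$sh[1] - ex) / L$upper_arm; vy <- (tg$sh[2] - ey) / L$upper_arm
    ct <- cos(s * th_el); st <- sin(s * th_el)
    setkp(paste0(kpre, "wrist"),
          ex + L$forearm * (ct * vx - st * vy),
          ey + L$forearm * (st * vx + ct * vy))
    # leg: hip anchor references the hip->shoulder direction
    th_hp <- acos(pmin(1, pmax(-1, angles[, paste0(pre, "hip")])))
    u2 <- unit(tg$sh - tg$hp)
    kne <- .rot_apply(th_hp, u2, s) * L$thigh
    kx <- tg$hp[1] + kne[, 1]; ky <- tg$hp[2] + kne[, 2]
    setkp(paste0(kpre, "knee"), kx, ky)
    # knee anchor references the knee->hip direction
    th_kn <- acos(pmin(1, pmax(-1, angles[, paste0(pre, "knee")])))
    wx <- (tg$hp[1] - kx) / L$thigh; wy <- (tg$hp[2] - ky) / L$thigh
    ck <- cos(s * th_kn); sk <- sin(s * th_kn)
    setkp(paste0(kpre, "ankle"),
          kx + L$shank * (ck * wx - sk * wy),
          ky + L$shank * (sk * wx + ck * wy))
  }
  pose_sequence(X, Y, conf = 1, fps = fps,
                subject_id = subject_id, gma_label = gma_label)
}

#' Generate a labelled synthetic cohort
#'
#' Simulates `n_per_group` normal and `n_per_group` cramped-synchronized
#' subjects end to end: angle dynamics under the class parameters, then
#' forward kinematics to full 17-keypoint pose sequences. Per-subject seeds
#' are derived deterministically from `master_seed`, and the oscillation
#' period, amplitude and slow period receive a per-subject jitter of
#' +/-10% for realism, so two cohorts generated from the same master seed
#' are identical.
#'
#' @param n_per_group Subjects per class (default 5, a typical pilot-study
#'   group size).
#' @param params_normal,params_cs Class parameter templates
#'   ([movement_params()]); their `seed` fields are overwritten per subject.
#' @param layout An [infant_layout()].
#' @param master_seed Integer master seed.
#' @param subject_jitter Relative jitter applied to period and amplitude
#'   per subject (default 0.1).
#' @return An object of class `synthetic_cohort`: list with `sequences`
#'   (pose sequences with labels), `manifest` (data frame of per-subject
#'   seeds and jittered parameters) and the two parameter templates.
#' @export
generate_cohort <- function(n_per_group = 5,
                            params_normal = movement_params("normal"),
                            params_cs = movement_params("cramped_synchronized"),
                            layout = infant_layout(),
                            master_seed = 1, subject_jitter = 0.1) {
  if (n_per_group < 1) stop("n_per_group must be >= 1", call. = FALSE)
  n_total <- 2L * as.integer(n_per_group)
  plan <- .with_seed(master_seed, {
    data.frame(
      subject = c(sprintf("normal_%02d", seq_len(n_per_group)),
                  sprintf("cs_%02d", seq_len(n_per_group))),
      gma_label = rep(c("normal", "cramped_synchronized"),
                      each = n_per_group),
      seed = sample.int(.Machine$integer.max, n_total),
      period_factor = stats::runif(n_total, 1 - subject_jitter,
                                   1 + subject_jitter),
      amplitude_factor = stats::runif(n_total, 1 - subject_jitter,
                                      1 + subject_jitter),
      slow_period_factor = stats::runif(n_total, 1 - subject_jitter,
                                        1 + subject_jitter),
      stringsAsFactors = FALSE)
  })
  sequences <- lapply(seq_len(n_total), function(i) {
    tpl <- if (plan$gma_label[i] == "normal") params_normal else params_cs
    tpl$seed <- plan$seed[i]
    tpl$oscillation_period_s <- tpl$oscillation_period_s * plan$period_factor[i]
    tpl$amplitude <- tpl$amplitude * plan$amplitude_factor[i]
    tpl$slow_period_s <- tpl$slow_period_s * plan$slow_period_factor[i]
    m <- simulate_angle_set(tpl)
    angles_to_keypoints(m, layout, fps = tpl$fps,
                        subject_id = plan$subject[i],
                        gma_label = plan$gma_label[i])
  })
  names(sequences) <- plan$subject
  structure(list(sequences = sequences, manifest = plan,
                 params_normal = params_normal, params_cs = params_cs,
                 layout = layout, master_seed = master_seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tab <- table(x$manifest$gma_label)
  cat(sprintf("<synthetic_cohort> %d sequences (%s), master seed %s\n",
              length(x$sequences),
              paste(names(tab), tab, sep = ": ", collapse = ", "),
              format(x$master_seed)))
  invisible(x)
}

#' Add pose-estimation jitter to a sequence
#'
#' Adds isotropic Gaussian pixel noise, independently per keypoint per
#' frame, emulating pose-model localization error. The per-keypoint
#' displacement distance is then Rayleigh-distributed with scale
#' `jitter_sd` (mean displacement `jitter_sd * sqrt(pi / 2)`).
#'
#' @param seq A [pose_sequence()].
#' @param jitter_sd Noise standard deviation in pixels, per axis (>= 0).
#' @param seed Integer seed.
#' @return A jittered copy of the sequence.
#' @export
perturb_keypoints <- function(seq, jitter_sd, seed = 1L) {
  validate_pose_sequence(seq)
  if (jitter_sd < 0) stop("jitter_sd must be >= 0", call. = FALSE)
  if (jitter_sd == 0) return(seq)
  n <- n_frames(seq)
  .with_seed(seed, {
    seq$x <- seq$x + matrix(stats::rnorm(n * .N_KEYPOINTS, 0, jitter_sd),
                            n, .N_KEYPOINTS)
    seq$y <- seq$y + matrix(stats::rnorm(n * .N_KEYPOINTS, 0, jitter_sd),
                            n, .N_KEYPOINTS)
  })
  seq
}

#' Pose sequence to annotation set
#'
#' Reinterprets the frames of a pose sequence as images of an annotation
#' set (one image per frame), with an optional second sequence providing
#' the predictions -- the bridge between the synthetic generator and OKS
#' evaluation.
#'
#' @param truth A [pose_sequence()] (ground truth).
#' @param pred Optional [pose_sequence()] of identical shape (predictions).
#' @param width,height Image dimensions in pixels.
#' @return An [annotation_set()].
#' @export
sequence_to_annotations <- function(truth, pred = NULL,
                                    width = 640, height = 480) {
  validate_pose_sequence(truth)
  ids <- sprintf("frame_%06d", truth$frame_index)
  pr <- NULL
  if (!is.null(pred)) {
    validate_pose_sequence(pred)
    if (n_frames(pred) != n_frames(truth))
      stop("truth and prediction sequences differ in length", call. = FALSE)
    pr <- list(x = pred$x, y = pred$y, conf = pred$conf)
  }
  annotation_set(ids, width, height,
                 gt = list(x = truth$x, y = truth$y, conf = truth$conf),
                 pred = pr)
}
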