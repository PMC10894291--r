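test_that("two-sided p from t reproduces tabulated df=8 values", {
  expect_equal(round(two_sided_p_from_t(-3.46, 8), 2), 0.01)
  expect_equal(round(two_sided_p_from_t(-2.39, 8), 2), 0.04)
  expect_equal(two_sided_p_from_t(0, 8), 1)
  expect_error(two_sided_p_from_t(1, 0.5), "df")
})

test_that("two-sided p is symmetric, monotone, and matches density integration", {
  set.seed(10)
  ts <- runif(20, 0, 6)
  for (df in c(1, 4, 8, 16, 30)) {
    expect_equal(two_sided_p_from_t(ts, df), two_sided_p_from_t(-ts, df))
    p <- two_sided_p_from_t(sort(ts), df)
    expect_true(all(diff(p) <= 0))
    # numerical-integration oracle of the t density over the two tails
    for (t0 in c(0.5, 2.2, 4.9)) {
      tail_mass <- integrate(function(u) dt(u, df), t0, Inf,
                             rel.tol = 1e-12)$value
      expect_equal(two_sided_p_from_t(t0, df), 2 * tail_mass,
                   tolerance = 1e-8)
    }
  }
})

test_that("benchmark t statistics are consistent with pooled df=8 p-values", {
  b <- acf_ttest_benchmark()
  p <- two_sided_p_from_t(b$t, 8)
  # printed p values come from unrounded t; rounding t to 2 decimals can
  # shift p by up to ~0.01 at df 8
  expect_true(all(abs(p - b$p_printed) <= 0.015))
  # and most cells agree exactly at the printed 2-decimal precision
  expect_gte(mean(round(p, 2) == b$p_printed), 0.9)
})

make_features <- function(vals_by_group, joints = "l_knee", lags = 5) {
  do.call(rbind, lapply(names(vals_by_group), function(g) {
    v <- vals_by_group[[g]]
    expand.grid(subject = paste0(g, seq_along(v)), joint = joints,
                lag_s = lags, KEEP.OUT.ATTRS = FALSE,
                stringsAsFactors = FALSE) |>
      transform(gma_label = g, r = rep(v, times = length(joints) * length(lags)))
  }))
}

test_that("per-cell t-tests: identity, separation limit and df bookkeeping", {
  f <- make_features(list(normal = c(0.1, 0.2, 0.3, 0.4, 0.5),
                          cramped_synchronized = c(0.1, 0.2, 0.3, 0.4, 0.5)))
  tb <- ttest_by_joint_lag(f)
  expect_equal(tb$t, 0)
  expect_equal(tb$p, 1)
  expect_equal(tb$df, 8)
  expect_false(tb$significant)

  f <- make_features(list(
    normal = c(0, 0, 0, 0, 0) + 1e-6 * (1:5),
    cramped_synchronized = c(1, 1, 1, 1, 1) + 1e-6 * (5:1)))
  tb <- ttest_by_joint_lag(f)
  expect_lt(tb$p, 1e-6)
  expect_lt(tb$t, 0)  # normal minus CS

  # exactly constant, unequal groups -> infinite-t sentinel
  f <- make_features(list(normal = rep(0, 3), cramped_synchronized = rep(1, 3)))
  tb <- ttest_by_joint_lag(f)
  expect_true(is.infinite(tb$t))
  expect_equal(tb$p, 0)

  f <- make_features(list(normal = 0.5, cramped_synchronized = c(0.1, 0.2)))
  expect_error(ttest_by_joint_lag(f), "insufficient data")
})

test_that("pooled t p-values agree with the exact permutation oracle on average", {
  set.seed(42)
  diffs <- replicate(40, {
    f <- make_features(list(normal = rnorm(5), cramped_synchronized = rnorm(5)))
    tb <- ttest_by_joint_lag(f)
    sel <- f$gma_label == "normal"
    tb$p - perm_p_two_sample(f$r[sel], f$r[!sel])
  })
  expect_lt(mean(abs(diffs)), 0.05)
  expect_lt(max(abs(diffs)), 0.2)
})

test_that("Welch variant is available and differs under unequal variances", {
  f <- make_features(list(normal = c(0.1, 0.11, 0.12, 0.09, 0.1),
                          cramped_synchronized = c(0.9, 0.2, 1.4, 0.6, -0.1)))
  pooled <- ttest_by_joint_lag(f, var_equal = TRUE)
  welch <- ttest_by_joint_lag(f, var_equal = FALSE)
  expect_equal(pooled$df, 8)
  expect_lt(welch$df, 8)
  expect_false(isTRUE(all.equal(pooled$p, welch$p)))
})

test_that("MANOVA across joints: separation, degeneracy guard and identity", {
  set.seed(9)
  mk <- function(n, shift, joints) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      rbind(data.frame(subject = paste0("n", i), gma_label = "normal",
                       joint = joints, lag_s = 5, r = rnorm(length(joints))),
            data.frame(subject = paste0("c", i), gma_label = "cramped_synchronized",
                       joint = joints, lag_s = 5,
                       r = rnorm(length(joints), mean = shift)))
    }))
  }
  joints4 <- c("r_hip", "l_hip", "r_knee", "l_knee")
  f <- mk(20, 5, joints4)
  m <- manova_across_joints(f, 5, joints = joints4)
  expect_lt(m$p, 1e-4)
  expect_lt(m$lambda, 0.5)
  # permutation oracle on Wilks' lambda: observed lambda is extreme
  obs <- m$lambda
  subj <- unique(f$subject)
  orig_lab <- f$gma_label[match(subj, f$subject)]
  perm <- replicate(200, {
    fp <- f
    map <- setNames(sample(orig_lab), subj)
    fp$gma_label <- unname(map[fp$subject])
    manova_across_joints(fp, 5, joints = joints4)$lambda
  })
  expect_lt(mean(perm <= obs), 0.02)

  # too few residual df for the response count -> informative degeneracy error
  f8 <- mk(4, 1, canonical_anchors()$joint)
  expect_error(manova_across_joints(f8, 5), "prune")

  # identical groups (same rows, different labels) -> lambda 1, p 1
  vals <- matrix(rnorm(18), 6, 3)
  fid <- do.call(rbind, lapply(1:6, function(i) {
    rbind(data.frame(subject = paste0("n", i), gma_label = "normal",
                     joint = joints4[1:3], lag_s = 5, r = vals[i, ]),
          data.frame(subject = paste0("c", i), gma_label = "cramped_synchronized",
                     joint = joints4[1:3], lag_s = 5, r = vals[i, ]))
  }))
  m <- manova_across_joints(fid, 5, joints = joints4[1:3])
  expect_equal(m$lambda, 1, tolerance = 1e-10)
  expect_equal(m$p, 1, tolerance = 1e-10)
})

test_that("MANOVA p-values are uniform under label permutation (null calibration)", {
  set.seed(123)
  joints4 <- c("r_hip", "l_hip", "r_knee", "l_knee")
  ps <- replicate(200, {
    f <- do.call(rbind, lapply(1:20, function(i) {
      g <- if (i <= 10) "normal" else "cramped_synchronized"
      data.frame(subject = paste0("s", i), gma_label = g,
                 joint = joints4, lag_s = 5, r = rnorm(4))
    }))
    manova_across_joints(f, 5, joints = joints4)$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("comparison summaries format cells as 't (p)' with 2 decimals", {
  f <- make_features(list(normal = c(0.1, 0.2, 0.3, 0.4, 0.5),
                          cramped_synchronized = c(0.1, 0.2, 0.3, 0.4, 0.5)),
                     joints = c("r_knee", "l_knee"), lags = c(5, 7))
  tb <- ttest_by_joint_lag(f)
  sm <- summarize_comparison(tb)
  expect_equal(nrow(sm$grid), 2)
  expect_true(all(c("r_knee", "l_knee") %in% names(sm$grid)))
  expect_equal(sm$grid$r_knee[1], "0.00 (1.00)")
  expect_equal(nrow(sm$significant), 0)

  # formatting example: t = -3.46, p = 0.0086 -> "-3.46 (0.01)"
  tb$t[1] <- -3.46; tb$p[1] <- 0.0086
  sm <- summarize_comparison(tb)
  expect_equal(sm$grid$r_knee[1], "-3.46 (0.01)")
})
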