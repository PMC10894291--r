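#' Two-sided p-value from a t statistic
#'
#' \eqn{p = 2 (1 - F_t(|t|; df))} with \eqn{F_t} the Student t cumulative
#' distribution. Symmetric in the sign of `t` and monotone decreasing in
#' `|t|`.
#'
#' @param t Numeric t statistic(s).
#' @param df Degrees of freedom, >= 1.
#' @return Two-sided p-value(s) in `[0, 1]`.
#' @export
#' @examples
#' two_sided_p_from_t(-3.46, 8)  # 0.0086 -> prints as 0.01
#' two_sided_p_from_t(0, 8)      # 1
two_sided_p_from_t <- function(t, df) {
  if (any(df < 1)) stop("df must be >= 1", call. = FALSE)
  2 * stats::pt(abs(t), df = df, lower.tail = FALSE)
}

#' Per-joint, per-lag two-sample t-tests between cohorts
#'
#' For every (joint, lag) cell of a tidy feature table (see
#' [extract_features()]), compares the autocorrelation values of the two
#' labelled groups with an independent two-sample t-test. The default is
#' the pooled-variance Student test (df = n1 + n2 - 2); Welch's unequal
#' variance test is available with `var_equal = FALSE`. The t statistic is
#' signed as group 1 minus group 2 (default: normal minus
#' cramped-synchronized, so stereotyped movement shows up as negative t).
#'
#' Cells where both groups are constant get t = 0, p = 1 when the means
#' agree, and an infinite-t sentinel with p = 0 when they differ.
#'
#' @param features Data frame with columns `gma_label`, `joint`, `lag_s`,
#'   `r` (and usually `subject`).
#' @param alpha Per-cell significance level for flagging (default 0.05).
#' @param var_equal Pooled Student test if `TRUE` (default), Welch otherwise.
#' @param groups Length-2 character vector naming the two `gma_label`
#'   levels, in the order entering the difference.
#' @return A data frame of class `gm_comparison` with columns `joint`,
#'   `lag_s`, `t`, `df`, `p`, `significant`, plus attributes `alpha`,
#'   `groups` and `n` (the group sizes).
#' @export
ttest_by_joint_lag <- function(features, alpha = 0.05, var_equal = TRUE,
                               groups = c("normal", "cramped_synchronized")) {
  stopifnot(length(groups) == 2L)
  f <- features[features$gma_label %in% groups, , drop = FALSE]
  if (!nrow(f)) stop("no rows for the requested groups", call. = FALSE)
  joints <- unique(features$joint)
  lags <- sort(unique(features$lag_s))
  cells <- expand.grid(joint = joints, lag_s = lags,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- f$joint == cells$joint[i] & f$lag_s == cells$lag_s[i]
    x <- f$r[sel & f$gma_label == groups[1]]
    y <- f$r[sel & f$gma_label == groups[2]]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2L || length(y) < 2L)
      stop(sprintf("insufficient data in cell (%s, %g s): need >= 2 per group",
                   cells$joint[i], cells$lag_s[i]), call. = FALSE)
    df_ <- if (var_equal) length(x) + length(y) - 2 else NA_real_
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      if (mean(x) == mean(y)) {
        c(t = 0, df = df_, p = 1)
      } else {
        c(t = sign(mean(x) - mean(y)) * Inf, df = df_, p = 0)
      }
    } else {
      tt <- stats::t.test(x, y, var.equal = var_equal)
      c(t = unname(tt$statistic), df = unname(tt$parameter),
        p = tt$p.value)
    }
  })
  res <- do.call(rbind, res)
  out <- data.frame(joint = cells$joint, lag_s = cells$lag_s,
                    t = res[, "t"], df = res[, "df"], p = res[, "p"],
                    significant = res[, "p"] < alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$lag_s, match(out$joint, canonical_anchors()$joint)), ]
  rownames(out) <- NULL
  structure(out, class = c("gm_comparison", "data.frame"),
            alpha = alpha, groups = groups,
            n = c(sum(f$gma_label == groups[1] & f$joint == joints[1] &
                        f$lag_s == lags[1]),
                  sum(f$gma_label == groups[2] & f$joint == joints[1] &
                        f$lag_s == lags[1])))
}

#' One-way MANOVA across joints at a fixed lag
#'
#' Omnibus test of a group difference in the joint vector of
#' autocorrelation values (all joints as responses) at one lag, using
#' Wilks' lambda with its F approximation. Requires strictly more residual
#' degrees of freedom (subjects minus 2) than response columns; with few
#' subjects, prune `joints` down (e.g. to the lower limbs) so the
#' within-group covariance stays well-conditioned.
#'
#' @param features Tidy feature table (see [extract_features()]).
#' @param lag Lag in seconds selecting the feature columns.
#' @param groups Length-2 character vector of `gma_label` levels.
#' @param joints Joints used as response columns (default: all present).
#' @return List with `lambda` (Wilks), `F`, `df1`, `df2`, `p`.
#' @export
manova_across_joints <- function(features, lag,
                                 groups = c("normal", "cramped_synchronized"),
                                 joints = NULL) {
  f <- features[features$lag_s == lag & features$gma_label %in% groups, ,
                drop = FALSE]
  if (!nrow(f)) stop("no feature rows at lag ", lag, " s", call. = FALSE)
  if (is.null(joints)) joints <- unique(f$joint)
  f <- f[f$joint %in% joints, , drop = FALSE]
  wide <- stats::reshape(f[c("subject", "gma_label", "joint", "r")],
                         idvar = c("subject", "gma_label"),
                         timevar = "joint", direction = "wide")
  Y <- as.matrix(wide[, paste0("r.", joints), drop = FALSE])
  g <- factor(wide$gma_label, levels = groups)
  if (any(table(g) < 2L))
    stop("each group needs >= 2 subjects", call. = FALSE)
  if (nrow(Y) - 2L <= ncol(Y))
    stop("singular within-group covariance: fewer residual degrees of ",
         "freedom (", nrow(Y) - 2L, ") than response columns (", ncol(Y),
         "); prune the joint set (e.g. lower limbs only)", call. = FALSE)
  fit <- stats::manova(Y ~ g)
  sm <- tryCatch(summary(fit, test = "Wilks")$stats,
                 error = function(e)
                   stop("singular within-group covariance: ",
                        conditionMessage(e),
                        "; prune the joint set", call. = FALSE))
  list(lambda = unname(sm[1, "Wilks"]),
       F = unname(sm[1, "approx F"]),
       df1 = unname(sm[1, "num Df"]),
       df2 = unname(sm[1, "den Df"]),
       p = unname(sm[1, "Pr(>F)"]))
}

#' Format a comparison table as a lag-by-joint grid
#'
#' Renders a [ttest_by_joint_lag()] result in the conventional report
#' shape: one row per lag, one column per joint, each cell the string
#' `"t (p)"` with both numbers rounded to 2 decimals (raw values stay in
#' the input table). Also returns the list of significant cells.
#'
#' @param table A `gm_comparison` from [ttest_by_joint_lag()].
#' @return List with `grid` (data frame, rows = lags), `significant`
#'   (data frame of significant cells with raw `t` and `p`).
#' @export
summarize_comparison <- function(table) {
  stopifnot(inherits(table, "gm_comparison"), nrow(table) > 0)
  joints <- unique(table$joint)
  joints <- joints[order(match(joints, canonical_anchors()$joint))]
  lags <- sort(unique(table$lag_s))
  grid <- data.frame(lag_s = lags)
  for (j in joints) {
    cells <- vapply(lags, function(l) {
      row <- table[table$joint == j & table$lag_s == l, ]
      sprintf("%.2f (%.2f)", row$t[1], row$p[1])
    }, "")
    grid[[j]] <- cells
  }
  sig <- table[table$significant, c("joint", "lag_s", "t", "p")]
  rownames(sig) <- NULL
  list(grid = grid, significant = sig)
}

#' @export
print.gm_comparison <- function(x, ...) {
  gr <- attr(x, "groups")
  cat(sprintf("<gm_comparison> %s vs %s, alpha = %g\n",
              gr[1], gr[2], attr(x, "alpha")))
  print(summarize_comparison(x)$grid, row.names = FALSE)
  invisible(x)
}
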