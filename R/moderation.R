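#' Windowed component score from a subject's beta map
#'
#' The subject's scalar score for a named ERP component: the arithmetic mean
#' of first-level b-values for one regressor over a ms window (inclusive at
#' both ends) at a single electrode, e.g. the feedback-valence b averaged
#' over Pz 500-520 ms for the feedback P3b.
#'
#' @param map a `beta_map`.
#' @param electrode channel name.
#' @param window length-2 ms interval, inside the map's time axis.
#' @param regressor regressor name (default `"valence"`).
#' @return Scalar mean b (uV per coding unit).
#' @export
window_score <- function(map, electrode, window, regressor = "valence") {
  ch <- match(electrode, map$channels)
  if (is.na(ch)) stop("electrode ", electrode, " not in map")
  if (!regressor %in% map$regressors)
    stop("regressor ", regressor, " not in map")
  idx <- which(map$times >= window[1] - 1e-6 & map$times <= window[2] + 1e-6)
  if (length(idx) == 0) stop("window contains no samples")
  mean(map$b[ch, idx, regressor])
}

#' Group-level moderated regression over the electrode x time grid
#'
#' At every cell, regresses the subjects' first-level b-values (typically an
#' inhibition-task trial-type effect) on a centered predictor (a windowed
#' feedback-component score) and its product with the centered moderator
#' (a trait score):
#' `y = b0 + b1 * x_c + b2 * (x_c * m_c) + error`.
#' Following the reported model, the moderator enters only through the
#' product term; `include_moderator_main = TRUE` adds the conventional
#' moderator main-effect column. Both variables are demeaned before the
#' product is formed. Residual df is `n - p` with `p` fitted columns.
#'
#' @param y_maps list of `beta_map`s (one per subject, common grid).
#' @param x numeric per-subject predictor scores, same order as `y_maps`.
#' @param m numeric per-subject moderator values (raw units).
#' @param regressor which regressor of `y_maps` forms the dependent maps
#'   (default `"trial_type"`).
#' @param moderator_name label carried into outputs.
#' @param include_moderator_main add a centered moderator main effect
#'   (default `FALSE`, matching the reported model).
#' @return A `moderation_fit` with per-cell coefficient, SE, t and p arrays
#'   for the main (`b1`) and interaction (`b2`) terms, the per-cell
#'   covariance entries for (b1, b2) needed by [jn_points()], residual `df`,
#'   and centering metadata.
#' @export
fit_moderated_map <- function(y_maps, x, m, regressor = "trial_type",
                              moderator_name = "moderator",
                              include_moderator_main = FALSE) {
  n <- length(y_maps)
  if (n < 10) stop("need at least 10 subjects")
  if (length(x) != n || length(m) != n)
    stop("x and m must have one value per subject map")
  if (stats::sd(x) < .Machine$double.eps^0.5)
    stop("predictor x has (near) zero variance: degenerate design")
  if (stats::sd(m) < .Machine$double.eps^0.5)
    stop("moderator has (near) zero variance: degenerate design")
  ref <- y_maps[[1]]
  x_c <- x - mean(x)
  m_c <- m - mean(m)
  X <- cbind(intercept = 1, main = x_c, interaction = x_c * m_c)
  if (include_moderator_main) X <- cbind(X, moderator = m_c)
  k <- ncol(X)
  df <- n - k
  cells <- length(ref$channels) * length(ref$times)
  Y <- vapply(y_maps, function(mp) as.numeric(mp$b[, , regressor]),
              numeric(cells))                     # cells x subjects
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = cells)  # single-cell grid
  XtXi <- solve(crossprod(X))
  coef <- Y %*% X %*% XtXi                        # cells x k
  resid <- Y - coef %*% t(X)
  sigma2 <- rowSums(resid^2) / df
  dims <- c(length(ref$channels), length(ref$times))
  se <- sqrt(outer(sigma2, diag(XtXi)))
  tv <- coef / se
  pv <- 2 * stats::pt(-abs(tv), df)
  as_grid <- function(v) array(v, dims)
  structure(list(
    b0 = as_grid(coef[, 1]), b1 = as_grid(coef[, 2]), b2 = as_grid(coef[, 3]),
    se1 = as_grid(se[, 2]), se2 = as_grid(se[, 3]),
    t1 = as_grid(tv[, 2]), t2 = as_grid(tv[, 3]),
    p1 = as_grid(pv[, 2]), p2 = as_grid(pv[, 3]),
    V11 = as_grid(sigma2 * XtXi[2, 2]),
    V12 = as_grid(sigma2 * XtXi[2, 3]),
    V22 = as_grid(sigma2 * XtXi[3, 3]),
    df = df, n = n, regressor = regressor,
    moderator = moderator_name, m_mean = mean(m), m_range = range(m),
    x_mean = mean(x), channels = ref$channels, times = ref$times),
    class = "moderation_fit")
}

#' @export
print.moderation_fit <- function(x, ...) {
  cat("<moderation_fit>", x$regressor, "~ x * ", x$moderator, ":",
      length(x$channels), "channels x", length(x$times),
      "times, df =", x$df, "\n")
  invisible(x)
}

#' Mask moderation maps at an uncorrected p threshold
#'
#' Suppresses (sets to `NA`) every cell whose term p-value exceeds `p_mask`.
#' As in the reported figures, masking is uncorrected -- no second-level FDR
#' is applied.
#'
#' @param fit a `moderation_fit`.
#' @param p_mask threshold in `(0, 1)`; the reported maps use 0.010.
#' @return list with `main` and `interaction`, each holding masked `beta`
#'   and `t` grids plus the logical `mask` of surviving cells.
#' @export
mask_map <- function(fit, p_mask = 0.010) {
  if (p_mask <= 0 || p_mask > 1) stop("p_mask must lie in (0, 1]")
  one <- function(beta, tv, p) {
    keep <- p <= p_mask
    beta[!keep] <- NA_real_
    tv[!keep] <- NA_real_
    list(beta = beta, t = tv, mask = keep)
  }
  list(main = one(fit$b1, fit$t1, fit$p1),
       interaction = one(fit$b2, fit$t2, fit$p2),
       p_mask = p_mask)
}

#' Johnson-Neyman regions of significance at one cell
#'
#' For the moderated model at one (electrode, time) cell, the simple slope
#' of the predictor at moderator value `m` (centered `m_c`) is
#' `s(m) = b1 + b2 * m_c` with squared standard error
#' `V11 + 2 m_c V12 + m_c^2 V22`. The JN boundaries are the real roots of
#' `s(m)^2 = t_crit^2 * SE^2(m)` with `t_crit` the two-sided critical t at
#' `threshold` and the fit's residual df -- a quadratic in `m_c`. Boundaries
#' are reported in raw moderator units and clipped to the observed moderator
#' range; each resulting interval is labelled significant or not by
#' evaluating the simple-slope p-value at its midpoint.
#'
#' @param fit a `moderation_fit`.
#' @param electrode,time_ms cell to analyse (time snapped to nearest sample).
#' @param threshold two-sided p threshold (default 0.01).
#' @param m_range moderator range to report over; default the observed range.
#' @return A `jn_result`: boundaries (raw units, 0-2 of them), an `intervals`
#'   data.frame (lower, upper, simple slope at midpoint, t, p, significant),
#'   and cell metadata.
#' @export
jn_points <- function(fit, electrode, time_ms, threshold = 0.01,
                      m_range = NULL) {
  ch <- match(electrode, fit$channels)
  if (is.na(ch)) stop("electrode ", electrode, " not in fit")
  ti <- which.min(abs(fit$times - time_ms))
  if (is.null(m_range)) m_range <- fit$m_range
  if (diff(m_range) <= 0) stop("degenerate moderator range")
  b1 <- fit$b1[ch, ti]; b2 <- fit$b2[ch, ti]
  V11 <- fit$V11[ch, ti]; V12 <- fit$V12[ch, ti]; V22 <- fit$V22[ch, ti]
  tc2 <- stats::qt(1 - threshold / 2, fit$df)^2
  # quadratic a m_c^2 + b m_c + c = 0 for |t(m)| = t_crit
  qa <- b2^2 - tc2 * V22
  qb <- 2 * b1 * b2 - 2 * tc2 * V12
  qc <- b1^2 - tc2 * V11
  disc <- qb^2 - 4 * qa * qc
  roots <- numeric(0)
  if (abs(qa) < .Machine$double.eps) {
    if (abs(qb) > .Machine$double.eps) roots <- -qc / qb
  } else if (disc >= 0) {
    roots <- sort((-qb + c(-1, 1) * sqrt(disc)) / (2 * qa))
  }
  lo_c <- m_range[1] - fit$m_mean
  hi_c <- m_range[2] - fit$m_mean
  roots <- roots[roots > lo_c & roots < hi_c]
  edges <- c(lo_c, roots, hi_c)
  slope_t <- function(mc) (b1 + b2 * mc) / sqrt(V11 + 2 * mc * V12 + mc^2 * V22)
  mids <- (utils::head(edges, -1) + utils::tail(edges, -1)) / 2
  tmid <- vapply(mids, slope_t, numeric(1))
  pmid <- 2 * stats::pt(-abs(tmid), fit$df)
  intervals <- data.frame(
    lower = utils::head(edges, -1) + fit$m_mean,
    upper = utils::tail(edges, -1) + fit$m_mean,
    slope = b1 + b2 * mids, t = tmid, p = pmid,
    significant = pmid < threshold)
  structure(list(
    electrode = fit$channels[ch], time_ms = fit$times[ti],
    boundaries = roots + fit$m_mean, intervals = intervals,
    threshold = threshold, df = fit$df, m_range = m_range,
    moderator = fit$moderator),
    class = "jn_result")
}

#' @export
print.jn_result <- function(x, ...) {
  cat("<jn_result>", x$moderator, "@", x$electrode, x$time_ms, "ms,",
      "threshold p =", x$threshold, "\n")
  if (length(x$boundaries) == 0) {
    cat("  no boundary in observed range; slope",
        if (x$intervals$significant[1]) "significant" else "not significant",
        "throughout\n")
  } else {
    cat("  JN point(s):", paste(round(x$boundaries, 2), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Residualize one trait score on another
#'
#' Raw residuals from the simple OLS regression (with intercept) of `a` on
#' `b`, isolating the variance of `a` not shared with `b`. Residuals have
#' mean exactly zero and are orthogonal to `b`. Downstream these replace the
#' raw moderator only inside the interaction term; the main-effect predictor
#' is unchanged.
#'
#' @param a numeric trait scores to residualize.
#' @param b numeric trait scores to partial out (non-constant).
#' @return Numeric residual scores.
#' @export
residualize <- function(a, b) {
  if (length(a) != length(b)) stop("`a` and `b` must have equal length")
  if (stats::sd(b) < .Machine$double.eps^0.5)
    stop("`b` is (near) constant: cannot residualize")
  unname(stats::resid(stats::lm(a ~ b)))
}
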