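#' Benjamini-Hochberg step-up false discovery rate control
#'
#' Standard step-up rule: with `m` p-values sorted ascending, find the
#' largest `k` with `p_(k) <= k / m * alpha` and reject all hypotheses with
#' `p <= p_(k)`. The largest rejected p-value is returned as `critical_p`
#' (0, by convention, when nothing is rejected) -- this is the data-dependent
#' per-test threshold used downstream for confidence-interval levels.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level in `(0, 1)`.
#' @return list with `reject` (logical, original order) and `critical_p`.
#' @export
fdr_bh <- function(pvals, alpha) {
  if (length(pvals) == 0) stop("empty p-value set")
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  m <- length(pvals)
  o <- order(pvals)
  ps <- pvals[o]
  ok <- which(ps <= seq_len(m) / m * alpha)
  if (length(ok) == 0)
    return(list(reject = rep(FALSE, m), critical_p = 0))
  crit <- ps[max(ok)]
  list(reject = pvals <= crit, critical_p = crit)
}

#' Group-level one-sample t-map over subjects' b-values
#'
#' For every (channel, time) cell, tests the subjects' first-level b-values
#' against zero with a two-tailed one-sample t-test (`df = n - 1`), then
#' controls the false discovery rate over all cells of the grid with the
#' Benjamini-Hochberg procedure at `alpha`.
#'
#' @param maps list of `beta_map`s on a common grid (same channels, times).
#' @param regressor name of the regressor to test (e.g. `"trial_type"`).
#' @param alpha two-tailed FDR level; default 0.025.
#' @return A `group_stat_map` with per-cell `beta` (mean b), `se`, `t`, `p`,
#'   `significant`, plus `df`, `critical_p` and grid metadata.
#' @export
group_onesample_map <- function(maps, regressor, alpha = 0.025) {
  if (length(maps) < 3) stop("need at least 3 subjects")
  ref <- maps[[1]]
  for (m in maps[-1]) {
    if (!identical(m$channels, ref$channels) ||
        length(m$times) != length(ref$times) ||
        max(abs(m$times - ref$times)) > 1e-9)
      stop("subjects' beta maps are not on a common grid")
  }
  n <- length(maps)
  cells <- length(ref$channels) * length(ref$times)
  B <- vapply(maps, function(m) as.numeric(m$b[, , regressor]),
              numeric(cells))                     # cells x subjects
  if (is.null(dim(B))) B <- matrix(B, nrow = cells)  # single-cell grid
  mu <- rowMeans(B)
  se <- sqrt(apply(B, 1, stats::var) / n)
  tval <- mu / se
  df <- n - 1
  p <- 2 * stats::pt(-abs(tval), df)
  p[se == 0 & mu != 0] <- 0          # degenerate certainty: zero variance
  p[se == 0 & mu == 0] <- 1
  fdr <- fdr_bh(p, alpha)
  dims <- c(length(ref$channels), length(ref$times))
  structure(list(
    term = regressor,
    beta = array(mu, dims), se = array(se, dims), t = array(tval, dims),
    p = array(p, dims), significant = array(fdr$reject, dims),
    df = df, n = n, alpha = alpha, critical_p = fdr$critical_p,
    channels = ref$channels, times = ref$times),
    class = "group_stat_map")
}

#' @export
print.group_stat_map <- function(x, ...) {
  cat("<group_stat_map>", x$term, ":", length(x$channels), "channels x",
      length(x$times), "times, df =", x$df, "\n")
  cat("  ", sum(x$significant), "/", length(x$significant),
      "cells significant (alpha =", x$alpha, ", critical p =",
      format(x$critical_p, digits = 3), ")\n")
  invisible(x)
}

#' One-sample Hedges' g from a t statistic
#'
#' `g = J * t / sqrt(n)` with the small-sample bias correction
#' `J = 1 - 3 / (4 (n - 1) - 1)`.
#'
#' @param t one-sample t statistic.
#' @param n number of subjects (>= 2).
#' @return Hedges' g.
#' @export
hedges_g <- function(t, n) {
  if (n < 2) stop("`n` must be at least 2")
  (1 - 3 / (4 * (n - 1) - 1)) * t / sqrt(n)
}

#' Locate the peak effect in a region of interest
#'
#' Searches the FDR-significant cells of a group map inside a channel subset
#' and time window for the cell with maximal |t| whose sign matches
#' `polarity`; ties are broken by earlier time, then by channel order. The
#' report carries the group beta, t, p, the map's critical p, a confidence
#' interval for the mean b at level `100 * (1 - critical_p)` percent, and
#' Hedges' g. When no significant cell of the requested sign exists in the
#' region an explicit no-peak result is returned rather than an error.
#'
#' @param map a `group_stat_map`.
#' @param channels character vector of ROI channels.
#' @param window length-2 ms interval searched (inclusive).
#' @param polarity "positive", "negative" or "any".
#' @return A `peak_report` (list); `$found` says whether a peak exists.
#' @export
find_peak <- function(map, channels, window,
                      polarity = c("positive", "negative", "any")) {
  polarity <- match.arg(polarity)
  ch_idx <- match(channels, map$channels)
  if (anyNA(ch_idx))
    stop("channel(s) not in map: ",
         paste(channels[is.na(ch_idx)], collapse = ", "))
  t_idx <- which(map$times >= window[1] & map$times <= window[2])
  if (length(t_idx) == 0) stop("empty search window")
  cand <- expand.grid(ch = ch_idx, ti = t_idx)
  keep <- map$significant[cbind(cand$ch, cand$ti)]
  tv <- map$t[cbind(cand$ch, cand$ti)]
  if (polarity == "positive") keep <- keep & tv > 0
  if (polarity == "negative") keep <- keep & tv < 0
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0)
    return(structure(list(found = FALSE, term = map$term,
                          channels = channels, window = window,
                          polarity = polarity),
                     class = "peak_report"))
  tv <- abs(map$t[cbind(cand$ch, cand$ti)])
  # max |t|; ties -> earlier time, then channel order as given in the map
  ord <- order(-tv, map$times[cand$ti], cand$ch)
  best <- cand[ord[1], ]
  beta <- map$beta[best$ch, best$ti]
  tstat <- map$t[best$ch, best$ti]
  se <- map$se[best$ch, best$ti]
  level <- 1 - map$critical_p
  tcrit <- stats::qt(1 - map$critical_p / 2, map$df)
  structure(list(
    found = TRUE, term = map$term,
    electrode = map$channels[best$ch], time_ms = map$times[best$ti],
    beta = beta, t = tstat, df = map$df, p = map$p[best$ch, best$ti],
    critical_p = map$critical_p, conf_level = level,
    ci = c(beta - tcrit * se, beta + tcrit * se),
    g = hedges_g(tstat, map$n)),
    class = "peak_report")
}

#' @export
print.peak_report <- function(x, ...) {
  if (!isTRUE(x$found)) {
    cat("<peak_report>", x$term, ": no significant peak in region\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<peak_report> %s: %s @ %g ms  b = %.2f  t(%d) = %.2f  p = %.3g\n",
    x$term, x$electrode, x$time_ms, x$beta, x$df, x$t, x$p))
  cat(sprintf("  critical p = %.3g, %.1f%% CI [%.2f, %.2f], g = %.2f\n",
              x$critical_p, 100 * x$conf_level, x$ci[1], x$ci[2], x$g))
  invisible(x)
}

#' Score a questionnaire from item responses
#'
#' Computes the validated sum score: negative urgency (`"nu"`) from 12 items
#' each in 1-4 (range 12-48); OCI-R compulsivity (`"ocir"`) from 18 items
#' each in 0-4 (range 0-72).
#'
#' @param responses integer item responses in scale order.
#' @param scale "nu" or "ocir".
#' @return Integer sum score.
#' @export
score_questionnaire <- function(responses, scale = c("nu", "ocir")) {
  scale <- match.arg(scale)
  spec <- switch(scale, nu = list(k = 12L, lo = 1L, hi = 4L),
                 ocir = list(k = 18L, lo = 0L, hi = 4L))
  if (length(responses) != spec$k)
    stop(scale, " requires ", spec$k, " items, got ", length(responses))
  bad <- which(responses < spec$lo | responses > spec$hi |
                 responses != round(responses))
  if (length(bad))
    stop("item(s) out of range [", spec$lo, ", ", spec$hi, "]: index ",
         paste(bad, collapse = ", "))
  as.integer(sum(responses))
}
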