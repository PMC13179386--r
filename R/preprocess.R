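#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean voltage over the pre-stimulus
#' baseline window. The default window is the 200 ms preceding the locking
#' event, `[-200, 0)`.
#'
#' @param epochs an [epoch_set].
#' @param window length-2 numeric, ms interval; samples with
#'   `window[1] <= t < window[2]` form the baseline.
#' @return The corrected [epoch_set].
#' @export
baseline_correct <- function(epochs, window = c(-200, 0)) {
  stopifnot(inherits(epochs, "epoch_set"), length(window) == 2)
  idx <- which(epochs$times >= window[1] & epochs$times < window[2])
  if (length(idx) == 0)
    stop("baseline window [", window[1], ", ", window[2],
         ") contains no samples")
  bl <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(bl)  # recycles over time (3rd dim)
  log_op(epochs, sprintf("baseline[%g,%g)", window[1], window[2]))
}

#' Temporally smooth epochs
#'
#' Replaces every sample by the average of itself with the two preceding and
#' two succeeding samples (5-point centered moving average). At the first and
#' last two samples the window truncates to the samples available, so the
#' operator remains an average (constants are preserved everywhere).
#'
#' @param epochs an [epoch_set] with at least 5 time samples.
#' @return The smoothed [epoch_set].
#' @export
smooth_temporal <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  nt <- length(epochs$times)
  if (nt < 5) stop("temporal smoothing needs at least 5 samples, got ", nt)
  lo <- pmax(seq_len(nt) - 2L, 1L)
  hi <- pmin(seq_len(nt) + 2L, nt)
  d <- dim(epochs$data)
  flat <- matrix(epochs$data, nrow = d[1] * d[2], ncol = d[3])
  cs <- cbind(0, t(apply(flat, 1, cumsum)))
  sm <- (cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]) /
    rep(hi - lo + 1L, each = nrow(flat))
  epochs$data <- array(sm, dim = d)
  log_op(epochs, "smooth5")
}

#' Reject improbable epochs
#'
#' Flags epochs whose voltages are jointly improbable relative to the rest of
#' the recording. For every (channel, time) cell a Gaussian is fitted across
#' trials; each epoch's improbability score is the mean, over all cells, of
#' the negative log density of its value under that cell's Gaussian. Epochs
#' scoring more than `z_thresh` standard deviations above the mean score are
#' removed in a single pass (no re-iteration after removal).
#'
#' @param epochs an [epoch_set] with at least 8 trials.
#' @param z_thresh rejection threshold in SD units of the score distribution
#'   (default 5).
#' @return A list with `epochs` (the retained trials, trial table filtered
#'   consistently) and `rejected` (integer indices of removed trials).
#' @export
reject_improbable <- function(epochs, z_thresh = 5) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (z_thresh <= 0) stop("`z_thresh` must be positive")
  d <- dim(epochs$data)
  if (d[1] < 8) stop("improbable-epoch rejection needs >= 8 trials")
  flat <- matrix(epochs$data, nrow = d[1])     # trials x (channel*time)
  mu <- colMeans(flat)
  sd_ <- apply(flat, 2, stats::sd)
  if (all(sd_ < .Machine$double.eps^0.5)) {
    warning("all epochs identical: no rejections possible")
    return(list(epochs = epochs, rejected = integer()))
  }
  sd_[sd_ < .Machine$double.eps^0.5] <- Inf   # constant cells carry no surprise
  z2 <- sweep(sweep(flat, 2, mu), 2, sd_, "/")^2
  const <- 0.5 * log(2 * pi) + log(ifelse(is.finite(sd_), sd_, 1))
  score <- rowMeans(sweep(z2 / 2, 2, const, "+"))
  cut <- mean(score) + z_thresh * stats::sd(score)
  rejected <- which(score > cut)
  if (length(rejected)) {
    epochs$data <- epochs$data[-rejected, , , drop = FALSE]
    epochs$trial_table <- epochs$trial_table[-rejected, , drop = FALSE]
    rownames(epochs$trial_table) <- NULL
  }
  epochs <- log_op(epochs, sprintf("reject_improbable(z=%g, n=%d)",
                                   z_thresh, length(rejected)))
  list(epochs = epochs, rejected = rejected)
}

#' Restrict epochs to the analysis window
#'
#' Keeps samples inside the given ms interval, endpoints inclusive. With the
#' default `[-100, 700]` window a 500 Hz recording retains 401 samples.
#'
#' @param epochs an [epoch_set].
#' @param interval length-2 numeric ms interval, both endpoints inside the
#'   epoch's time axis.
#' @return The windowed [epoch_set].
#' @export
select_analysis_window <- function(epochs, interval = c(-100, 700)) {
  stopifnot(inherits(epochs, "epoch_set"), length(interval) == 2)
  eps <- 1e-6
  if (interval[1] < min(epochs$times) - eps ||
      interval[2] > max(epochs$times) + eps)
    stop("interval [", interval[1], ", ", interval[2],
         "] extends beyond epoch time axis [", min(epochs$times), ", ",
         max(epochs$times), "]")
  idx <- which(epochs$times >= interval[1] - eps &
                 epochs$times <= interval[2] + eps)
  epochs$data <- epochs$data[, , idx, drop = FALSE]
  epochs$times <- epochs$times[idx]
  log_op(epochs, sprintf("window[%g,%g]", interval[1], interval[2]))
}
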