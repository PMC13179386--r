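# IRLS core without argument validation; called per (channel, time) cell.
# Tukey bisquare weights (tuning 4.685), scale re-estimated each iteration
# as median(|r|)/0.6745, convergence on max coefficient change < tol.
irls_engine <- function(X, y, tuning = 4.685, tol = 1e-6, max_iter = 50L) {
  fit <- stats::.lm.fit(X, y)
  b <- fit$coefficients
  w <- rep(1, length(y))
  converged <- FALSE
  iter <- 0L
  repeat {
    r <- y - drop(X %*% b)
    s <- stats::median(abs(r)) / 0.6745
    if (s < .Machine$double.eps^0.5) { converged <- TRUE; break }
    u <- r / (tuning * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w > 0) < ncol(X)) break  # too few points carry weight
    iter <- iter + 1L
    sw <- sqrt(w)
    b_new <- stats::.lm.fit(X * sw, y * sw)$coefficients
    if (max(abs(b_new - b)) < tol) { b <- b_new; converged <- TRUE; break }
    b <- b_new
    if (iter >= max_iter) break
  }
  list(b = b, weights = w, iterations = iter, converged = converged)
}

#' Robust regression by iteratively reweighted least squares
#'
#' Fits `y = X b` with Tukey bisquare weights (tuning constant 4.685) and a
#' per-iteration robust scale estimate `median(|residual|) / 0.6745`,
#' starting from the ordinary least-squares solution. Iteration stops when
#' the largest coefficient change falls below `1e-6` or after 50 iterations.
#' On outlier-free Gaussian data the estimate coincides with OLS to within
#' the convergence tolerance; with gross outliers the bisquare weights
#' drive their influence to zero.
#'
#' @param y numeric response (single-trial voltages at one electrode and
#'   time point).
#' @param X a `design_matrix` or plain numeric model matrix; must have at
#'   least `ncol + 5` rows and full column rank.
#' @return list with `b` (named coefficients), `weights` (final robustness
#'   weights), `iterations` and `converged`.
#' @export
irls_fit <- function(y, X) {
  if (inherits(X, "design_matrix")) X <- X$X
  X <- as.matrix(X)
  if (nrow(X) != length(y))
    stop("length(y) = ", length(y), " does not match nrow(X) = ", nrow(X))
  if (nrow(X) < ncol(X) + 5)
    stop("need at least ncol(X) + 5 = ", ncol(X) + 5, " observations")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design is rank-deficient; dependent column(s): ",
         paste(dep, collapse = ", "))
  }
  out <- irls_engine(X, y)
  names(out$b) <- colnames(X)
  out
}

#' Fit first-level b-value maps for one subject
#'
#' Runs [irls_fit()] independently at every (channel, time) cell of the
#' epoch grid, regressing single-trial voltages on the task design. The
#' epoch set should already be baseline-corrected, artifact-screened,
#' temporally smoothed and restricted to the analysis window; design rows
#' are aligned to epochs through the design's `$kept` indices, so designs
#' that drop trials (failed stops, zero-point feedback) subset the epochs
#' consistently.
#'
#' @param epochs an [epoch_set].
#' @param design a `design_matrix` built from this epoch set's trial table.
#' @return A `beta_map`: `b` array `[channel, time, regressor]` plus
#'   per-cell `iterations` and `converged` diagnostics.
#' @export
fit_subject_maps <- function(epochs, design) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(design, "design_matrix"))
  if (max(design$kept) > n_trials(epochs))
    stop("design refers to trial ", max(design$kept), " but epochs hold ",
         n_trials(epochs))
  X <- design$X
  d <- dim(epochs$data)
  n_ch <- d[2]; n_t <- d[3]; n_reg <- ncol(X)
  b <- array(NA_real_, c(n_ch, n_t, n_reg),
             dimnames = list(epochs$channels, NULL, colnames(X)))
  iters <- conv <- array(NA_integer_, c(n_ch, n_t))
  dat <- epochs$data[design$kept, , , drop = FALSE]
  for (ch in seq_len(n_ch)) {
    ymat <- matrix(dat[, ch, ], ncol = n_t)
    for (t in seq_len(n_t)) {
      fit <- tryCatch(irls_engine(X, ymat[, t]), error = function(e) NULL)
      if (is.null(fit)) next  # flagged cell: NA betas, NA diagnostics
      b[ch, t, ] <- fit$b
      iters[ch, t] <- fit$iterations
      conv[ch, t] <- as.integer(fit$converged)
    }
  }
  structure(list(b = b, channels = epochs$channels, times = epochs$times,
                 regressors = colnames(X), subject = epochs$subject,
                 task = epochs$task, iterations = iters,
                 converged = conv, n_trials = nrow(X)),
            class = "beta_map")
}

#' @export
print.beta_map <- function(x, ...) {
  cat("<beta_map>", x$subject, x$task, ":", length(x$channels), "channels x",
      length(x$times), "times x", length(x$regressors), "regressors (",
      paste(x$regressors, collapse = ", "), ")\n")
  invisible(x)
}
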