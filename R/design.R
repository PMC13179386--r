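new_design <- function(X, kept, coding, dropped = 0L) {
  keep_const_check(X)
  structure(list(X = X, kept = kept, coding = coding, dropped = dropped),
            class = "design_matrix")
}

keep_const_check <- function(X) {
  for (j in seq_len(ncol(X))[-1]) {
    if (length(unique(X[, j])) == 1L)
      stop("design column `", colnames(X)[j],
           "` is constant: degenerate design")
  }
  invisible(X)
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("<design_matrix>", nrow(x$X), "trials x", ncol(x$X), "columns (",
      paste(colnames(x$X), collapse = ", "), ")\n")
  if (x$dropped > 0) cat("  dropped", x$dropped, "trials\n")
  invisible(x)
}

#' Build the go/nogo single-trial design
#'
#' Regressors: intercept; trial type coded go = -1, nogo = +1 (the predictor
#' of interest); the preceding inter-trial interval, centered, in seconds
#' (regressor of no interest).
#'
#' @param trial_table data.frame with `trial_type` ("go"/"nogo") and `iti`.
#' @return A `design_matrix`; `$kept` holds the retained row indices.
#' @export
build_design_gonogo <- function(trial_table) {
  bad <- setdiff(unique(trial_table$trial_type), c("go", "nogo"))
  if (length(bad))
    stop("unknown trial_type level(s): ", paste(bad, collapse = ", "))
  X <- cbind(intercept = 1,
             trial_type = ifelse(trial_table$trial_type == "nogo", 1, -1),
             iti = trial_table$iti - mean(trial_table$iti))
  new_design(X, seq_len(nrow(trial_table)),
             coding = list(signed = "trial_type", centered = "iti"))
}

#' Build the stop-signal single-trial design
#'
#' The contrast of interest is go vs. successfully stopped trials: failed
#' stop trials are dropped (count recorded in `$dropped`). Regressors:
#' intercept; trial type coded go = -1, successful stop = +1; arrow
#' direction coded left = -1, right = +1; centered inter-trial interval in
#' seconds.
#'
#' @param trial_table data.frame with `trial_type` ("go"/"stop"),
#'   `stop_success`, `arrow_direction` and `iti`.
#' @return A `design_matrix`.
#' @export
build_design_sst <- function(trial_table) {
  bad <- setdiff(unique(trial_table$trial_type), c("go", "stop"))
  if (length(bad))
    stop("unknown trial_type level(s): ", paste(bad, collapse = ", "))
  keep <- which(trial_table$trial_type == "go" |
                  (!is.na(trial_table$stop_success) & trial_table$stop_success))
  dropped <- nrow(trial_table) - length(keep)
  tt <- trial_table[keep, , drop = FALSE]
  X <- cbind(intercept = 1,
             trial_type = ifelse(tt$trial_type == "stop", 1, -1),
             arrow_direction = ifelse(tt$arrow_direction == "right", 1, -1),
             iti = tt$iti - mean(tt$iti))
  new_design(X, keep, dropped = dropped,
             coding = list(signed = c("trial_type", "arrow_direction"),
                           centered = "iti"))
}

#' Build the feedback-valence single-trial design
#'
#' For the incentive flanker task, valence is coded at the context level:
#' all feedback trials are retained, potential-gain context = -1,
#' loss-avoidance context = +1. For the two-step task, feedback worth zero
#' points is excluded and negative-point feedback (loss) is coded +1,
#' positive-point feedback (gain) -1. An `outcome_level` switch for the
#' flanker codes by realized outcome (gain/loss-omission = -1,
#' loss/gain-omission = +1) instead; default off.
#'
#' @param trial_table data.frame; flanker needs `context` (and `outcome` for
#'   outcome-level coding), two-step needs `outcome_points`.
#' @param task "miflat" or "twostep".
#' @param outcome_level flanker only: code by realized outcome rather than
#'   context (default `FALSE`).
#' @return A `design_matrix` with columns intercept and `valence`.
#' @export
build_design_feedback <- function(trial_table, task = c("miflat", "twostep"),
                                  outcome_level = FALSE) {
  task <- match.arg(task)
  if (task == "miflat") {
    val <- if (outcome_level)
      ifelse(trial_table$outcome %in% c("loss", "gain_omission"), 1, -1)
    else ifelse(trial_table$context == "loss_avoidance", 1, -1)
    keep <- seq_len(nrow(trial_table))
    dropped <- 0L
  } else {
    keep <- which(trial_table$outcome_points != 0)
    if (length(keep) == 0)
      stop("all two-step outcomes are zero points: empty design")
    dropped <- nrow(trial_table) - length(keep)
    val <- ifelse(trial_table$outcome_points[keep] < 0, 1, -1)
  }
  X <- cbind(intercept = 1, valence = val)
  new_design(X, keep, dropped = dropped, coding = list(signed = "valence"))
}

#' Build the task's default design from an epoch set
#'
#' Dispatch helper mapping a task label to its design builder, applied to
#' the epoch set's trial table.
#'
#' @param epochs an [epoch_set] with a task label.
#' @return A `design_matrix`.
#' @export
build_design <- function(epochs) {
  switch(epochs$task,
    gonogo = build_design_gonogo(epochs$trial_table),
    sst = build_design_sst(epochs$trial_table),
    miflat = build_design_feedback(epochs$trial_table, "miflat"),
    twostep = build_design_feedback(epochs$trial_table, "twostep"),
    stop("no design builder for task: ", epochs$task))
}
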