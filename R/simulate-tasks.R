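#' Simulate questionnaire trait scores
#'
#' Draws correlated compulsivity (OCI-R sum, theoretical range 0-72) and
#' negative urgency (UPPS subscale sum, range 12-48) scores from a bivariate
#' normal, rounded to integers and clipped to the theoretical ranges. The
#' defaults reproduce a community sample enriched for a wide compulsivity
#' range: OCI-R 12.6 +/- 9.5, negative urgency 26.3 +/- 5.9, inter-trait
#' correlation 0.18.
#'
#' @param n number of subjects (>= 3).
#' @param means,sds length-2 numeric: (OCI-R, urgency) population mean and SD.
#' @param rho latent inter-trait correlation, |rho| < 1.
#' @param seed optional integer seed.
#' @return data.frame with columns `subject_id`, `oci_r`, `negative_urgency`.
#' @export
simulate_traits <- function(n, means = c(12.6, 26.3), sds = c(9.5, 5.9),
                            rho = 0.18, seed = NULL) {
  if (n < 3) stop("`n` must be at least 3")
  if (any(sds <= 0)) stop("`sds` must be positive")
  if (abs(rho) >= 1) stop("`rho` must satisfy |rho| < 1")
  if (!is.null(seed)) set.seed(seed)
  Sigma <- diag(sds) %*% matrix(c(1, rho, rho, 1), 2) %*% diag(sds)
  raw <- MASS::mvrnorm(n, mu = means, Sigma = Sigma)
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    oci_r = pmin(pmax(round(raw[, 1]), 0L), 72L),
    negative_urgency = pmin(pmax(round(raw[, 2]), 12L), 48L))
}

new_task_events <- function(task, trials) {
  structure(list(task = task, trials = trials), class = "task_events")
}

#' @export
print.task_events <- function(x, ...) {
  cat("<task_events>", x$task, "-", nrow(x$trials), "trials\n")
  print(utils::head(x$trials, 4))
  invisible(x)
}

iti_jitter <- function(n) stats::runif(n, 0.8, 1.2)  # seconds

#' Simulate go/nogo task events
#'
#' Produces a randomized event stream in which exactly 25% of trials are
#' nogo (withhold) trials and the rest are go trials, with a jittered
#' inter-trial interval (uniform 0.8-1.2 s).
#'
#' @param n_trials total trial count, divisible by 4.
#' @param seed optional integer seed.
#' @return A `task_events` object; `$trials` has columns `trial`,
#'   `trial_type` ("go"/"nogo") and `iti` (s).
#' @export
simulate_gonogo_events <- function(n_trials, seed = NULL) {
  if (n_trials %% 4 != 0) stop("`n_trials` must be divisible by 4")
  if (!is.null(seed)) set.seed(seed)
  type <- sample(rep(c("go", "nogo"), c(3L, 1L) * (n_trials %/% 4L)))
  new_task_events("gonogo", data.frame(
    trial = seq_len(n_trials), trial_type = type, iti = iti_jitter(n_trials)))
}

#' Simulate stop-signal task events with staircase SSD tracking
#'
#' Exactly 25% of trials carry a stop signal. The stop-signal delay (SSD)
#' starts at `ssd0` and is staircase-tracked: +`step` ms after a successful
#' stop, -`step` ms after a failed stop (floored at 0), which holds the
#' long-run stop-success rate near 50% for any respondent whose go and stop
#' finishing-time distributions overlap. Success on a stop trial follows the
#' independent-race model: the stop process wins iff SSD + stop finishing
#' time < go finishing time, both drawn per trial from the respondent's
#' Gaussian finishing-time distributions.
#'
#' @param n_trials total trial count, divisible by 4.
#' @param respondent list with `go_mu`, `go_sd`, `stop_mu`, `stop_sd`
#'   (ms); defaults go ~ N(450, 80), stop ~ N(200, 40).
#' @param staircase list with `ssd0` (initial SSD, ms, > 0) and `step`
#'   (ms, > 0); defaults 200 and 50.
#' @param seed optional integer seed.
#' @return A `task_events` object; `$trials` has columns `trial`,
#'   `trial_type` ("go"/"stop"), `arrow_direction` ("left"/"right"), `iti`
#'   (s), `ssd` (ms, NA on go trials) and `stop_success` (logical, NA on go
#'   trials).
#' @export
simulate_sst_events <- function(n_trials,
                                respondent = list(go_mu = 450, go_sd = 80,
                                                  stop_mu = 200, stop_sd = 40),
                                staircase = list(ssd0 = 200, step = 50),
                                seed = NULL) {
  if (n_trials %% 4 != 0) stop("`n_trials` must be divisible by 4")
  if (respondent$go_sd <= 0 || respondent$stop_sd <= 0)
    stop("respondent finishing-time scales must be positive")
  if (staircase$ssd0 <= 0 || staircase$step <= 0)
    stop("staircase `ssd0` and `step` must be positive")
  if (!is.null(seed)) set.seed(seed)
  is_stop <- sample(rep(c(FALSE, TRUE), c(3L, 1L) * (n_trials %/% 4L)))
  arrow <- sample(c("left", "right"), n_trials, replace = TRUE)
  ssd <- rep(NA_real_, n_trials)
  success <- rep(NA, n_trials)
  cur <- staircase$ssd0
  for (i in which(is_stop)) {
    go_t <- stats::rnorm(1, respondent$go_mu, respondent$go_sd)
    stop_t <- stats::rnorm(1, respondent$stop_mu, respondent$stop_sd)
    ssd[i] <- cur
    success[i] <- (cur + stop_t) < go_t
    cur <- max(0, cur + if (success[i]) staircase$step else -staircase$step)
  }
  new_task_events("sst", data.frame(
    trial = seq_len(n_trials),
    trial_type = ifelse(is_stop, "stop", "go"),
    arrow_direction = arrow, iti = iti_jitter(n_trials),
    ssd = ssd, stop_success = success))
}

reflect_into <- function(x, lower, upper) {
  # fold x back into [lower, upper] (handles multi-bounce steps)
  span <- upper - lower
  while (x < lower || x > upper) {
    if (x > upper) x <- 2 * upper - x
    if (x < lower) x <- 2 * lower - x
  }
  x
}

#' Simulate two-step task events
#'
#' First-stage choices transition to their common second-stage state with
#' probability 0.80 and to the rare one with 0.20. Second-stage feedback
#' points follow a Gaussian-step random walk reflected at the bounds
#' (defaults +5 and -4), reported as integer points; zero-point feedback can
#' occur and is excluded later by design construction, not here.
#'
#' @param n_trials trial count.
#' @param walk list with `step_sd` (Gaussian step SD in points, default 1),
#'   `lower`, `upper` (reflective bounds, `lower < 0 < upper`; defaults -4,
#'   +5) and `start` (initial walk value, default 0).
#' @param seed optional integer seed.
#' @return A `task_events` object; `$trials` has columns `trial`,
#'   `transition_type` ("common"/"rare"), `outcome_points` (integer in
#'   `[lower, upper]`) and `iti` (s).
#' @export
simulate_twostep_events <- function(n_trials,
                                    walk = list(step_sd = 1, lower = -4,
                                                upper = 5, start = 0),
                                    seed = NULL) {
  if (is.null(walk$start)) walk$start <- 0
  if (walk$lower >= 0 || walk$upper <= 0)
    stop("walk bounds must satisfy lower < 0 < upper")
  if (walk$step_sd < 0) stop("`step_sd` must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  trans <- sample(c("common", "rare"), n_trials, replace = TRUE,
                  prob = c(0.8, 0.2))
  val <- numeric(n_trials)
  x <- walk$start
  steps <- stats::rnorm(n_trials, 0, walk$step_sd)
  for (i in seq_len(n_trials)) {
    x <- reflect_into(x + steps[i], walk$lower, walk$upper)
    val[i] <- x
  }
  new_task_events("twostep", data.frame(
    trial = seq_len(n_trials), transition_type = trans,
    outcome_points = as.integer(round(val)), iti = iti_jitter(n_trials)))
}

#' Simulate incentivized flanker task events
#'
#' Trials are split evenly between a potential-gain context (fast correct
#' responses rewarded, errors/slow responses leave the reward omitted) and a
#' loss-avoidance context (errors/slow responses punished, fast correct
#' responses avoid the loss). Per-trial performance is sampled from the
#' stated error and too-slow rates; the feedback outcome follows from
#' context and performance.
#'
#' @param n_trials trial count, divisible by 2.
#' @param performance list with `error_rate` and `slow_rate`, both in
#'   `[0, 1]` with sum <= 1 (defaults 0.10 and 0.15).
#' @param seed optional integer seed.
#' @return A `task_events` object; `$trials` has columns `trial`, `context`
#'   ("gain"/"loss_avoidance"), `outcome` ("gain", "gain_omission", "loss",
#'   "loss_omission") and `iti` (s).
#' @export
simulate_miflat_events <- function(n_trials,
                                   performance = list(error_rate = 0.10,
                                                      slow_rate = 0.15),
                                   seed = NULL) {
  if (n_trials %% 2 != 0) stop("`n_trials` must be divisible by 2")
  er <- performance$error_rate; sr <- performance$slow_rate
  if (er < 0 || er > 1 || sr < 0 || sr > 1 || er + sr > 1)
    stop("error and slow rates must lie in [0,1] with sum <= 1")
  if (!is.null(seed)) set.seed(seed)
  ctx <- sample(rep(c("gain", "loss_avoidance"), n_trials %/% 2L))
  fail <- stats::runif(n_trials) < (er + sr)
  outcome <- ifelse(ctx == "gain",
                    ifelse(fail, "gain_omission", "gain"),
                    ifelse(fail, "loss", "loss_omission"))
  new_task_events("miflat", data.frame(
    trial = seq_len(n_trials), context = ctx, outcome = outcome,
    iti = iti_jitter(n_trials)))
}
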