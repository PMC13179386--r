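#' Default 19-channel montage with approximate scalp coordinates
#'
#' A reduced equidistant montage covering the midline and centroparietal
#' sites at which inhibition- and feedback-related P3 effects are expressed
#' (FC1, FCz, Cz, CPz, CP1, CP2, CP4, Pz, P1, P2, P10, PO2, IO1) plus
#' frontal/occipital fillers. Coordinates are a flattened 2-d layout (x:
#' left negative, y: anterior positive) used only to shape the simulated
#' spatial templates; they are not a head model.
#'
#' @return data.frame with columns `channel`, `x`, `y`.
#' @export
default_montage <- function() {
  data.frame(
    channel = c("Fz", "F3", "F4", "FC1", "FCz", "C3", "Cz", "C4",
                "CP1", "CPz", "CP2", "CP4", "P1", "Pz", "P2", "P10",
                "PO2", "Oz", "IO1"),
    x = c(0, -1.5, 1.5, -0.7, 0, -2, 0, 2,
          -0.8, 0, 0.8, 1.8, -0.8, 0, 0.8, 3,
          0.8, 0, -1),
    y = c(3, 3, 3, 2, 2, 1, 1, 1,
          0, 0, 0, 0, -1, -1, -1, -1.5,
          -2, -3, -4))
}

# gaussian falloff from the component's peak channel; 1 at the peak
spatial_template <- function(montage, channel, sigma = 1.5) {
  i <- match(channel, montage$channel)
  if (is.na(i)) stop("channel ", channel, " not in montage")
  d2 <- (montage$x - montage$x[i])^2 + (montage$y - montage$y[i])^2
  exp(-d2 / (2 * sigma^2))
}

# half-cosine bump: 1 at peak_ms, 0 outside +/- halfwidth_ms
temporal_kernel <- function(times, peak_ms, halfwidth_ms) {
  dt <- (times - peak_ms) / halfwidth_ms
  ifelse(abs(dt) <= 1, cos(pi / 2 * dt), 0)
}

#' Condition coding used by both the simulator and the design builders
#'
#' Maps trial covariates to the -1/1 contrast the first-level regression
#' estimates: go/nogo -- go -1, nogo +1; stop-signal -- go -1, successful
#' stop +1 (failed stops 0, excluded from designs); flanker -- potential-gain
#' context -1, loss-avoidance context +1; two-step -- positive points (gain)
#' -1, negative points (loss) +1, zero points 0 (excluded from designs).
#'
#' @param task one of "gonogo", "sst", "miflat", "twostep".
#' @param trial_table per-trial covariates (see the task simulators).
#' @return numeric vector in \{-1, 0, 1\}.
#' @export
condition_code <- function(task, trial_table) {
  switch(task,
    gonogo = ifelse(trial_table$trial_type == "nogo", 1, -1),
    sst = ifelse(trial_table$trial_type == "go", -1,
                 ifelse(!is.na(trial_table$stop_success) &
                          trial_table$stop_success, 1, 0)),
    miflat = ifelse(trial_table$context == "loss_avoidance", 1, -1),
    twostep = sign(-trial_table$outcome_points),
    stop("unknown task: ", task))
}

#' Synthesize single-trial ERP epochs for one subject and task
#'
#' Forward model: each epoch is the sum of (i) a condition-dependent ERP
#' component -- spatial template (Gaussian falloff around a peak channel)
#' times a half-cosine temporal kernel times a per-trial amplitude
#' `base_amp + effect_amp * code`, where `code` is the -1/1 condition coding
#' of [condition_code()]; (ii) a per-trial DC baseline offset; and (iii)
#' temporally AR(1)-correlated noise generated in channel-independent
#' sources and spatially mixed through a random orthonormal matrix. With
#' probability `outlier_rate` an epoch's noise is scaled by `outlier_scale`,
#' planting the gross artifacts the robust first-level estimator and the
#' improbable-epoch rejection are meant to absorb.
#'
#' @param events a `task_events` object from one of the task simulators.
#' @param base_amp condition-independent component amplitude (uV).
#' @param effect_amp condition effect amplitude (uV per coding unit): at the
#'   component's peak channel and latency the first-level b for the
#'   condition regressor recovers this value.
#' @param component list(`channel`, `peak_ms`, `halfwidth_ms`) placing the
#'   component on the grid.
#' @param noise list(`sd` -- stationary noise SD in uV, `ar` -- AR(1)
#'   coefficient in (-1,1), `outlier_rate` in [0,1), `outlier_scale`).
#' @param montage montage data.frame (see [default_montage()]).
#' @param fs sampling rate, Hz.
#' @param window length-2 ms epoch window; must contain the component peak
#'   and a pre-stimulus baseline.
#' @param baseline_sd SD of the per-trial DC offset (uV).
#' @param subject,seed identifiers / reproducibility.
#' @return An [epoch_set] whose `trial_table` is the event table.
#' @export
synthesize_epochs <- function(events, base_amp, effect_amp,
                              component = list(channel = "Cz", peak_ms = 400,
                                               halfwidth_ms = 150),
                              noise = list(sd = 8, ar = 0.9,
                                           outlier_rate = 0.05,
                                           outlier_scale = 8),
                              montage = default_montage(), fs = 500,
                              window = c(-200, 700), baseline_sd = 2,
                              subject = NA_character_, seed = NULL) {
  stopifnot(inherits(events, "task_events"))
  if (abs(noise$ar) >= 1) stop("AR coefficient must lie in (-1, 1)")
  if (noise$outlier_rate < 0 || noise$outlier_rate >= 1)
    stop("outlier rate must lie in [0, 1)")
  if (component$peak_ms <= window[1] || component$peak_ms >= window[2])
    stop("epoch window [", window[1], ", ", window[2],
         "] does not contain the component peak at ", component$peak_ms, " ms")
  if (!is.null(seed)) set.seed(seed)
  tt <- events$trials
  n_tr <- nrow(tt)
  n_ch <- nrow(montage)
  times <- seq(window[1], window[2], by = 1000 / fs)
  n_t <- length(times)
  code <- condition_code(events$task, tt)

  tmpl <- spatial_template(montage, component$channel)
  kern <- temporal_kernel(times, component$peak_ms, component$halfwidth_ms)
  amp <- base_amp + effect_amp * code

  # spatially mixed AR(1) noise: sources are AR(1) in time, innovations
  # scaled so the stationary SD is noise$sd, then rotated across channels
  Q <- qr.Q(qr(matrix(stats::rnorm(n_ch * n_ch), n_ch)))
  innov_sd <- noise$sd * sqrt(1 - noise$ar^2)
  outlier <- stats::runif(n_tr) < noise$outlier_rate
  dc <- stats::rnorm(n_tr, 0, baseline_sd)

  dat <- array(0, dim = c(n_tr, n_ch, n_t))
  st <- outer(tmpl, kern)                      # channel x time component shape
  for (i in seq_len(n_tr)) {
    src <- matrix(stats::rnorm(n_ch * n_t, 0, innov_sd), n_ch, n_t)
    src <- t(apply(src, 1, function(e)
      as.numeric(stats::filter(e, noise$ar, method = "recursive"))))
    eps <- Q %*% src
    if (outlier[i]) eps <- eps * noise$outlier_scale
    dat[i, , ] <- amp[i] * st + dc[i] + eps
  }
  epoch_set(dat, montage$channel, times, fs, tt,
            subject = subject, task = events$task,
            log = sprintf("synthesized(effect=%.3g)", effect_amp))
}

#' Ground-truth parameter set for the synthetic cohort
#'
#' Collects every data-generating assumption behind the synthetic cohort:
#' component placements per task, per-subject amplitude distributions, the
#' between-subject coupling of the inhibition effect on the feedback effect,
#' its moderation by the trait score, the noise model, and the trait
#' distribution. Defaults place the feedback P3b at Pz (~510 ms), the
#' two-step feedback P3 at CP1 (~450 ms) and the inhibition P3s at Cz, with
#' coupling 0.5 uV/uV attenuating by 0.03 per OCI-R unit -- the magnitudes
#' the group-level moderated regression is expected to recover.
#'
#' @param ... named overrides of the defaults.
#' @return A list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(...) {
  truth <- list(
    components = list(
      gonogo = list(channel = "Cz", peak_ms = 400, halfwidth_ms = 150),
      sst = list(channel = "Cz", peak_ms = 450, halfwidth_ms = 150),
      miflat = list(channel = "Pz", peak_ms = 510, halfwidth_ms = 150),
      twostep = list(channel = "CP1", peak_ms = 450, halfwidth_ms = 150)),
    base_amp = c(gonogo = 4, sst = 4, miflat = 4, twostep = 4),
    fb_effect_mu = 4, fb_effect_sd = 1.5,  # feedback (loss>gain) amplitude
    twostep_dev_sd = 0.5,                  # twostep amp = miflat amp + dev
    inh_base_mu = 3,                       # inhibition amplitude at mean trait
    coupling = 0.5,                        # uV inhibition per uV feedback
    moderation = -0.03,                    # coupling change per trait unit
    moderator = "oci_r",
    subject_noise_sd = 0.8,                # residual inhibition-amplitude SD
    noise = list(sd = 8, ar = 0.9, outlier_rate = 0.05, outlier_scale = 8),
    baseline_sd = 2,
    traits = list(means = c(12.6, 26.3), sds = c(9.5, 5.9), rho = 0.18))
  over <- list(...)
  bad <- setdiff(names(over), names(truth))
  if (length(bad)) stop("unknown truth parameters: ", paste(bad, collapse = ", "))
  truth[names(over)] <- over
  if (truth$fb_effect_sd <= 0 || truth$subject_noise_sd <= 0)
    stop("all SDs must be positive")
  class(truth) <- "synthetic_truth"
  truth
}

#' Generate a synthetic multi-subject cohort
#'
#' Draws per-subject trait scores and component amplitudes, then synthesizes
#' epochs for all four tasks. The inhibition-effect amplitude of subject i
#' (used for both go/nogo and stop-signal tasks, with independent residuals)
#' is `inh_base_mu + (coupling + moderation * (trait_i - mean trait)) *
#' (feedback_amp_i - fb_effect_mu) + residual`, so the group-level moderated
#' regression of inhibition maps on windowed feedback scores has known true
#' slopes: main effect `coupling`, interaction `moderation`. Fully
#' deterministic given `(config, seed)`.
#'
#' @param config list with `n_subjects` and `trials` (named trial counts for
#'   `gonogo`, `sst`, `miflat`, `twostep`); optional `montage`, `fs`,
#'   `window` override the defaults (19 channels, 500 Hz, -200..700 ms).
#' @param truth a [synthetic_truth()] parameter set.
#' @param seed integer seed.
#' @return list with `traits` (data.frame), `subjects` (per subject a list
#'   of four [epoch_set]s plus that subject's true amplitudes), and `truth`.
#' @export
make_cohort <- function(config, truth = synthetic_truth(), seed = 1) {
  need <- c("gonogo", "sst", "miflat", "twostep")
  if (is.null(config$n_subjects) || !all(need %in% names(config$trials)))
    stop("config must provide `n_subjects` and trial counts for tasks: ",
         paste(need, collapse = ", "))
  montage <- if (is.null(config$montage)) default_montage() else config$montage
  fs <- if (is.null(config$fs)) 500 else config$fs
  window <- if (is.null(config$window)) c(-200, 700) else config$window
  set.seed(seed)
  n <- config$n_subjects
  traits <- simulate_traits(n, truth$traits$means, truth$traits$sds,
                            truth$traits$rho)
  m <- traits[[truth$moderator]]
  m_c <- m - mean(m)

  fb_amp <- stats::rnorm(n, truth$fb_effect_mu, truth$fb_effect_sd)
  ts_amp <- fb_amp + stats::rnorm(n, 0, truth$twostep_dev_sd)
  slope <- truth$coupling + truth$moderation * m_c
  gng_amp <- truth$inh_base_mu + slope * (fb_amp - truth$fb_effect_mu) +
    stats::rnorm(n, 0, truth$subject_noise_sd)
  sst_amp <- truth$inh_base_mu + slope * (fb_amp - truth$fb_effect_mu) +
    stats::rnorm(n, 0, truth$subject_noise_sd)
  eff <- list(gonogo = gng_amp, sst = sst_amp, miflat = fb_amp, twostep = ts_amp)

  sim_events <- list(
    gonogo = function(k) simulate_gonogo_events(k),
    sst = function(k) simulate_sst_events(k),
    miflat = function(k) simulate_miflat_events(k),
    twostep = function(k) simulate_twostep_events(k))

  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    sets <- list()
    for (task in need) {
      ev <- sim_events[[task]](config$trials[[task]])
      sets[[task]] <- synthesize_epochs(
        ev, base_amp = truth$base_amp[[task]], effect_amp = eff[[task]][i],
        component = truth$components[[task]], noise = truth$noise,
        montage = montage, fs = fs, window = window,
        baseline_sd = truth$baseline_sd, subject = traits$subject_id[i])
    }
    subjects[[i]] <- list(subject_id = traits$subject_id[i], epochs = sets,
                          true_amp = vapply(eff, `[`, numeric(1), i))
  }
  list(traits = traits, subjects = subjects, truth = truth)
}
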