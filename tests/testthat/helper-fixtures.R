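# Shared fixtures, all generated in code at test time.

# 6-channel midline/centroparietal montage for fast grids
small_montage <- function(chans = c("FCz", "Cz", "CP1", "CPz", "Pz", "P1")) {
  m <- default_montage()
  m[m$channel %in% chans, , drop = FALSE]
}

# minimal beta_map straight from a b grid (channels x times x 1 regressor)
fake_beta_map <- function(b, channels = NULL, times = NULL,
                          regressor = "trial_type", subject = "S") {
  if (is.matrix(b)) b <- array(b, c(dim(b), 1))
  nc <- dim(b)[1]; nt <- dim(b)[2]
  if (is.null(channels)) channels <- paste0("ch", seq_len(nc))
  if (is.null(times)) times <- seq(0, by = 10, length.out = nt)
  dimnames(b) <- list(channels, NULL, regressor)
  structure(list(b = b, channels = channels, times = times,
                 regressors = regressor, subject = subject, task = "fake",
                 n_trials = NA_integer_),
            class = "beta_map")
}

# standard preprocessing chain used by recovery tests
prep_epochs <- function(ep, window = c(-100, 700)) {
  ep <- baseline_correct(ep)
  ep <- smooth_temporal(reject_improbable(ep)$epochs)
  select_analysis_window(ep, window)
}

# Reduced-grid two-level recovery: SST maps regressed on windowed flanker
# feedback scores with OCI-R moderation. Planted moderation is -0.06
# (well-powered recovery condition); grid restricted to 3 channels and
# 350-600 ms. Memoized across test files.
.fixture_cache <- new.env(parent = emptyenv())

recovery_runs <- function(n_seeds = 15) {
  key <- paste0("recovery", n_seeds)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  truth <- synthetic_truth(moderation = -0.06)
  mont <- small_montage(c("Cz", "CP1", "Pz"))
  one <- function(seed) {
    co <- make_cohort(list(
      n_subjects = 60,
      trials = list(gonogo = 8, sst = 160, miflat = 160, twostep = 8),
      montage = mont, fs = 100), truth = truth, seed = seed)
    n <- length(co$subjects)
    ymaps <- vector("list", n); x <- numeric(n)
    for (i in seq_len(n)) {
      ey <- prep_epochs(co$subjects[[i]]$epochs$sst, c(350, 600))
      ymaps[[i]] <- fit_subject_maps(ey, build_design(ey))
      ex <- prep_epochs(co$subjects[[i]]$epochs$miflat, c(350, 600))
      xm <- fit_subject_maps(ex, build_design(ex))
      x[i] <- window_score(xm, "Pz", c(500, 520))
    }
    fit <- fit_moderated_map(ymaps, x, co$traits$oci_r,
                             moderator_name = "oci_r")
    ch <- match("Cz", fit$channels)
    ti <- which.min(abs(fit$times - truth$components$sst$peak_ms))
    A <- vapply(co$subjects, function(s) s$true_amp[["miflat"]], numeric(1))
    lambda <- stats::var(stats::fitted(stats::lm(x ~ A))) / stats::var(x)
    jn <- jn_points(fit, "Cz", truth$components$sst$peak_ms, threshold = 0.01)
    list(b1 = fit$b1[ch, ti], b2 = fit$b2[ch, ti], t2 = fit$t2[ch, ti],
         lambda = lambda, jn = jn)
  }
  out <- lapply(seq_len(n_seeds), one)
  .fixture_cache[[key]] <- list(runs = out, truth = truth)
  .fixture_cache[[key]]
}
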