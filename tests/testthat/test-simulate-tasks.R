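test_that("trait scores reproduce the target moments and stay in range", {
  tr <- simulate_traits(4000, seed = 42)
  expect_true(all(tr$oci_r >= 0 & tr$oci_r <= 72))
  expect_true(all(tr$negative_urgency >= 12 & tr$negative_urgency <= 48))
  # clipping at 0 shifts the OCI-R moments slightly upward; allow for it
  expect_lt(abs(mean(tr$oci_r) - 12.6), 1.0)
  expect_lt(abs(stats::sd(tr$oci_r) - 9.5), 1.0)
  expect_lt(abs(mean(tr$negative_urgency) - 26.3), 0.5)
  expect_lt(abs(stats::sd(tr$negative_urgency) - 5.9), 0.5)
})

test_that("trait correlation tracks rho, including independence", {
  rs <- vapply(1:100, function(s) {
    tr <- simulate_traits(10000, rho = 0.18, seed = s)
    stats::cor(tr$oci_r, tr$negative_urgency)
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.18), 0.02)
  tr0 <- simulate_traits(4000, rho = 0, seed = 7)
  expect_lt(abs(stats::cor(tr0$oci_r, tr0$negative_urgency)), 0.05)
})

test_that("trait simulation rejects invalid parameters", {
  expect_error(simulate_traits(2), "at least 3")
  expect_error(simulate_traits(10, rho = 1), "rho")
  expect_error(simulate_traits(10, sds = c(0, 5.9)), "positive")
})

test_that("go/nogo streams hold exactly 25% nogo trials", {
  ev <- simulate_gonogo_events(400, seed = 1)
  expect_equal(sum(ev$trials$trial_type == "nogo"), 100)
  expect_equal(sum(ev$trials$trial_type == "go"), 300)
  expect_true(all(ev$trials$iti > 0))
  tiny <- simulate_gonogo_events(4, seed = 1)
  expect_equal(sum(tiny$trials$trial_type == "nogo"), 1)
  expect_error(simulate_gonogo_events(10), "divisible by 4")
  expect_identical(simulate_gonogo_events(80, seed = 9)$trials,
                   simulate_gonogo_events(80, seed = 9)$trials)
})

test_that("stop-signal staircase tracks ~50% success for an overlapping racer", {
  ev <- simulate_sst_events(1200, seed = 3)  # 300 stop trials
  st <- ev$trials[ev$trials$trial_type == "stop", ]
  expect_equal(nrow(st), 300)
  acc <- mean(st$stop_success)
  expect_gte(acc, 0.40)
  expect_lte(acc, 0.60)
  # staircase rule: SSD moves by +step after success, -step after failure
  d <- diff(st$ssd)
  expected <- ifelse(utils::head(st$stop_success, -1), 50, -50)
  floored <- utils::head(st$ssd, -1) == 0 & !utils::head(st$stop_success, -1)
  expect_true(all(d[!floored] == expected[!floored]))
})

test_that("mean stop success across seeded sessions converges to 50%", {
  accs <- vapply(1:40, function(s) {
    ev <- simulate_sst_events(1200, seed = s)
    mean(ev$trials$stop_success, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.02)
})

test_that("an unbeatable stop process drives success to 1 and SSD upward", {
  ev <- simulate_sst_events(400, respondent = list(go_mu = 450, go_sd = 80,
                                                   stop_mu = -1e6, stop_sd = 1),
                            seed = 2)
  st <- ev$trials[ev$trials$trial_type == "stop", ]
  expect_true(all(st$stop_success))
  expect_true(all(diff(st$ssd) == 50))
  expect_error(
    simulate_sst_events(400, respondent = list(go_mu = 450, go_sd = -1,
                                               stop_mu = 200, stop_sd = 40)),
    "positive")
  expect_error(simulate_sst_events(400, staircase = list(ssd0 = 0, step = 50)),
               "positive")
})

test_that("two-step transitions are 80/20 and the reward walk stays in bounds", {
  ev <- simulate_twostep_events(10000, seed = 5)
  expect_lt(abs(mean(ev$trials$transition_type == "common") - 0.80), 0.012)
  expect_true(all(ev$trials$outcome_points >= -4 &
                    ev$trials$outcome_points <= 5))
  frozen <- simulate_twostep_events(
    50, walk = list(step_sd = 0, lower = -4, upper = 5, start = 2), seed = 1)
  expect_true(all(frozen$trials$outcome_points == 2))
  expect_error(
    simulate_twostep_events(10, walk = list(step_sd = 1, lower = 4, upper = 5)),
    "bounds")
})

test_that("the reflected walk attains its bounds over long runs", {
  ev <- simulate_twostep_events(50000, seed = 11)
  expect_equal(max(ev$trials$outcome_points), 5L)
  expect_equal(min(ev$trials$outcome_points), -4L)
})

test_that("flanker contexts are balanced and outcomes follow performance", {
  ev <- simulate_miflat_events(200, seed = 4)
  expect_equal(sum(ev$trials$context == "gain"), 100)
  expect_equal(sum(ev$trials$context == "loss_avoidance"), 100)
  perfect <- simulate_miflat_events(
    100, performance = list(error_rate = 0, slow_rate = 0), seed = 1)
  g <- perfect$trials[perfect$trials$context == "gain", ]
  l <- perfect$trials[perfect$trials$context == "loss_avoidance", ]
  expect_true(all(g$outcome == "gain"))
  expect_true(all(l$outcome == "loss_omission"))
  fails <- vapply(1:40, function(s) {
    tt <- simulate_miflat_events(
      200, performance = list(error_rate = 0.1, slow_rate = 0.15),
      seed = s)$trials
    mean(tt$outcome %in% c("gain_omission", "loss"))
  }, numeric(1))
  expect_lt(abs(mean(fails) - 0.25), 0.02)
  expect_error(
    simulate_miflat_events(100, performance = list(error_rate = 0.7,
                                                   slow_rate = 0.7)),
    "sum")
})

test_that("epoch synthesis recovers planted effects in clean limits", {
  mont <- small_montage()
  ev <- simulate_gonogo_events(80, seed = 1)
  # null effect: condition means agree everywhere
  ep0 <- synthesize_epochs(ev, base_amp = 4, effect_amp = 0,
                           component = list(channel = "Cz", peak_ms = 400,
                                            halfwidth_ms = 150),
                           noise = list(sd = 1, ar = 0, outlier_rate = 0,
                                        outlier_scale = 1),
                           montage = mont, fs = 100, baseline_sd = 0,
                           seed = 2)
  code <- condition_code("gonogo", ep0$trial_table)
  dmean <- apply(ep0$data[code > 0, , , drop = FALSE], c(2, 3), mean) -
    apply(ep0$data[code < 0, , , drop = FALSE], c(2, 3), mean)
  expect_lt(max(abs(dmean)), 1.5)  # pure noise at sd 1, n=80
  # noiseless limit: single-trial regression recovers the coded effect
  ep <- synthesize_epochs(ev, base_amp = 4, effect_amp = 3,
                          component = list(channel = "Cz", peak_ms = 400,
                                           halfwidth_ms = 150),
                          noise = list(sd = 1e-9, ar = 0, outlier_rate = 0,
                                       outlier_scale = 1),
                          montage = mont, fs = 100, baseline_sd = 0, seed = 3)
  ep <- select_analysis_window(ep)
  bm <- fit_subject_maps(ep, build_design(ep))
  cz <- match("Cz", bm$channels)
  pk <- which(ep$times == 400)
  expect_equal(bm$b[cz, pk, "trial_type"], 3, tolerance = 1e-6)
  far <- which(ep$times == -100)
  expect_lt(abs(bm$b[cz, far, "trial_type"]), 1e-6)
  expect_error(
    synthesize_epochs(ev, 4, 3,
                      component = list(channel = "Cz", peak_ms = 900,
                                       halfwidth_ms = 150),
                      montage = mont, fs = 100),
    "component peak")
})

test_that("cohort generation is deterministic and encodes the planted coupling", {
  cfg <- list(n_subjects = 12,
              trials = list(gonogo = 8, sst = 8, miflat = 8, twostep = 8),
              montage = small_montage(), fs = 100)
  a <- make_cohort(cfg, seed = 5)
  b <- make_cohort(cfg, seed = 5)
  expect_identical(a$traits, b$traits)
  expect_identical(a$subjects[[3]]$epochs$miflat$data,
                   b$subjects[[3]]$epochs$miflat$data)
  # amplitudes obey inh = base + (coupling + moderation*(m - mean m))*(fb - mu)
  tr <- a$truth
  amps <- t(vapply(a$subjects, function(s) s$true_amp, numeric(4)))
  m_c <- a$traits$oci_r - mean(a$traits$oci_r)
  slope <- tr$coupling + tr$moderation * m_c
  pred <- tr$inh_base_mu + slope * (amps[, "miflat"] - tr$fb_effect_mu)
  resid_sd <- stats::sd(amps[, "gonogo"] - pred)
  expect_lt(resid_sd, 3 * tr$subject_noise_sd)
  expect_error(make_cohort(list(n_subjects = 5,
                                trials = list(gonogo = 8)), seed = 1),
               "trial counts")
})
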