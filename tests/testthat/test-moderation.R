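fake_mod_fit <- function(b1, b2, V11, V12, V22, df,
                         m_mean = 0, m_range = c(-50, 50)) {
  g <- function(v) matrix(v, 1, 1)
  structure(list(
    b0 = g(0), b1 = g(b1), b2 = g(b2),
    se1 = g(sqrt(V11)), se2 = g(sqrt(V22)),
    t1 = g(b1 / sqrt(V11)), t2 = g(b2 / sqrt(V22)),
    p1 = g(2 * pt(-abs(b1 / sqrt(V11)), df)),
    p2 = g(2 * pt(-abs(b2 / sqrt(V22)), df)),
    V11 = g(V11), V12 = g(V12), V22 = g(V22),
    df = df, n = df + 3, regressor = "trial_type", moderator = "m",
    m_mean = m_mean, m_range = m_range, x_mean = 0,
    channels = "chX", times = 0),
    class = "moderation_fit")
}

# dense grid scan of simple-slope p-values: independent JN oracle
jn_grid_oracle <- function(fit, threshold, m_range, res = 0.001) {
  ms <- seq(m_range[1], m_range[2], by = res)
  mc <- ms - fit$m_mean
  tt <- (fit$b1[1] + fit$b2[1] * mc) /
    sqrt(fit$V11[1] + 2 * mc * fit$V12[1] + mc^2 * fit$V22[1])
  sig <- 2 * pt(-abs(tt), fit$df) < threshold
  ms[which(diff(sig) != 0)]  # grid points just before each crossing
}

test_that("window scores average the named electrode and window", {
  b <- matrix(seq_len(10 * 451), 10, 451)  # 10 channels, 500 Hz -200..700
  times <- seq(-200, 700, by = 2)
  map <- fake_beta_map(array(b, c(10, 451, 1)), times = times,
                       regressor = "valence")
  map$channels[4] <- "Pz"
  idx <- which(times >= 500 & times <= 520)
  expect_length(idx, 11)   # 500-520 ms at 500 Hz -> 11 samples
  expect_equal(window_score(map, "Pz", c(500, 520)), mean(b[4, idx]))
  const <- fake_beta_map(array(2.5, c(2, 20, 1)), regressor = "valence")
  expect_equal(window_score(const, "ch1", c(0, 50)), 2.5)
  expect_error(window_score(map, "CP9", c(500, 520)), "not in map")
  expect_error(window_score(map, "Pz", c(500, 520), regressor = "other"),
               "not in map")
})

test_that("moderated regression recovers planted slopes on constructed maps", {
  set.seed(20)
  n <- 80
  x <- rnorm(n, 4, 1.5)
  m <- rnorm(n, 12, 9)
  x_c <- x - mean(x); m_c <- m - mean(m)
  y <- 1 + 0.5 * x_c - 0.02 * x_c * m_c + rnorm(n, sd = 0.1)
  maps <- lapply(y, function(v) fake_beta_map(matrix(v, 1, 1)))
  fit <- fit_moderated_map(maps, x, m, moderator_name = "oci_r")
  expect_equal(fit$b1[1, 1], 0.5, tolerance = 0.05)
  expect_equal(fit$b2[1, 1], -0.02, tolerance = 0.005)
  expect_equal(fit$df, n - 3)
  # cross-check SEs and p-values against lm at the single cell
  ref <- summary(lm(y ~ x_c + I(x_c * m_c)))$coefficients
  expect_equal(fit$se1[1, 1], ref[2, 2], tolerance = 1e-10)
  expect_equal(fit$p2[1, 1], ref[3, 4], tolerance = 1e-10)
  # optional conventional form with the moderator main effect
  fit4 <- fit_moderated_map(maps, x, m, include_moderator_main = TRUE)
  expect_equal(fit4$df, n - 4)
})

test_that("degenerate second-level inputs are rejected", {
  maps <- lapply(1:12, function(i) fake_beta_map(matrix(rnorm(1), 1, 1)))
  expect_error(fit_moderated_map(maps, rep(1, 12), rnorm(12)), "zero variance")
  expect_error(fit_moderated_map(maps, rnorm(12), rep(3, 12)),
               "zero variance")
  expect_error(fit_moderated_map(maps[1:5], rnorm(5), rnorm(5)),
               "at least 10")
})

test_that("beta1 is the simple slope at the moderator mean", {
  set.seed(21)
  n <- 60
  x <- rnorm(n); m <- rnorm(n, 20, 5)
  y <- 0.4 * (x - mean(x)) - 0.05 * (x - mean(x)) * (m - mean(m)) + rnorm(n)
  maps <- lapply(y, function(v) fake_beta_map(matrix(v, 1, 1)))
  fit <- fit_moderated_map(maps, x, m)
  jn <- jn_points(fit, fit$channels[1], 0, threshold = 0.01)
  # evaluate the simple-slope t at m = mean via the quadratic's ingredients
  t_at_mean <- fit$b1[1, 1] / sqrt(fit$V11[1, 1])
  expect_equal(t_at_mean, fit$t1[1, 1], tolerance = 1e-12)
})

test_that("JN boundaries match a dense grid scan of simple-slope p-values", {
  # constructed fit with a known crossing
  fit <- fake_mod_fit(b1 = 1, b2 = -0.05, V11 = 0.01, V12 = 0, V22 = 4e-4,
                      df = 202)
  jn <- jn_points(fit, "chX", 0, threshold = 0.01)
  oracle <- jn_grid_oracle(fit, 0.01, fit$m_range)
  expect_length(jn$boundaries, length(oracle))
  expect_true(all(abs(sort(jn$boundaries) - sort(oracle)) <= 0.001))
  # 100 random fits
  set.seed(22)
  for (i in 1:100) {
    V11 <- runif(1, 1e-4, 0.05)
    V22 <- runif(1, 1e-5, 5e-3)
    V12 <- runif(1, -1, 1) * 0.8 * sqrt(V11 * V22)  # keep covariance PSD
    f <- fake_mod_fit(b1 = rnorm(1), b2 = rnorm(1, sd = 0.1),
                      V11 = V11, V12 = V12, V22 = V22,
                      df = sample(20:300, 1),
                      m_mean = rnorm(1, 10, 5), m_range = c(-40, 60))
    thr <- runif(1, 0.005, 0.05)
    jn <- jn_points(f, "chX", 0, threshold = thr)
    oracle <- jn_grid_oracle(f, thr, f$m_range)
    expect_length(jn$boundaries, length(oracle))
    if (length(oracle))
      expect_true(all(abs(sort(jn$boundaries) - sort(oracle)) <= 0.0011))
  }
})

test_that("a strong unmoderated slope is significant across the whole range", {
  fit <- fake_mod_fit(b1 = 1, b2 = 0, V11 = 1e-4, V12 = 0, V22 = 1e-8,
                      df = 100)
  jn <- jn_points(fit, "chX", 0, threshold = 0.01)
  expect_length(jn$boundaries, 0)
  expect_true(all(jn$intervals$significant))
})

test_that("interval labels are consistent with the slope t at midpoints", {
  fit <- fake_mod_fit(b1 = 0.5, b2 = -0.04, V11 = 0.004, V12 = 0,
                      V22 = 1e-4, df = 57, m_mean = 15, m_range = c(0, 45))
  jn <- jn_points(fit, "chX", 0, threshold = 0.01)
  expect_gt(nrow(jn$intervals), 1)
  # negative moderation: low-moderator side significant, high side not
  expect_true(jn$intervals$significant[1])
  expect_false(jn$intervals$significant[nrow(jn$intervals)])
  expect_true(all(jn$boundaries >= 0 & jn$boundaries <= 45))
})

test_that("map masking is monotone and the identity at p = 1", {
  set.seed(23)
  n <- 40
  x <- rnorm(n); m <- rnorm(n, 15, 8)
  maps <- lapply(seq_len(n), function(i)
    fake_beta_map(matrix(0.5 * x[i] + rnorm(12, sd = 2), 3, 4)))
  fit <- fit_moderated_map(maps, x, m)
  full <- mask_map(fit, 1)
  expect_true(all(full$main$mask))
  expect_identical(full$main$beta, fit$b1)
  m10 <- mask_map(fit, 0.10)
  m01 <- mask_map(fit, 0.01)
  expect_true(all(m10$main$mask[m01$main$mask]))
  expect_lte(sum(m01$interaction$mask), sum(m10$interaction$mask))
  expect_true(all(is.na(m01$main$beta[!m01$main$mask])))
})

test_that("residualization isolates unique trait variance", {
  set.seed(24)
  b <- rnorm(100, 26, 6)
  a <- 0.3 * b + rnorm(100, sd = 4)
  r <- residualize(a, b)
  expect_equal(mean(r), 0, tolerance = 1e-12)
  expect_equal(sum(r * (b - mean(b))), 0, tolerance = 1e-8)
  expect_equal(residualize(2 * b, b), rep(0, 100), tolerance = 1e-10)
  ind <- rnorm(100)
  expect_gt(stats::cor(residualize(ind, b), ind - mean(ind)), 0.99)
  expect_error(residualize(a, rep(1, 100)), "constant")
})
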