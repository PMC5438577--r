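test_that("velocity: finite differences scaled by fs", {
  ramp <- seq(0, 20, by = 2)  # 2 deg/frame
  expect_equal(compute_velocity(ramp, 120), rep(240, length(ramp)))
  expect_equal(compute_velocity(rep(5, 10), 120), rep(0, 10))
  t <- (0:239) / 120
  v <- compute_velocity(10 * sin(2 * pi * t), 120)
  truth <- 10 * 2 * pi * cos(2 * pi * t)
  expect_lt(max(abs(v - truth)[2:239]) / max(abs(truth)), 0.001)
  expect_error(compute_velocity(1:2, 120), "3 samples")
})

test_that("amplitude normalization maps extrema to [-1, 1]", {
  expect_equal(normalize_amplitude(c(0, 5, 10)), c(-1, 0, 1))
  expect_equal(normalize_amplitude(c(-2, 2)), c(-1, 1))
  expect_error(normalize_amplitude(c(3, 3, 3)), "degenerate-signal")
})

test_that("phase angle covers the quadrants and unwraps", {
  pp <- structure(list(norm_theta = c(1, 0, -1, 0),
                       norm_v = c(0, 1, 0, -1)),
                  class = "crp_phase_portrait")
  phi <- compute_phase_angle(pp)$phi
  # unwrapped continuation of 0, 90, 180, 270 (raw -90 lifted by 360)
  expect_equal(phi, c(0, 90, 180, 270))
  pp0 <- structure(list(norm_theta = c(0, 1), norm_v = c(0, 0)),
                   class = "crp_phase_portrait")
  expect_error(compute_phase_angle(pp0), "undefined-phase")
})

test_that("pure sinusoid phase falls linearly from 90 deg, 360 per cycle", {
  t <- seq(0, 1, length.out = 101)
  pp <- phase_portrait(sin(2 * pi * t), 2 * pi * cos(2 * pi * t))
  phi <- compute_phase_angle(pp)$phi
  expect_equal(phi, 90 - 360 * t, tolerance = 1e-6)
  expect_true(all(abs(diff(phi)) <= 180))
})

test_that("unwrap removes 360-degree jumps and respects offsets", {
  expect_equal(unwrap_degrees(c(170, -175, -160)), c(170, 185, 200))
  expect_equal(unwrap_degrees(c(0, 10, 20)), c(0, 10, 20))
  set.seed(7)
  x <- cumsum(runif(50, -170, 170))
  wrapped <- ((x + 180) %% 360) - 180
  expect_equal(unwrap_degrees(wrapped + 720), unwrap_degrees(wrapped) + 720)
  expect_true(all(abs(diff(unwrap_degrees(wrapped))) <= 180))
})

test_that("CRP is proximal minus distal phase, antisymmetric under swap", {
  expect_equal(compute_crp(c(30, 40), c(10, 20), "TS")$crp, c(20, 20))
  expect_equal(compute_crp(c(5, 5), c(5, 5), "TF")$crp, c(0, 0))
  set.seed(3)
  a <- cumsum(rnorm(101)); b <- cumsum(rnorm(101))
  expect_equal(compute_crp(a, b, "SF")$crp, -compute_crp(b, a, "SF")$crp)
  expect_error(compute_crp(1:5, 1:4, "TS"), "length mismatch")
})

test_that("CRP of lagged equal-frequency sinusoids equals the lag", {
  t <- seq(0, 1, length.out = 101)
  for (lag in c(10, 30, 60, 90)) {
    th1 <- sin(2 * pi * t)
    # distal segment leading by the lag makes CRP = prox - dist = +lag
    th2 <- sin(2 * pi * t + lag * pi / 180)
    phi1 <- compute_phase_angle(phase_portrait(th1, 2 * pi * cos(2 * pi * t)))
    phi2 <- compute_phase_angle(phase_portrait(
      th2, 2 * pi * cos(2 * pi * t + lag * pi / 180)))
    crp <- compute_crp(phi1, phi2, "TS")$crp
    mid <- 10:90
    expect_lt(max(abs(crp[mid] - lag)), 1)
  }
})

test_that("per-phase summaries: RMS of the mean curve, SD across trials", {
  pw <- structure(list(task = "gait", n_points = 101L,
                       windows = list(stance = c(1L, 63L),
                                      swing = c(63L, 102L))),
                  class = "crp_phase_windows")
  const <- function(v) structure(list(couple = "TS", crp = rep(v, 101)),
                                 class = "crp_series")
  s1 <- summarize_crp(list(const(10), const(10), const(10)), pw)
  expect_equal(s1$rms, c(10, 10))
  expect_equal(s1$sd, c(0, 0))
  expect_equal(s1$n_trials, c(3L, 3L))

  s2 <- summarize_crp(list(const(0), const(10), const(20)), pw)
  expect_equal(s2$rms, c(10, 10))
  expect_equal(s2$sd, rep(sd(c(0, 10, 20)), 2))

  # mean curve 30 sin over a full-cycle window: RMS -> 30/sqrt(2)
  pw1 <- structure(list(task = "gait", n_points = 101L,
                        windows = list(cycle = c(1L, 102L))),
                   class = "crp_phase_windows")
  g <- seq(0, 1, length.out = 101)
  sine <- structure(list(couple = "TS", crp = 30 * sin(2 * pi * g)),
                    class = "crp_series")
  s3 <- summarize_crp(list(sine, sine), pw1)
  expect_equal(s3$rms, 30 / sqrt(2), tolerance = 0.01)

  expect_error(summarize_crp(list(const(1)), pw, sd_mode = "across_trials"),
               "within_curve")
  s4 <- summarize_crp(list(const(1)), pw, sd_mode = "within_curve")
  expect_equal(s4$sd, c(0, 0))
})

test_that("identical angle inputs give CRP identically zero end to end", {
  m <- gait_model(jitter_sd = 0, noise_sd = 0,
                  couple_lags = c(ts = 0, sf = 0))
  tr <- lapply(1:2, function(i) generate_gait_trial(m, trial_index = i))
  # force thigh and shank channels identical
  for (i in seq_along(tr)) tr[[i]]$angles$shank <- tr[[i]]$angles$thigh
  fit <- crp_analysis(tr)
  expect_true(all(abs(fit$crp$TS) < 1e-9))
  ts_rows <- fit$summary[fit$summary$couple == "TS", ]
  expect_true(all(ts_rows$rms < 1e-9))
  expect_true(all(ts_rows$sd < 1e-9))
})
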