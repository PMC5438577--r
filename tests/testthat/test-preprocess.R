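fs <- 120
tt <- (0:599) / fs

# least-squares projection onto sin/cos at frequency f over interior samples
sine_fit <- function(y, f, i = 101:500) {
  X <- cbind(sin(2 * pi * f * tt[i]), cos(2 * pi * f * tt[i]))
  a <- unname(stats::coef(stats::lm.fit(X, y[i])))
  c(gain = sqrt(sum(a^2)), phase_deg = atan2(a[2], a[1]) * 180 / pi)
}

test_that("dual-pass Butterworth has unit DC gain and half gain at cutoff", {
  expect_equal(lowpass_filter(rep(3.7, 100), fs, 6, 4), rep(3.7, 100),
               tolerance = 1e-8)

  r1 <- sine_fit(lowpass_filter(sin(2 * pi * 1 * tt), fs, 6, 4), 1)
  expect_lt(abs(r1["gain"] - 1), 0.01)
  expect_lt(abs(r1["phase_deg"]), 0.5)

  # at the cutoff each pass attenuates by 1/sqrt(2): dual-pass gain 1/2
  r6 <- sine_fit(lowpass_filter(sin(2 * pi * 6 * tt), fs, 6, 4), 6)
  expect_lt(abs(r6["gain"] - 0.5), 0.02)
  expect_lt(abs(r6["phase_deg"]), 0.5)

  expect_error(lowpass_filter(1:5, fs, 6, 4), "too short")
  expect_error(lowpass_filter(sin(tt), fs, 70, 4), "fs/2")
})

test_that("filtering is idempotent in the pass band", {
  x <- sin(2 * pi * 0.5 * tt)
  y1 <- lowpass_filter(x, fs, 6, 4)
  y2 <- lowpass_filter(y1, fs, 6, 4)
  expect_lt(max(abs(y2 - y1)) / max(abs(y1)), 0.01)
})

test_that("contact events: threshold runs give IC at run start, TO after", {
  # push-off run at samples 3..5, landing run at 8..10 (1-based)
  grf <- c(0, 0, 50, 80, 50, 0, 0, 40, 60, 40, 0)
  ev <- detect_contact_events(grf, fs = 120, threshold = 10, task = "hop")
  expect_equal(ev$toe_offs, 6L)
  expect_equal(ev$initial_contacts, 8L)
  expect_error(detect_contact_events(rep(0, 10), 120, 10, "gait"),
               "no contact detected")
  # single stance is not enough for a gait cycle
  expect_error(detect_contact_events(c(0, 0, 50, 80, 50, 0, 0), 120, 10, "gait"),
               "insufficient-cycle")
})

test_that("event detection ignores sub-threshold offsets and short blips", {
  grf <- rep(0, 400)
  grf[51:110] <- 400
  grf[151:152] <- 400  # 2 samples @120 Hz < 25 ms: debounce drops it
  grf[251:310] <- 400
  base <- detect_contact_events(grf, 120, 10, "gait")
  expect_equal(base$initial_contacts, c(51L, 251L))
  expect_equal(base$toe_offs, c(111L, 311L))
  # constant sub-threshold offset leaves events unchanged
  shifted <- detect_contact_events(grf + 5, 120, 10, "gait")
  expect_equal(shifted$initial_contacts, base$initial_contacts)
  expect_equal(shifted$toe_offs, base$toe_offs)
})

test_that("gait events on synthetic GRF recover the built-in stance", {
  m <- gait_model(jitter_sd = 0, noise_sd = 0)
  tr <- generate_gait_trial(m)
  ev <- detect_contact_events(tr$grf_vertical, tr$fs, 10, "gait")
  ic <- ev$initial_contacts
  true_ic <- (0:(m$n_cycles - 1)) * m$cycle_samples + 1
  expect_true(all(abs(ic - true_ic[seq_along(ic)]) <= 1))
  # event detection is invariant to a constant sub-threshold offset
  ev2 <- detect_contact_events(correct_grf_baseline(tr$grf_vertical + 4),
                               tr$fs, 10, "gait")
  expect_equal(ev2$initial_contacts, ev$initial_contacts)
  expect_equal(ev2$toe_offs, ev$toe_offs)
})

test_that("phase windows: gait stance/swing split on the 101-point base", {
  ev <- structure(list(task = "gait",
                       initial_contacts = c(1L, 101L), toe_offs = 63L),
                  class = "crp_events")
  pw <- define_phase_windows(ev, task = "gait", n_points = 101)
  expect_equal(pw$windows$stance, c(1L, 63L))  # 62% of the cycle
  expect_equal(pw$windows$swing, c(63L, 102L))
  expect_equal(length(window_indices(pw, "stance")) +
                 length(window_indices(pw, "swing")), 101L)
})

test_that("phase windows: hop preflight/flight/landing partition", {
  ev <- structure(list(task = "hop", initial_contacts = c(1L, 71L),
                       toe_offs = 41L), class = "crp_events")
  pw <- define_phase_windows(ev, trial_span = c(1L, 101L), task = "hop",
                             n_points = 101)
  expect_equal(pw$windows$preflight, c(1L, 41L))
  expect_equal(pw$windows$flight, c(41L, 71L))
  expect_equal(pw$windows$landing, c(71L, 102L))
})

test_that("windows always partition the normalized base", {
  set.seed(42)
  for (rep in 1:50) {
    np <- sample(11:151, 1)
    span <- c(1L, 100L)
    to <- sample(5:95, 1)
    ic2 <- sample((to + 4):100, 1)
    ev <- structure(list(task = "gait",
                         initial_contacts = c(1L, as.integer(ic2)),
                         toe_offs = as.integer(to)), class = "crp_events")
    pw <- tryCatch(define_phase_windows(ev, task = "gait", n_points = np),
                   error = function(e) NULL)
    if (is.null(pw)) next  # degenerate window (< 2 grid points) rejected
    idx <- sort(unlist(lapply(names(pw$windows), window_indices, pw = pw)))
    expect_equal(idx, 1:np)
  }
})

test_that("time normalization: spline onto the percent grid", {
  expect_equal(time_normalize(c(0, 1, 2, 3), c(1, 4), n_points = 5),
               c(0, 0.75, 1.5, 2.25, 3))
  expect_equal(time_normalize(rep(2, 10), c(1, 10), n_points = 7), rep(2, 7))
  # 2 Hz sinusoid resampled 120 -> 101 points over one second
  x <- sin(2 * pi * 2 * (0:120) / 120)
  y <- time_normalize(x, c(1, 121), n_points = 101)
  truth <- sin(2 * pi * 2 * seq(0, 1, length.out = 101))
  expect_lt(max(abs(y - truth)), 1e-3)
  expect_error(time_normalize(1:3, c(1, 3), 11), "interpolation error")
})
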