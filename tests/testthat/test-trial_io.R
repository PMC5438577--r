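test_that("trial constructor enforces the channel invariants", {
  t4 <- (0:3) / 120
  tr <- trial("S01", "gait", "none", 1, fs = 120, time = t4,
              angles = list(thigh = c(1, 2, 3, 4)),
              grf_vertical = c(0, 10, 10, 0))
  expect_s3_class(tr, "crp_trial")
  expect_equal(tr$fs, 120)

  expect_error(
    trial("S01", "gait", "none", 1, fs = 120, time = c(0, 1, 2) / 100,
          angles = list(thigh = 1:3), grf_vertical = c(0, 0, 0)),
    "sampling error")
  expect_error(
    trial("S01", "gait", "none", 1, fs = 120, time = t4,
          angles = list(thigh = 1:3), grf_vertical = c(0, 0, 0, 0)),
    "length")
  expect_error(
    trial("S01", "gait", "none", 1, fs = 120, time = t4,
          angles = list(knee = 1:4), grf_vertical = rep(0, 4)),
    "unknown angle channel")
})

test_that("GRF baseline correction removes plate offset and clamps at zero", {
  grf <- c(rep(5, 50), 5 + 800 * sin(pi * (1:50) / 50))
  out <- correct_grf_baseline(grf)
  expect_true(all(out >= 0))
  expect_equal(out[1:50], rep(0, 50))
  expect_equal(max(out), max(grf) - 5)
})

test_that("trial CSV write -> load round-trips, angles and markers", {
  n <- 8
  tr <- trial("S07", "gait", "sleeve", 3, fs = 120, time = (0:(n - 1)) / 120,
              angles = list(thigh = sin(1:n), shank = cos(1:n),
                            foot = rep(0.5, n)),
              markers = list(sacrum = cbind(x = 1:n / 10, y = 0, z = 1)),
              grf_vertical = c(0, 0, 50, 80, 60, 20, 0, 0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(tr, path)
  tr2 <- load_trial_csv(path, meta = list(subject_id = "S07", task = "gait",
                                          condition = "sleeve", trial_index = 3,
                                          fs = 120))
  expect_equal(tr2$angles, tr$angles, tolerance = 1e-12)
  expect_equal(unname(tr2$markers$sacrum), unname(tr$markers$sacrum))
  expect_equal(tr2$grf_vertical, tr$grf_vertical)
  expect_equal(tr2$condition, "sleeve")
})

test_that("loading rejects missing columns and bad time bases", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,angle_thigh", "0,1", "0.01,2"), path)
  expect_error(load_trial_csv(path), "grf_vertical")
  writeLines(c("time,grf_vertical", "0,1", "0.01,2"), path)
  expect_error(load_trial_csv(path), "angle")
  writeLines(c("time,angle_thigh,grf_vertical", "0,1,0", "0.01,2,0", "0.05,3,0"),
             path)
  expect_error(load_trial_csv(path), "non-uniform")
})

test_that("config loading applies defaults, merges keys, rejects junk", {
  expect_equal(load_config(NULL), run_config())
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", path)
  cfg <- load_config(path)
  expect_equal(cfg$cutoff_hz, 6)
  expect_equal(cfg$n_points, 101L)
  expect_equal(cfg$alpha, 0.05)

  writeLines("cutoff_hz: 8", path)
  cfg8 <- load_config(path)
  expect_equal(cfg8$cutoff_hz, 8)
  cfg8$cutoff_hz <- 6
  expect_equal(cfg8, run_config())

  jpath <- withr::local_tempfile(fileext = ".json")
  writeLines('{"n_points": 51, "sd_mode": "within_curve"}', jpath)
  cj <- load_config(jpath)
  expect_equal(cj$n_points, 51L)
  expect_equal(cj$sd_mode, "within_curve")

  writeLines("alpha: 1.5", path)
  expect_error(load_config(path), "alpha")
  writeLines("cutoff: 8", path)
  expect_error(load_config(path), "unknown config key")
})

test_that("results table formats at fixed precision and round-trips", {
  rows <- data.frame(parameter = c("velocity", "stride"),
                     mean_a = c(136.04, 147.23), sd_a = c(6.91, 10.2),
                     mean_b = c(140.1, 149.8), sd_b = c(7.4, 10.1),
                     test = c("paired_t", "wilcoxon"),
                     statistic = c(2.01, 12), p = c(0.032, 0.0004),
                     n = c(11L, 11L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_results_table(rows, path)
  txt <- readLines(path)
  expect_true(any(grepl("0.032", txt)))
  expect_true(any(grepl("<0.001", txt)))

  back <- read_results_table(path)
  expect_equal(back$mean_a, c(136.0, 147.2))
  expect_equal(back$p[1], 0.032)
  expect_true(is.na(back$p[2]))
  expect_equal(back$p_ceiling[2], 0.001)

  expect_error(write_results_table(rows[0, ], path), "nonempty")
})
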