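test_that("flow-noise calibration inverts the linearized power budget", {
  cal <- calibrate_flow_noise(23.1, 135.0)
  u <- cal$noise_frac; e <- cal$exponent
  # forward model reproduces both targets
  expect_equal(100 * (sqrt(1 + u * ((4 / 3.5)^(2 * e) - 1)) - 1), 23.1,
               tolerance = 1e-8)
  expect_equal(100 * (sqrt(1 + u * ((4.5 / 3.5)^(2 * e) - 1)) - 1), 135.0,
               tolerance = 1e-8)
  expect_true(u > 0 && u < 1)

  g <- calibrate_thrombosis_gain(6.4, u, e)
  phi <- (3.3 / 3.5)^(2 * e)
  expect_equal(100 * (sqrt(1 - u + u * phi * (1 + g)^2) - 1), 6.4,
               tolerance = 1e-8)
})

test_that("thrombosis gain is zero pre-onset, monotone, and saturates", {
  t <- seq(0, 3000, by = 10)
  g <- thrombosis_gain(t, onset_s = 600, rise_time_s = 300, max_gain = 2)
  expect_true(all(g[t < 600] == 0))
  expect_true(all(diff(g) >= 0))
  expect_equal(g[length(g)], 2, tolerance = 1e-3)
  expect_equal(thrombosis_gain(600 + 300, 600, 300, 2), 1,
               tolerance = 0.01)    # half-maximum at the rise time
})

test_that("identical seeds reproduce recordings and written cohorts exactly", {
  cfg <- quick_sim(n_subjects = 2, include = "reversal",
                   post_reversal_s = 120, seed = 42)
  r1 <- simulate_recording(cfg, 1)
  r2 <- simulate_recording(cfg, 1)
  expect_identical(r1$recording$gx, r2$recording$gx)
  expect_identical(r1$recording$aux$delta_p_oxy, r2$recording$aux$delta_p_oxy)
  expect_identical(r1$params, r2$params)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_cohort(cfg, dir = d1)
  simulate_cohort(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("degenerate configurations produce degenerate signals", {
  # zero target RMS: no harmonics, no noise; zero gravity: all-zero axes
  cfg <- quick_sim(n_subjects = 1, include = "reversal",
                   post_reversal_s = 120, seed = 1,
                   baseline_rms_g = 0, gravity_g = c(0, 0, 0))
  rec <- simulate_recording(cfg, 1)$recording
  expect_true(all(rec$gx == 0) && all(rec$gy == 0) && all(rec$gz == 0))
})

test_that("a single injected harmonic matches the analytic window RMS", {
  A <- 0.3
  cfg <- sim_config(n_subjects = 1, include = "speed", level_duration_s = 60,
                    rpm = c(low = 3000, medium = 3000, high = 3000),
                    harmonic_rel = 1, axis_rel = 0,
                    baseline_rms_g = A / sqrt(2), seed = 5,
                    sdlog_harmonics = 0, sdlog_noise = 0, sdlog_gain = 0)
  # pin the derived block to a pure tone: amplitude A, no broadband floor
  cfg$derived$amplitudes_g <- A
  cfg$derived$sigma_broadband_g <- 0
  cfg$derived$harmonic_power <- A^2 / 2
  cfg$derived$noise_power_inband <- 0
  res <- simulate_recording(cfg, 1)
  # fundamental at rpm/60 = 50 Hz, amplitude A on the gravity axis: the norm
  # is |1 + A sin|, linear for A < 1, so in-band RMS is exactly A / sqrt(2)
  rs <- process_recording(res$recording)
  expect_lt(max(abs(rs$values - A / sqrt(2))), 1e-6)
  expect_equal(res$truth$rms_low, A / sqrt(2), tolerance = 1e-12)

  # a sub-passband drift component must contribute nothing after filtering
  cfg_d <- cfg; cfg_d$drift_amp_g <- 0.05; cfg_d$drift_hz <- 0.5
  rs_d <- process_recording(simulate_recording(cfg_d, 1)$recording)
  expect_lt(max(abs(rs_d$values - rs$values)), 1e-6)
})

test_that("RMS responds to gain and noise, not to in-band frequency placement", {
  base <- quick_sim(n_subjects = 1, include = "reversal",
                    post_reversal_s = 960, seed = 9,
                    sdlog_harmonics = 0, sdlog_noise = 0, sdlog_gain = 0)
  t15_rms <- function(cfg) {
    res <- simulate_recording(cfg, 1)
    rs <- process_recording(res$recording)
    extract_at_timepoint(rs, event_time(res$timeline, "t15"))
  }
  r0 <- t15_rms(base)
  up <- base; up$derived$max_gain <- base$derived$max_gain * 2
  expect_gt(t15_rms(up), r0)                 # larger gain, larger RMS

  # moving the fundamental inside the passband leaves the RMS unchanged
  shifted <- quick_sim(n_subjects = 1, include = "reversal",
                       post_reversal_s = 960, seed = 9,
                       rpm = c(low = 3600, medium = 4200, high = 4800),
                       sdlog_harmonics = 0, sdlog_noise = 0, sdlog_gain = 0)
  expect_equal(t15_rms(shifted), r0, tolerance = 5e-3)
})

test_that("cohort generation has the requested cardinality and spread", {
  cfg <- quick_sim(n_subjects = 7, include = "reversal",
                   post_reversal_s = 120, seed = 13)
  dir <- withr::local_tempdir()
  co <- simulate_cohort(cfg, dir = dir)
  expect_length(co$subjects, 7)
  expect_length(list.files(dir, pattern = "recording\\.csv$"), 7)
  expect_length(list.files(dir, pattern = "timeline\\.csv$"), 7)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.txt")))
  expect_identical(co$manifest$n_subjects, 7L)

  # zero between-subject spread: identical drawn parameters, distinct noise
  cfg0 <- quick_sim(n_subjects = 3, include = "reversal",
                    post_reversal_s = 120, seed = 13,
                    sdlog_harmonics = 0, sdlog_noise = 0, sdlog_gain = 0)
  co0 <- simulate_cohort(cfg0)
  sc <- vapply(co0$subjects, function(s) s$params$s_harm, numeric(1))
  expect_true(all(sc == 1))
  tr <- vapply(co0$subjects, function(s) s$truth$drms_t15_pct, numeric(1))
  expect_equal(tr, rep(tr[1], 3))
})

test_that("detection lead time reflects the configured pressure lag", {
  cfg <- quick_sim(n_subjects = 1, include = "reversal",
                   post_reversal_s = 1800, seed = 21,
                   sdlog_harmonics = 0, sdlog_noise = 0, sdlog_gain = 0)
  res <- simulate_recording(cfg, 1)
  rs <- process_recording(res$recording)
  onset <- event_time(res$timeline, "reversal")
  lt <- detection_lead_time(rs, res$recording$aux$delta_p_oxy, onset)
  expect_true(lt$crossed_rms && lt$crossed_dp)
  expect_gt(lt$lead_s, 0)                    # 900-s lag: vibration leads

  # lag 0 with matched response shapes and no flow dip: near-simultaneous
  cfg0 <- quick_sim(n_subjects = 1, include = "reversal",
                    post_reversal_s = 1200, seed = 21, lag_s = 0,
                    flow_post = c(t0 = 3.5, t15 = 3.5, t30 = 3.5, t60 = 3.5),
                    sdlog_harmonics = 0, sdlog_noise = 0, sdlog_gain = 0)
  # match the pressure response magnitude to the vibration response so the
  # two fractional thresholds are crossed at the same point of the rise
  u <- cfg0$derived$noise_frac
  cfg0$dp_clot_frac <-
    sqrt(1 - u + u * (1 + cfg0$derived$max_gain)^2) - 1
  res0 <- simulate_recording(cfg0, 1)
  rs0 <- process_recording(res0$recording)
  lt0 <- detection_lead_time(rs0, res0$recording$aux$delta_p_oxy,
                             event_time(res0$timeline, "reversal"))
  expect_true(lt0$crossed_rms && lt0$crossed_dp)
  expect_lte(abs(lt0$lead_s), 2 * rs0$window_s)

  expect_error(detection_lead_time(rs, res$recording$aux$delta_p_oxy,
                                   onset_s = 10),
               "no pre-reversal baseline windows")
})
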