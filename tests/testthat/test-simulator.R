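test_that("a clean 60 s recording at HR 60 contains ~60 beats", {
  sim <- clean_sim(60, hr = 60, seed = 1)
  # brute-force local-maximum scan on the generated signal
  x <- sim$recording$samples
  mid <- (max(x) + min(x)) / 2
  i <- 2:(length(x) - 1L)
  n_peaks <- sum(x[i] > x[i - 1L] & x[i] >= x[i + 1L] & x[i] > mid)
  expect_lte(abs(n_peaks - 60), 1)
  expect_lte(abs(nrow(sim$truth$beats) - 60), 1)
})

test_that("identical config and seed reproduce the recording bit for bit", {
  cfg <- sim_config(30, hr_bpm = 72, sbp_mmHg = 118, dbp_mmHg = 76,
                    wander = list(model = "random_walk", amplitude = 0.5),
                    sensor = list(gain = 0.04, offset = 1, noise_sd = 0.01),
                    seed = 42)
  a <- simulate_recording(cfg)
  b <- simulate_recording(cfg)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$truth$beats, b$truth$beats)
  expect_identical(a$truth$wander_trace, b$truth$wander_trace)
})

test_that("degenerate trajectories (DBP >= SBP) are rejected", {
  expect_error(sim_config(60, sbp_mmHg = 100, dbp_mmHg = 100),
               "SBP must exceed DBP")
  expect_error(sim_config(60, sbp_mmHg = traj_ramp(120, 70), dbp_mmHg = 80),
               "SBP must exceed DBP")
})

test_that("per-beat max/min of a clean unity-gain recording match truth", {
  sim <- clean_sim(40, hr = 64, sbp = 125, dbp = 78, seed = 3)
  tb <- sim$truth$beats
  x <- sim$recording$samples
  fs <- sim$recording$fs
  for (k in seq_len(nrow(tb) - 1L)) {
    span <- (floor(tb$trough_t[k] * fs) - 1L):(floor(tb$trough_t[k + 1] * fs) + 1L)
    expect_lt(abs(max(x[span]) - tb$sbp[k + 1]), 0.05)
    expect_lt(abs(min(x[span]) - tb$dbp[k]), 0.05)
  }
})

test_that("wander injection is additive, seeded, and spectrally low-frequency", {
  sim <- clean_sim(120, seed = 2)
  rec <- sim$recording

  # zero amplitude is the identity
  w0 <- inject_baseline_wander(rec, list(model = "random_walk", amplitude = 0))
  expect_identical(w0$samples, rec$samples)
  expect_identical(attr(w0, "wander_trace"), numeric(length(rec$samples)))

  # determinism and exact additivity
  w1 <- inject_baseline_wander(rec, list(model = "random_walk", amplitude = 0.5),
                               seed = 7)
  w2 <- inject_baseline_wander(rec, list(model = "random_walk", amplitude = 0.5),
                               seed = 7)
  expect_identical(w1$samples, w2$samples)
  expect_equal(w1$samples - rec$samples, attr(w1, "wander_trace"),
               tolerance = 1e-12)
  expect_equal(stats::sd(attr(w1, "wander_trace")), 0.5, tolerance = 1e-10)

  # sum-of-sinusoids at 0.05 Hz: >= 95% of power below 0.2 Hz
  w3 <- inject_baseline_wander(rec, list(model = "sum_of_sinusoids",
                                         amplitude = 1,
                                         corner_freq_Hz = 0.05), seed = 9)
  expect_gte(power_below(attr(w3, "wander_trace"), rec$fs, 0.2), 0.95)

  # the random-walk model concentrates its power at low frequency too
  expect_gte(power_below(attr(w1, "wander_trace"), rec$fs, 0.2), 0.95)
})

test_that("motion artifacts behave as specified on a flat carrier", {
  fs <- 250
  flat <- waveform_recording(rep(0, 60 * fs), fs = fs)
  tt <- rec_times(flat)

  # empty event list is the identity
  expect_identical(inject_motion_artifacts(flat, list())$samples, flat$samples)

  # a +2 unit step at t = 30 s shifts the mean by 2
  st <- inject_motion_artifacts(flat, list(
    artifact_event("step", t_start = 30, magnitude = 2, duration_s = 0.2)))
  expect_equal(mean(st$samples[tt > 30.5]) - mean(st$samples[tt < 29.5]), 2,
               tolerance = 1e-12)

  # a 1 Hz cyclic event dominates the periodogram at 1 Hz
  cy <- inject_motion_artifacts(
    waveform_recording(rep(5, 60 * fs), fs = fs),
    list(artifact_event("cyclic", t_start = 0, magnitude = 1,
                        duration_s = 60, freq_Hz = 1)))
  x <- cy$samples - mean(cy$samples)
  p <- Mod(stats::fft(x))^2
  half <- 2:(length(x) / 2)
  f_peak <- (which.max(p[half])) / length(x) * fs
  expect_equal(f_peak, 1, tolerance = 0.02)

  # impulse transients return to baseline outside their span
  im <- inject_motion_artifacts(flat, list(
    artifact_event("impulse", t_start = 10, magnitude = 3, duration_s = 1)))
  expect_equal(im$samples[tt < 10 | tt > 11.01], rep(0, sum(tt < 10 | tt > 11.01)))
  expect_equal(max(im$samples), 3, tolerance = 1e-6)

  # events beyond the recording end are rejected
  expect_error(inject_motion_artifacts(flat, list(
    artifact_event("impulse", t_start = 100, magnitude = 1, duration_s = 1))),
    "beyond the end")
})

test_that("sensor transform is affine with calibrated Gaussian noise", {
  rec <- waveform_recording(c(1, 2, 3), fs = 100)
  out <- sensor_transform(rec, gain = 2, offset = 5)
  expect_equal(out$samples, c(7, 9, 11))
  expect_identical(out$units, "sensor")

  idn <- sensor_transform(waveform_recording(c(4, 5), fs = 100), 1, 0, 0)
  expect_equal(idn$samples, c(4, 5))

  expect_error(sensor_transform(rec, gain = 0), "gain must be > 0")

  big <- sensor_transform(waveform_recording(rep(0, 1e5), fs = 100),
                          gain = 1, offset = 0, noise_sd = 0.1, seed = 11)
  expect_gt(stats::sd(big$samples), 0.09)
  expect_lt(stats::sd(big$samples), 0.11)
})

test_that("recordings round-trip through CSV and bad files are rejected", {
  sim <- clean_sim(5, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(sim$recording, path)
  back <- read_recording(path)
  expect_equal(back$samples, sim$recording$samples, tolerance = 1e-9)
  expect_equal(back$fs, sim$recording$fs, tolerance = 1e-9)
  expect_identical(back$units, sim$recording$units)

  # a shuffled row breaks monotonicity and is rejected
  df <- utils::read.csv(path)
  df[c(10, 11), ] <- df[c(11, 10), ]
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_recording(path), "not strictly increasing")
})
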