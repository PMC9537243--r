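cuff_120_80 <- cuff_calibration(120, 80)

test_that("m0 calibration reproduces the hand-computed worked value", {
  # 5 identical beats: peak 3.0 u, following trough 1.0 u, PP_s 2.0 u,
  # DTT 0.7 s, cuff 120/80 (PP0 = 40): m0 = (40/2.0)*(2.0/0.7)
  b <- make_beats(n = 5, peak_v = 3, onset_v = 1, end_v = 1, dtt_s = 0.7)
  cal <- calibrate_m0(b, cuff_120_80, n = 5)
  expect_equal(cal$m0, 57.142857142857, tolerance = 1e-12)

  # doubling all sensor values leaves m0 unchanged (sensor-unit invariance)
  b2 <- make_beats(n = 5, peak_v = 6, onset_v = 2, end_v = 2, dtt_s = 0.7)
  expect_equal(calibrate_m0(b2, cuff_120_80, n = 5)$m0, cal$m0,
               tolerance = 1e-12)

  # gain anchors the first-five mean pulse amplitude to PP0
  expect_equal(cal$gain, 40 / 2)
  expect_equal(cal$gain * 1 + cal$offset, 80) # trough 1.0 u -> DBP0

  # a zero-DTT calibration beat is rejected
  b3 <- make_beats(n = 5, dtt_s = c(0.7, 0.7, 0, 0.7, 0.7))
  b3$valid <- b3$dtt_s > 0
  expect_error(calibrate_m0(b3, cuff_120_80, n = 5), "fewer than 5")
  b3$valid <- TRUE
  expect_error(calibrate_m0(b3, cuff_120_80, n = 5), "non-positive")
})

test_that("the DBP estimator reproduces the worked examples", {
  b <- make_beats(n = 5, peak_v = 3, onset_v = 1, end_v = 1, dtt_s = 0.7,
                  c_slope = 10)
  cal <- calibrate_m0(b, cuff_120_80, n = 5)
  expect_equal(cal$m0, 400 / 7, tolerance = 1e-12)

  # calibration identity: DTT 0.7, C/C0 = 1 -> eDBP = DBP0 = 80
  expect_equal(estimate_dbp(b, cal, cuff_120_80), rep(80, 5),
               tolerance = 1e-12)

  # DTT 0.6 -> 120 - (400/7)*0.6 = 85.714...
  b06 <- make_beats(n = 5, dtt_s = 0.6, c_slope = 10)
  expect_equal(estimate_dbp(b06, cal, cuff_120_80)[1], 120 - 240 / 7,
               tolerance = 1e-12)

  # C/C0 = 2, DTT 0.7 -> 120 - 20 = 100
  b2c <- make_beats(n = 5, dtt_s = 0.7, c_slope = 20)
  expect_equal(estimate_dbp(b2c, cal, cuff_120_80)[1], 100, tolerance = 1e-12)

  # monotonicity: eDBP decreases in DTT, increases in C
  dtts <- seq(0.4, 0.9, by = 0.05)
  e_dtt <- vapply(dtts, function(d) {
    estimate_dbp(make_beats(1, dtt_s = d, c_slope = 10), cal, cuff_120_80)
  }, numeric(1))
  expect_true(all(diff(e_dtt) < 0))
  cs <- seq(4, 30, by = 2)
  e_c <- vapply(cs, function(cc) {
    estimate_dbp(make_beats(1, dtt_s = 0.7, c_slope = cc), cal, cuff_120_80)
  }, numeric(1))
  expect_true(all(diff(e_c) > 0))
})

test_that("pressure-unit transform anchors the calibration beats to the cuff", {
  b <- make_beats(n = 5, peak_v = 3, onset_v = 1, end_v = 1, dtt_s = 0.7)
  cal <- calibrate_m0(b, cuff_120_80, n = 5)
  rec <- waveform_recording(c(1, 2, 3), fs = 100, units = "sensor")
  out <- to_pressure_units(rec, cal)
  expect_equal(out$samples, c(80, 100, 120)) # gain 20, trough 1 u -> 80 mmHg
  expect_identical(out$units, "mmHg")
  # first-five mean end-trough maps to DBP0 by construction
  expect_equal(cal$gain * mean(b$end_v[1:5]) + cal$offset, 80,
               tolerance = 1e-9)
  # identity transform
  cal1 <- cal; cal1$gain <- 1; cal1$offset <- 0
  expect_equal(to_pressure_units(rec, cal1)$samples, rec$samples)
  expect_warning(to_pressure_units(out, cal), "already in mmHg")
})

test_that("moving median matches a brute-force sort oracle", {
  expect_equal(moving_median(c(1, 9, 2, 8, 3), 3), c(5.0, 2, 8, 3, 5.5))
  expect_equal(moving_median(rep(4, 10), 5), rep(4, 10))
  set.seed(31)
  x <- stats::rnorm(200)
  expect_identical(moving_median(x, 1), x)

  # independent brute force: sort each window and index the middle
  brute <- function(x, w) {
    n <- length(x)
    lo_h <- (w - 1) %/% 2
    hi_h <- w - 1 - lo_h
    vapply(seq_len(n), function(i) {
      win <- sort(x[max(1, i - lo_h):min(n, i + hi_h)])
      m <- length(win)
      if (m %% 2 == 1) win[(m + 1) / 2] else (win[m / 2] + win[m / 2 + 1]) / 2
    }, numeric(1))
  }
  for (rep_i in 1:25) {
    n <- sample(5:60, 1)
    w <- sample(1:12, 1)
    x <- stats::rnorm(n)
    expect_identical(moving_median(x, w), brute(x, w))
  }
  expect_identical(moving_median(numeric(0), 5), numeric(0))
})

test_that("baseline offsets follow their definition and reject mismatches", {
  e <- rep(80, 100)
  b0 <- baseline_offset(e, e)
  expect_equal(b0$raw_offset, rep(0, 100))
  expect_equal(b0$smoothed_offset, rep(0, 100))

  # linear ramp 0 -> 10 mmHg over 100 beats: the smoothed offset tracks it
  ramp <- seq(0, 10, length.out = 100)
  br <- baseline_offset(e + ramp, e)
  inc <- ramp[2] - ramp[1]
  expect_lt(max(abs(br$smoothed_offset - ramp)), 15 * inc)

  # one +50 mmHg outlier vanishes under the median
  out1 <- rep(0, 100); out1[40] <- 50
  bo <- baseline_offset(e + out1, e)
  expect_equal(bo$smoothed_offset, rep(0, 100))

  expect_error(baseline_offset(1:5, 1:4), "equal length")
})

test_that("MAP arithmetic and output ordering hold in extraction", {
  expect_equal(80 + (120 - 80) / 3, 93.333333333, tolerance = 1e-9)
  sim <- clean_sim(40, seed = 9)
  fit <- dtt_bp(sim$recording, cuff_120_80)
  bp <- fit$bp
  expect_equal(bp$MAP, bp$DBP + (bp$SBP - bp$DBP) / 3, tolerance = 1e-12)
  ok <- !bp$excluded
  expect_true(all(bp$DBP[ok] < bp$MAP[ok]))
  expect_true(all(bp$MAP[ok] < bp$SBP[ok]))
  expect_true(all(bp$HR[ok] > 0))
  # degenerate MAP limit
  expect_equal(100 + (100 - 100) / 3, 100)
})

test_that("calibration closure: mean eDBP of calibration beats equals DBP0", {
  sim <- clean_sim(60, hr = 60, sbp = 120, dbp = 80, seed = 1)
  beats <- delineate_beats(sim$recording)
  cal <- calibrate_m0(beats, cuff_120_80)
  edbp <- estimate_dbp(beats, cal, cuff_120_80)
  expect_lt(abs(mean(edbp[cal$cal_beats]) - 80), 1e-6)
})

test_that("drift that is constant within beats moves raw offsets exactly", {
  sim <- clean_sim(60, seed = 10)
  rec <- sim$recording
  beats <- delineate_beats(rec)
  cal <- calibrate_m0(beats, cuff_120_80)
  edbp <- estimate_dbp(beats, cal, cuff_120_80)
  raw_dbp <- cal$gain * beats$end_v + cal$offset
  base1 <- baseline_offset(raw_dbp, edbp)

  # add a per-beat-constant offset trace (in sensor units)
  set.seed(11)
  shift_mmHg <- stats::rnorm(nrow(beats), 0, 3)
  raw_dbp2 <- raw_dbp + shift_mmHg
  # DTT, C, PP are untouched by additive constants, so eDBP is unchanged
  base2 <- baseline_offset(raw_dbp2, edbp)
  expect_equal(base2$raw_offset - base1$raw_offset, shift_mmHg,
               tolerance = 1e-12)
})

test_that("baseline correction is idempotent", {
  # wander slow and gentle enough for the 30-beat median to model fully;
  # the residual a first pass cannot represent is what a second pass sees
  cfg <- sim_config(600, hr_bpm = 65, hrv_sd_s = 0, sbp_jitter_mmHg = 0,
                    dbp_jitter_mmHg = 0,
                    wander = list(model = "random_walk", amplitude = 0.15,
                                  corner_freq_Hz = 0.005),
                    sensor = list(gain = 0.05, offset = 1, noise_sd = 0),
                    seed = 12)
  sim <- simulate_recording(cfg)
  fit1 <- dtt_bp(sim$recording, cuff_120_80)
  corrected <- attr(fit1$bp, "corrected")
  corrected$units <- "sensor"
  fit2 <- dtt_bp(corrected, cuff_120_80)
  expect_lt(max(abs(fit2$baseline$smoothed_offset)), 1)
})

test_that("extracted DBP tracks the eDBP-anchored corrected trough", {
  cfg <- ramp_sim_config(13)
  sim <- simulate_recording(cfg)
  cuff <- cuff_from_truth(sim$truth)
  fit <- dtt_bp(sim$recording, cuff)
  raw_dbp <- fit$cal$gain * fit$beats$end_v + fit$cal$offset
  anchored <- raw_dbp - fit$baseline$smoothed_offset
  ok <- !fit$bp$excluded
  agree <- abs(fit$bp$DBP - anchored) <= 1
  expect_gte(mean(agree[ok]), 0.95)
})
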