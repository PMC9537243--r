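# Pulse-waveform simulator with known ground-truth hemodynamics.
#
# Each beat spans trough -> trough.  The systolic upstroke is a Gaussian
# edge of *fixed absolute width* (so the maximum upstroke slope, the
# contractility surrogate, is proportional to pulse amplitude), and the
# systolic decay — dicrotic notch, dicrotic wave and diastolic runoff — is a
# fixed shape stretched over the beat's diastolic transit time.  The DTT of
# each beat is generated from that beat's true DBP by inverting the linear
# single-point calibration model, so the synthetic waveform carries BP
# information in its intra-beat timing the way the estimator assumes real
# waveforms do.

# Normalised systolic-decay template on v in [0, 1]: value 1 at the peak
# (v = 0), strictly 0 at the diastolic trough (v = 1), with a dicrotic notch
# near v = 0.3 and a dicrotic wave near v = 0.45.  The linear runoff term
# keeps the approach to the trough strictly decreasing so the trough is a
# well-defined minimum.
pulse_decay_shape <- function(v) {
  raw <- exp(-(v / 0.18)^2) +
    0.25 * exp(-((v - 0.45) / 0.12)^2) +
    0.12 * (1 - v)
  norm <- 1 + 0.25 * exp(-(0.45 / 0.12)^2) + 0.12
  raw / norm
}

# Gaussian upstroke edge approaching the peak from the left; sigma_up is in
# seconds and fixed across beats, which makes max upstroke slope
# proportional to pulse amplitude.
pulse_upstroke_shape <- function(dt_to_peak, sigma_up) {
  exp(-(dt_to_peak / sigma_up)^2)
}

#' Motion-artifact event description
#'
#' @param kind `"impulse"` (raised-cosine transient), `"step"` (persistent
#'   offset with a smooth onset ramp) or `"cyclic"` (additive sinusoid with
#'   tapered edges, emulating walking-type cyclic motion).
#' @param t_start event onset in seconds (>= 0).
#' @param magnitude event amplitude in signal units.
#' @param duration_s event duration in seconds (> 0); for `"step"` this is
#'   the onset ramp length, after which the offset persists.
#' @param freq_Hz oscillation frequency, `"cyclic"` only.
#' @return An `artifact_event` list.
#' @export
artifact_event <- function(kind = c("impulse", "step", "cyclic"),
                           t_start, magnitude, duration_s, freq_Hz = NULL) {
  kind <- match.arg(kind)
  stopifnot(t_start >= 0, duration_s > 0)
  if (kind == "cyclic" && is.null(freq_Hz)) {
    stop("cyclic artifacts require `freq_Hz`")
  }
  structure(list(kind = kind, t_start = t_start, magnitude = magnitude,
                 duration_s = duration_s, freq_Hz = freq_Hz),
            class = "artifact_event")
}

#' Simulation configuration
#'
#' Bundles everything [simulate_recording()] needs: duration, sampling rate,
#' hemodynamic trajectories, beat-to-beat variability, baseline-wander
#' model, motion artifacts and the sensor transform.
#'
#' @param duration_s recording length in seconds (> 0).
#' @param fs sampling rate in Hz (>= 100; default 250).
#' @param hr_bpm heart-rate trajectory (bpm): a number or a trajectory spec.
#' @param sbp_mmHg,dbp_mmHg systolic/diastolic trajectories (mmHg); the SBP
#'   trajectory must exceed the DBP trajectory everywhere.
#' @param hrv_sd_s SD of Gaussian inter-beat-interval jitter in seconds.
#' @param sbp_jitter_mmHg,dbp_jitter_mmHg SD of per-beat Gaussian BP
#'   fluctuation around the trajectories (the source of genuine beat-to-beat
#'   BP variability in the synthetic data).
#' @param wander list: `model` (`"random_walk"` or `"sum_of_sinusoids"`),
#'   `amplitude` (SD of the injected trace, sensor units; 0 disables) and
#'   optional `corner_freq_Hz`.
#' @param artifacts list of [artifact_event()]s.
#' @param sensor list: `gain` (units/mmHg, > 0), `offset` (units),
#'   `noise_sd` (units of additive white Gaussian noise).
#' @param dtt_frac baseline diastolic transit time as a fraction of the
#'   inter-beat interval (default 0.6).
#' @param sigma_up_s width of the systolic upstroke edge in seconds.
#' @param seed integer seed; fixes every random element of the simulation.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(duration_s, fs = 250, hr_bpm = 70,
                       sbp_mmHg = 120, dbp_mmHg = 80,
                       hrv_sd_s = 0.02,
                       sbp_jitter_mmHg = 1.2, dbp_jitter_mmHg = 0.9,
                       wander = list(model = "random_walk", amplitude = 0),
                       artifacts = list(),
                       sensor = list(gain = 1, offset = 0, noise_sd = 0),
                       dtt_frac = 0.6, sigma_up_s = 0.07,
                       seed = 1L) {
  stopifnot(duration_s > 0, fs >= 100)
  sensor$gain <- sensor$gain %||% 1
  sensor$offset <- sensor$offset %||% 0
  sensor$noise_sd <- sensor$noise_sd %||% 0
  if (sensor$gain <= 0) stop("sensor gain must be > 0")
  cfg <- structure(
    list(duration_s = duration_s, fs = fs, hr_bpm = hr_bpm,
         sbp_mmHg = sbp_mmHg, dbp_mmHg = dbp_mmHg, hrv_sd_s = hrv_sd_s,
         sbp_jitter_mmHg = sbp_jitter_mmHg, dbp_jitter_mmHg = dbp_jitter_mmHg,
         wander = wander, artifacts = artifacts, sensor = sensor,
         dtt_frac = dtt_frac, sigma_up_s = sigma_up_s,
         seed = as.integer(seed)),
    class = "sim_config")
  tt <- seq(0, duration_s, length.out = max(64L, ceiling(duration_s)))
  s <- eval_trajectory(cfg$sbp_mmHg, tt, duration_s)
  d <- eval_trajectory(cfg$dbp_mmHg, tt, duration_s)
  if (any(s <= d)) {
    stop("invalid trajectories: SBP must exceed DBP at all times")
  }
  h <- eval_trajectory(cfg$hr_bpm, tt, duration_s)
  if (any(h <= 20 | h > 240)) stop("heart-rate trajectory outside 20-240 bpm")
  cfg
}

#' Simulate a pulse recording with ground truth
#'
#' Generates (i) a clean arterial-pressure carrier in mmHg (returned as the
#' `reference` channel, playing the role of an invasive arterial line),
#' (ii) the sensor-unit recording obtained by applying the affine sensor
#' transform, additive white noise, stochastic baseline wander and motion
#' artifacts, and (iii) per-beat ground truth.
#'
#' Identical configurations (including `seed`) give bit-identical output.
#'
#' @param config a [sim_config()].
#' @return A list with components:
#' \describe{
#'   \item{recording}{`waveform_recording` in sensor units (the device).}
#'   \item{reference}{clean `waveform_recording` in mmHg (the A-line).}
#'   \item{truth}{list with `beats` (data frame: `peak_t`, `trough_t`,
#'     `sbp`, `dbp`, `map`, `hr`, `ibi_s`, `dtt_s`) and `wander_trace`
#'     (per-sample injected offset, sensor units).}
#' }
#' @export
simulate_recording <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$fs
  dur <- config$duration_s
  n <- round(dur * fs)
  tgrid <- (seq_len(n) - 1L) / fs

  ref0 <- eval_trajectory(config$hr_bpm, 0, dur)
  S0 <- eval_trajectory(config$sbp_mmHg, 0, dur)
  D0 <- eval_trajectory(config$dbp_mmHg, 0, dur)
  PP0 <- S0 - D0
  ibi_ref <- 60 / ref0
  dtt0 <- config$dtt_frac * ibi_ref

  beats <- with_seed(config$seed + 11L, {
    t_on <- 0.2
    out <- vector("list", ceiling(dur * 4))
    k <- 0L
    while (TRUE) {
      hr_k <- eval_trajectory(config$hr_bpm, t_on, dur)
      ibi <- 60 / hr_k + stats::rnorm(1L, 0, config$hrv_sd_s)
      ibi <- clamp(ibi, 0.3, 2)
      t_end <- t_on + ibi
      if (t_end > dur - 1 / fs) break
      sbp_k <- eval_trajectory(config$sbp_mmHg, t_on + 0.4 * ibi, dur) +
        stats::rnorm(1L, 0, config$sbp_jitter_mmHg)
      dbp_k <- eval_trajectory(config$dbp_mmHg, t_end, dur) +
        stats::rnorm(1L, 0, config$dbp_jitter_mmHg)
      if (sbp_k - dbp_k < 5) sbp_k <- dbp_k + 5
      pp_k <- sbp_k - dbp_k
      # Invert the single-point calibration model: the intra-beat timing
      # carries the DBP information.
      dtt <- dtt0 * (S0 - dbp_k) * pp_k / PP0^2
      dtt <- clamp(dtt, 0.3 * ibi, 0.82 * ibi)
      k <- k + 1L
      out[[k]] <- c(t_on = t_on, t_end = t_end, ibi = ibi,
                    sbp = sbp_k, dbp = dbp_k, dtt = dtt)
      t_on <- t_end
    }
    do.call(rbind, out[seq_len(k)])
  })
  if (is.null(beats) || nrow(beats) < 2L) {
    stop("recording too short to contain beats")
  }
  nb <- nrow(beats)
  t_peak <- beats[, "t_end"] - beats[, "dtt"]

  # Piecewise-linear diastolic baseline: dbp of beat k is reached exactly at
  # that beat's end trough, keeping the carrier continuous across beats.
  knot_t <- c(0, beats[, "t_end"], dur)
  knot_v <- c(beats[1L, "dbp"], beats[, "dbp"], beats[nb, "dbp"])
  base <- stats::approx(knot_t, knot_v, xout = tgrid, rule = 2)$y

  clean <- base
  su <- config$sigma_up_s
  i_on <- pmax(1L, floor(beats[, "t_on"] * fs) + 1L)
  i_pk <- pmin(n, floor(t_peak * fs) + 1L)
  i_end <- pmin(n, floor(beats[, "t_end"] * fs) + 1L)
  pp <- beats[, "sbp"] - beats[, "dbp"]
  # Small linear pre-systolic foot (5% of pulse amplitude): the waveform
  # rises immediately after each diastolic trough, as real pulses do, which
  # pins the inter-beat minimum to the trough regardless of the slow
  # diastolic baseline slope.
  foot <- 0.05
  for (k in seq_len(nb)) {
    iu <- i_on[k]:i_pk[k]
    u_len <- max(t_peak[k] - beats[k, "t_on"], 2 / fs)
    clean[iu] <- clean[iu] + pp[k] *
      ((1 - foot) * pulse_upstroke_shape(tgrid[iu] - t_peak[k], su) +
         foot * clamp((tgrid[iu] - beats[k, "t_on"]) / u_len, 0, 1))
    if (i_end[k] > i_pk[k] + 1L) {
      id <- (i_pk[k] + 1L):(i_end[k] - 1L)
      v <- (tgrid[id] - t_peak[k]) / beats[k, "dtt"]
      clean[id] <- clean[id] + pp[k] * pulse_decay_shape(v)
    }
  }

  # Ground truth reflects the generated signal: true SBP is the carrier's
  # analytic peak value, true DBP the trough value.
  sbp_true <- base[i_pk] + pp
  dbp_true <- beats[, "dbp"]
  truth_beats <- data.frame(
    beat = seq_len(nb),
    peak_t = t_peak,
    trough_t = beats[, "t_end"],
    sbp = sbp_true,
    dbp = dbp_true,
    map = dbp_true + (sbp_true - dbp_true) / 3,
    hr = 60 / beats[, "ibi"],
    ibi_s = beats[, "ibi"],
    dtt_s = beats[, "dtt"])

  reference <- waveform_recording(clean, fs = fs, t0 = 0,
                                  channel = "aline", units = "mmHg")
  sensor <- sensor_transform(reference,
                             gain = config$sensor$gain,
                             offset = config$sensor$offset,
                             noise_sd = config$sensor$noise_sd,
                             seed = config$seed + 13L)
  sensor$channel <- "cap"
  wtr <- numeric(n)
  if (!is.null(config$wander) && (config$wander$amplitude %||% 0) > 0) {
    sensor <- inject_baseline_wander(sensor, config$wander,
                                     seed = config$seed + 17L)
    wtr <- attr(sensor, "wander_trace")
  }
  if (length(config$artifacts)) {
    sensor <- inject_motion_artifacts(sensor, config$artifacts)
  }
  list(recording = sensor, reference = reference,
       truth = list(beats = truth_beats, wander_trace = wtr))
}

#' Inject stochastic baseline wander
#'
#' Adds a seeded low-frequency offset trace to a recording.  Two models:
#' `"random_walk"` — white noise passed through two cascaded leaky
#' integrators (corner default 0.01 Hz), an integrated 1/f^2-type drift
#' emulating viscoelastic sensor creep; `"sum_of_sinusoids"` — random-phase
#' sinusoids below the corner (default 0.2 Hz), emulating respiratory-type
#' oscillation.  The trace is scaled so its SD equals `amplitude` and is
#' stored in the `"wander_trace"` attribute of the result, so
#' `out$samples - rec$samples` equals the trace exactly.
#'
#' @param rec a [waveform_recording()].
#' @param wander list with `model`, `amplitude` (trace SD, signal units)
#'   and optional `corner_freq_Hz`.
#' @param seed integer seed.
#' @return The recording with wander added; attribute `wander_trace` holds
#'   the injected per-sample offset.
#' @export
inject_baseline_wander <- function(rec, wander, seed = 1L) {
  stopifnot(inherits(rec, "waveform_recording"))
  amp <- wander$amplitude %||% 0
  if (amp < 0) stop("wander amplitude must be >= 0")
  n <- length(rec$samples)
  model <- wander$model %||% "random_walk"
  if (amp == 0) {
    attr(rec, "wander_trace") <- numeric(n)
    return(rec)
  }
  trace <- with_seed(seed, {
    if (model == "random_walk") {
      fc <- wander$corner_freq_Hz %||% 0.01
      a <- exp(-2 * pi * fc / rec$fs)
      x <- stats::rnorm(n)
      x <- stats::filter(x, a, method = "recursive")
      x <- as.numeric(stats::filter(x, a, method = "recursive"))
      x <- x - mean(x)
      s <- stats::sd(x)
      if (s > 0) x * (amp / s) else numeric(n)
    } else if (model == "sum_of_sinusoids") {
      fc <- wander$corner_freq_Hz %||% 0.2
      kk <- 8L
      freqs <- stats::runif(kk, 0.15 * fc, fc)
      phases <- stats::runif(kk, 0, 2 * pi)
      amps <- 1 / freqs
      tt <- rec_times(rec)
      x <- numeric(n)
      for (j in seq_len(kk)) {
        x <- x + amps[j] * sin(2 * pi * freqs[j] * tt + phases[j])
      }
      x <- x - mean(x)
      x * (amp / stats::sd(x))
    } else {
      stop("unknown wander model: ", model)
    }
  })
  rec$samples <- rec$samples + trace
  attr(rec, "wander_trace") <- trace
  rec
}

#' Inject motion artifacts
#'
#' Applies a list of [artifact_event()]s to a recording.  Impulses are
#' raised-cosine transients (smooth, band-limited, fully recoverable);
#' steps ramp up smoothly over `duration_s` and then persist; cyclic events
#' add a sinusoid with raised-cosine on/off tapers.  Samples outside all
#' events are untouched.
#'
#' @param rec a [waveform_recording()].
#' @param events list of [artifact_event()]s; all must start within the
#'   recording span.
#' @return The recording with artifacts applied.
#' @export
inject_motion_artifacts <- function(rec, events) {
  stopifnot(inherits(rec, "waveform_recording"))
  if (!length(events)) return(rec)
  tt <- rec_times(rec)
  t_max <- tt[length(tt)]
  x <- rec$samples
  for (ev in events) {
    stopifnot(inherits(ev, "artifact_event"))
    if (ev$t_start > t_max) {
      stop("artifact event starts beyond the end of the recording")
    }
    t1 <- ev$t_start
    t2 <- min(ev$t_start + ev$duration_s, t_max)
    idx <- which(tt >= t1 & tt <= t2)
    if (ev$kind == "impulse") {
      u <- (tt[idx] - t1) / ev$duration_s
      x[idx] <- x[idx] + ev$magnitude * 0.5 * (1 - cos(2 * pi * u))
    } else if (ev$kind == "step") {
      u <- (tt[idx] - t1) / ev$duration_s
      x[idx] <- x[idx] + ev$magnitude * 0.5 * (1 - cos(pi * u))
      after <- which(tt > t2)
      x[after] <- x[after] + ev$magnitude
    } else if (ev$kind == "cyclic") {
      u <- (tt[idx] - t1) / (t2 - t1)
      taper <- pmin(1, pmin(u, 1 - u) / 0.1)
      x[idx] <- x[idx] +
        ev$magnitude * taper * sin(2 * pi * ev$freq_Hz * (tt[idx] - t1))
    }
  }
  rec$samples <- x
  rec
}

#' Apply an affine sensor transform with additive noise
#'
#' `out = gain * in + offset + N(0, noise_sd)`; the unit flag of the result
#' is `"sensor"`, emulating the arbitrary-unit output of capacitive or
#' optical pulse sensors that later requires cuff calibration.
#'
#' @param rec a [waveform_recording()].
#' @param gain multiplicative gain in units/mmHg (> 0).
#' @param offset additive offset in sensor units.
#' @param noise_sd SD of additive white Gaussian noise in sensor units.
#' @param seed integer seed for the noise.
#' @return A `waveform_recording` in sensor units.
#' @export
sensor_transform <- function(rec, gain = 1, offset = 0, noise_sd = 0,
                             seed = 1L) {
  stopifnot(inherits(rec, "waveform_recording"))
  if (gain <= 0) stop("sensor gain must be > 0")
  x <- gain * rec$samples + offset
  if (noise_sd > 0) {
    x <- x + with_seed(seed, stats::rnorm(length(x), 0, noise_sd))
  }
  waveform_recording(x, fs = rec$fs, t0 = rec$t0, channel = rec$channel,
                     units = "sensor")
}

#' Ground-truth beats as a BP series
#'
#' Reshapes the simulator's ground truth into the same beat-indexed form
#' produced by the estimation pipeline, for pairing and agreement analysis.
#'
#' @param truth the `truth` component returned by [simulate_recording()].
#' @return A `bp_series` data frame (`t`, `SBP`, `DBP`, `MAP`, `HR`,
#'   `eDBP = NA`, `excluded = FALSE`).
#' @export
truth_bp_series <- function(truth) {
  b <- truth$beats
  out <- data.frame(t = b$peak_t, SBP = b$sbp, DBP = b$dbp, MAP = b$map,
                    HR = b$hr, eDBP = NA_real_, excluded = FALSE)
  class(out) <- c("bp_series", "data.frame")
  out
}
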