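# Shared fixture builders: everything is generated in code at test time.

# Stationary, jitter-free, noise-free simulation: every beat identical.
clean_sim <- function(duration_s = 60, hr = 60, sbp = 120, dbp = 80,
                      fs = 250, seed = 1L, ...) {
  simulate_recording(sim_config(
    duration_s, fs = fs, hr_bpm = hr, sbp_mmHg = sbp, dbp_mmHg = dbp,
    hrv_sd_s = 0, sbp_jitter_mmHg = 0, dbp_jitter_mmHg = 0,
    seed = seed, ...))
}

# Minimal hand-built beat feature table for engine-level arithmetic tests.
make_beats <- function(n = 5, peak_v = 3, onset_v = 1, end_v = 1,
                       dtt_s = 0.7, c_slope = 10, ibi_s = 1,
                       t_start = 1) {
  rep_out <- function(x) rep_len(x, n)
  peak_t <- t_start + (seq_len(n) - 1) * ibi_s
  out <- data.frame(
    beat = seq_len(n),
    onset_t = peak_t - 0.3, peak_t = peak_t, notch_t = NA_real_,
    end_t = peak_t + rep_out(dtt_s),
    onset_v = rep_out(onset_v), peak_v = rep_out(peak_v),
    end_v = rep_out(end_v),
    dtt_s = rep_out(dtt_s), c_slope = rep_out(c_slope),
    pp_s = rep_out(peak_v) - rep_out(onset_v),
    ibi_s = rep_out(ibi_s), hr_bpm = 60 / rep_out(ibi_s),
    valid = TRUE,
    onset_idx = 1L, peak_idx = 2L, end_idx = 3L)
  class(out) <- c("beat_feature_table", "data.frame")
  out
}

# Power fraction of a trace below a cutoff frequency (periodogram oracle).
power_below <- function(x, fs, f_cut) {
  x <- x - mean(x)
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  half <- 2:(floor(n / 2) + 1L)
  freqs <- (half - 1L) / n * fs
  sum(p[half][freqs <= f_cut]) / sum(p[half])
}

# Comparator-ordering replicate: a labile +20 mmHg SBP / +10 mmHg DBP ramp
# over two minutes of a 300 s recording with random-walk wander.
ramp_sim_config <- function(seed, gain = 0.05, S0 = 120, D0 = 80) {
  sim_config(300, fs = 250, hr_bpm = 75,
             sbp_mmHg = traj_piecewise(c(0, .2, .6, 1), c(S0, S0, S0 + 20, S0 + 20)),
             dbp_mmHg = traj_piecewise(c(0, .2, .6, 1), c(D0, D0, D0 + 10, D0 + 10)),
             wander = list(model = "random_walk", amplitude = gain * (S0 - D0),
                           corner_freq_Hz = 0.01),
             sensor = list(gain = gain, offset = 2,
                           noise_sd = 0.005 * gain * (S0 - D0)),
             seed = seed)
}
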