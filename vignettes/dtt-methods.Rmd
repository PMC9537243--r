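---
title: "Estimating beat-to-beat blood pressure from a single pulse waveform: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating beat-to-beat blood pressure from a single pulse waveform: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dttbp)
```

## The problem

Continuous non-invasive blood pressure (CNIBP) monitoring with wearable
pulse sensors — capacitive pressure (CAP) sensors, tonometers,
photoplethysmographs (PPG) — is limited by two chronic nuisances: slow
stochastic baseline wander (respiration, viscoelastic sensor creep,
contact-pressure drift) and motion artifacts.  Frequency-domain fixes
(high-pass or band-pass filtering, wavelet detrending) cannot distinguish
artificial drift from genuine slow physiological changes in blood
pressure, so they track hemodynamic excursions poorly.  Multi-sensor
timing features (pulse transit time, pulse arrival time) avoid the
amplitude problem but need two synchronised devices.

This package implements a single-sensor alternative built on an
*intra-beat* timing feature, the **diastolic transit time (DTT)**: the
interval from a beat's systolic peak to the diastolic trough that
terminates it.  Because DTT and the other per-beat quantities used by the
estimator are differences *within* one beat, an additive offset that is
approximately constant over a beat — which is what sub-0.2 Hz wander looks
like at heart rates of 1 Hz and above — cancels out of them exactly.

## The estimation model

With one initial cuff reading (SBP₀, DBP₀, pulse pressure
PP₀ = SBP₀ − DBP₀), beat-to-beat diastolic pressure is estimated as

$$\widehat{\mathrm{DBP}}(i) \;=\; \mathrm{SBP}_0 \;-\;
  m_0 \, \mathrm{DTT}(i) \left( \frac{C(i)}{C_0} \right)^{-1}$$

where $C(i)$ is the beat's *contractility* — the maximum of the first
derivative of the systolic upstroke — and $C_0$ its mean over the
calibration beats.  The contractility ratio adjusts for stress- or
drug-induced changes in left-ventricular dynamics that reshape the beat.
The calibration factor $m_0$ (mmHg/s) is the average over the first five
beats of

$$m_0 = \frac{1}{5} \sum_{i=1}^{5}
  \frac{\mathrm{PP}_0}{\mathrm{PP}_s(i)} \cdot
  \frac{\mathrm{SBP}_s(i) - \mathrm{DBP}_s(i+1)}{\mathrm{DTT}(i)}$$

with $\mathrm{PP}_s$, $\mathrm{SBP}_s$, $\mathrm{DBP}_s$ the sensor-unit
pulse pressure, peak and trough values.  The index convention deserves a
note: the trough written $\mathrm{DBP}_s(i+1)$ is the trough *following*
peak $i$ — the same trough that defines $\mathrm{DTT}(i)$.  This package
stores it as beat $i$'s own end trough (`end_v`); whether that trough is
bookkept with beat $i$ or $i+1$ has no numerical consequence, and the
convention used here makes each row of the beat table self-contained.

The raw-to-pressure map is affine, with gain
$\mathrm{PP}_0 / \overline{\mathrm{PP}_s}$ and offset chosen so the mean
calibration-beat trough maps exactly to DBP₀.  This anchoring makes the
calibration *closure* exact: on a stationary drift-free recording the
mean estimated DBP of the calibration beats reproduces DBP₀ to machine
precision (the estimator inverts the calibration identity).

Because $\widehat{\mathrm{DBP}}$ is wander-immune while the raw trough
pressure is not, their difference *is* the baseline wander sampled once
per beat.  That per-beat offset series is smoothed with a 30-point moving
median (robust to occasional corrupt beats), linearly interpolated across
samples (step interpolation would put discontinuities inside beats), and
subtracted from the raw pressure signal.  The corrected signal then
yields per-beat SBP (beat maximum), DBP (minimum between consecutive
peaks), MAP = DBP + (SBP − DBP)/3, and HR.  Beats deviating from their
own 30-point moving median of SBP or DBP by more than 10 mmHg are marked
excluded; the median filter is stated by the source method, the 10 mmHg
threshold is this package's choice of a conservative physiological bound
(a genuine beat-to-beat jump of that size at the beat scale is almost
always an artifact).

## Signal quality control

Two rules precede estimation.  A *continuity filter* keeps only beats in
maximal runs of valid beats spanning at least 30 s.  When a paired
reference channel is available, an *applanation test* looks for trends in
waveform amplitude that affect one channel only (the signature of sensor
contact-pressure drift): over 30 s sliding windows (5 s step), each
channel's contractility is normalised by its own window mean and
regressed on time, and the slopes are compared with the interaction
t-test of the pooled regression `lm(c_norm ~ t * channel)` — the ANCOVA
formulation, which shares the residual variance between channels.
Windows with p < 0.05 are excluded.  Mean-normalisation makes the test
exactly invariant to static channel gain.

Two interpretations were open here.  "Change in normalised contractility"
could mean first differences of the series; but differencing a linear
trend leaves a constant, destroying exactly the slope information the
test needs, so the level-on-time regression is used.  And in
single-sensor deployments the pairwise test has no reference to compare
against; the stage is then reported as not evaluable rather than silently
passed.

## The pulse-waveform simulator

The synthetic generator exists to exercise the whole pipeline against a
known ground truth.  Each beat spans trough → trough and is built from
three parts, all positive on the beat's interior so the three fiducials
(systolic peak, dicrotic notch, diastolic trough) are always present:

* a **systolic upstroke**: a Gaussian edge of fixed absolute width
  (σ = 70 ms).  Fixed width makes the maximum upstroke slope — the
  contractility surrogate — exactly proportional to pulse amplitude,
  so $C(i)/C_0 = \mathrm{PP}(i)/\mathrm{PP}_0$;
* a **systolic decay** stretched over the beat's DTT: a narrow Gaussian
  lobe, a dicrotic-wave Gaussian near 45% of the decay (leaving a
  dicrotic notch near 30%), and a linear diastolic runoff that keeps the
  approach to the trough strictly decreasing;
* a **pre-systolic foot** (5% of pulse amplitude, linear): the waveform
  starts rising immediately after each trough, as arterial pulses do.
  Without it the minimum between beats is set by the slope of the slow
  diastolic baseline and wanders ~100 ms around the true trough,
  destroying the timing feature the estimator reads.

The per-beat DTT is generated by inverting the estimation model: given
the true DBP trajectory,
$\mathrm{DTT}(i) = \mathrm{DTT}_0\,(S_0 - \mathrm{DBP}_i)\,
\mathrm{PP}_i / \mathrm{PP}_0^2$ with a baseline transit fraction of 0.6
of the inter-beat interval (clamped to [0.3, 0.82]).  This must be stated
plainly: *the simulator embeds the same intra-beat timing–pressure
relationship that the estimator inverts.*  Passing the end-to-end tests
therefore shows that the pipeline — delineation, calibration, wander
modelling, correction, extraction — recovers blood pressure whenever the
biomarker carries the information, with realistic noise, drift, artifacts
and quantisation in the way.  It cannot show that DTT is physiologically
informative in real arteries; only clinical recordings can do that.
Equally, features the generator does not emulate (reflected-wave
morphology changes, arrhythmic beats, probe repositioning) are outside
what the tests establish.

Two baseline-wander models are provided, both seeded and both scaled so
the injected trace's SD equals the requested amplitude:

* `random_walk` (default corner 0.01 Hz): white noise through two cascaded
  leaky integrators — an integrated, 1/f²-type drift whose power
  concentrates at the lowest frequencies, the signature of viscoelastic
  sensor creep.  A corner of 0.2 Hz would instead describe a broadband
  oscillation; creep is the mechanism being emulated, hence the low
  corner.
* `sum_of_sinusoids` (default corner 0.2 Hz): random-phase sinusoids
  below the corner, a respiratory-type oscillation.

Motion artifacts are raised-cosine impulses (smooth, band-limited,
recoverable), smoothly ramped persistent steps, and tapered additive
sinusoids for cyclic (walking-type) motion.  Per-beat Gaussian BP jitter
(defaults 1.2 / 0.9 mmHg for SBP / DBP, chosen to match short-term
beat-to-beat variability indices in the 1–1.5 mmHg range typical of
anesthetised adults) provides genuine BPV; inter-beat-interval jitter
defaults to 20 ms.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `n_cal_beats` | 5 | beats | beats averaged into m₀, C₀ and the affine anchor |
| `median_window` | 30 | beats | wander smoothing and outlier rejection window |
| `outlier_mmHg` | 10 | mmHg | exclusion threshold around the beat-series moving median |
| `min_run_s` | 30 | s | continuity filter minimum segment |
| `qc_window_s` / `qc_step_s` | 30 / 5 | s | applanation-test sliding window |
| `qc_alpha` | 0.05 | — | slope-difference significance level |
| `bpv_window_beats` | 30 | beats | BPV summary window (non-overlapping) |
| `bpv_labile_mmHg` | 10 | mmHg | per-window range beyond which BPV is not summarised |
| `dtt_frac` | 0.6 | — | simulator baseline DTT as a fraction of the beat |
| `sigma_up_s` | 0.07 | s | simulator upstroke width (sets contractility scale) |

The 30-beat median window bounds what the wander model can represent:
components with periods much shorter than ~30 beats (≈25–30 s) pass
through the correction untouched.  This is also why the idempotence
property (re-correcting an already corrected recording changes nothing)
holds for drift inside that band and cannot hold outside it — residual
fast wander looks the same to a second pass as it did to the first.

## Comparator methods

Three common alternatives are implemented for benchmarking, each feeding
the same cuff-anchored rescaling so the comparison isolates the
processing step:

* **BF** — zero-phase Chebyshev II band-pass, 0.5–10 Hz, 40 dB stopband.
  Realised as cascaded 4th-order high-pass and low-pass sections (a
  single band-pass polynomial at a normalised edge of 0.004 is
  numerically ill-conditioned), each applied forward–backward so beat
  timing is not shifted; the signal mean is removed first since the
  Chebyshev II stopband floor leaks DC at −40 dB.  Note that this design
  necessarily attenuates 1 Hz (power gain ≈ 0.49 after the zero-phase
  pass): a 4th-order filter with its stopband edge at 0.5 Hz is still in
  transition one octave up.  The cuff re-anchoring absorbs the scale
  loss; the tracking failure under genuine slow BP change remains.
* **DWT** — Daubechies-4 discrete wavelet transform to level 7;
  approximation coefficients multiplied by a reduction factor (default 0
  = removal) and the signal reconstructed.  Implemented in-package as an
  orthogonal periodized filter bank on a symmetrically extended signal,
  giving exact (≤ 1e−8) reconstruction at factor 1.  At 250 Hz the
  level-7 approximation spans roughly 0–1 Hz, so zeroing it removes
  drift *and* any genuine BP trend in that band.
* **STT** — slope transit time, PPₛ/C: the time to traverse the pulse
  amplitude at the maximum upstroke slope.  The source literature gives
  no BP mapping for it, so the DTT-analogous single-point calibration is
  used with STT in place of DTT — an interpretive choice, made so the
  comparison tests the feature rather than the calibration scheme.

## Variability and agreement statistics

BPV indices (SD, COV = SD/mean as a fraction, ARV = mean absolute
successive difference) are computed over non-overlapping 30-beat windows,
separately for SBP and DBP; windows whose own series ranges more than
10 mmHg are flagged labile and excluded from recording-level averages
(the per-series reading of the rule is this package's resolution of an
ambiguity — SBP windows are judged by SBP range, DBP by DBP).  The
sample (n−1) standard deviation is used throughout.

Agreement between an estimated and a reference series uses
nearest-in-time pairing within 0.5 s (half the one-second clock
synchronisation typical of clinical recordings, to avoid cross-beat
matches above 60 bpm), Pearson correlation, Bland–Altman mean bias with
68% and 95% limits of agreement, absolute percent errors, and the
AAMI/ISO 81060-2 verdict (|mean bias| ≤ 5 mmHg and SD < 8 mmHg).
Differences are `estimate − reference`; swapping the arguments negates
the bias and changes nothing else.  Equality of variability between two
sets of BPV values uses the Brown–Forsythe test (one-way ANOVA on
absolute deviations from group medians), implemented on base `stats` and
cross-checked in the test suite against `car::leveneTest(center = median)`.

## The synthetic validation study

`evaluate_study()` fixes the study conditions used by the package's tests
and reproduction script: twenty 20-minute recordings at 250 Hz, heart
rates drawn from 55–90 bpm with a slow drift, adult SBP/DBP baselines, a
ramp-and-step trajectory with excursions of at least 10% of baseline
(emulating drug- and stress-induced hemodynamic change), per-beat BP
jitter, and random-walk wander whose SD equals the sensor pulse
amplitude.  Each recording is processed with one initial cuff calibration
and no recalibration, and every corrected beat is compared with ground
truth.  The signal-integrity arm applies the pipeline to the clean
reference channel of the same simulations and compares windowed BPV
against truth — isolating what the algorithm does to variability from
what sensor noise does, the same design used to validate against clinical
gold standards.  The problem sizes (20 × 20 min ≈ 28,000 beats) keep the
full study under a minute of compute while estimating pooled bias and SD
to well under the bounds being checked.

## Numerical choices and degenerate inputs

* Derivatives: central differences after a 15 ms moving average; raw
  differences amplify noise, and wider smoothing measurably attenuates
  the upstroke-derivative maximum.
* Ties between equal-height maxima resolve to the earliest sample;
  fiducials carry sample resolution (≤ 4 ms at 250 Hz), with no
  sub-sample refinement.
* The contractility ratio in the estimator is clamped to [0.25, 4] to
  bound the leverage of derivative noise on single beats.
* The moving median shrinks its window at the series edges (output
  length equals input length); window 1 is the identity.
* Empty or constant signals yield empty beat tables with a warning, not
  errors; a cuff with SBP ≤ DBP, non-positive sensor gain, non-finite
  samples, or calibration beats with non-positive DTT or pulse pressure
  are rejected with errors.
* All randomness is seeded explicitly and restored afterwards; identical
  configurations reproduce recordings bit for bit.

## Known limitations

* The applanation QC test is pairwise by construction; single-sensor
  recordings get continuity filtering and outlier rejection only.
* The wander correction is blind to drift components faster than the
  30-beat median window; such components pass into the output (they are
  also where the estimator's per-beat noise lives).
* WFDB-format I/O is not provided; recordings are CSV with a JSON
  sidecar.
* The simulator's beat morphology is a three-component template, not a
  hemodynamic model; its DTT–DBP coupling is the estimator's own model
  inverted, with the interpretive consequences described above.
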