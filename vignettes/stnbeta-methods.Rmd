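---
title: "Methods: subthalamic beta-band LFP analysis with stnbeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subthalamic beta-band LFP analysis with stnbeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Excessive beta-band (13–35 Hz) synchronisation in the subthalamic nucleus
(STN) is a well-established electrophysiological correlate of parkinsonian
motor impairment, and beta power recorded by sensing-enabled deep brain
stimulation (DBS) devices is the leading candidate feedback signal for
closed-loop stimulation. Within the beta range, low beta (13–20 Hz) is
linked to the hypodopaminergic state, while high beta (20–35 Hz) behaves
more like physiological motor-circuit activity that desynchronises during
movement. `stnbeta` implements a complete, testable pipeline for studying
how movement, dopaminergic medication (M0/M1) and DBS (S0/S1) modulate
subthalamic beta activity in a four-condition within-patient design
(M0S0, M0S1, M1S0, M1S1): from raw bipolar LFP (250 Hz) and tri-axial
accelerometer traces (4 kHz) through artifact removal, Morlet
time-frequency decomposition, rest/movement spectral statistics with
cluster-based permutation inference, and mixed-effects prediction of motor
performance from beta power.

Because clinical STN recordings cannot be redistributed, the package ships
a first-class synthetic session generator with recorded ground truth, so
that every downstream stage is testable without any data download.

## Session model and paradigm

A session is one condition's recording: 60 s of rest followed by three
blocks of 10 s repetitive finger tapping, each followed by 10 s of rest
(120 s in total). The LFP and the accelerometer run on separate clocks; a
signed clock offset (accelerometer start minus LFP start) aligns them. All
annotations (block spans, tap times) live on the LFP time base.

## The synthetic generator

`generate_session()` synthesises a paired LFP + accelerometer session with
known ground truth. Design choices:

* **Aperiodic background**: Gaussian noise shaped in the frequency domain
  to $1/f^{\chi}$ power with exponent $\chi = 1.5$ (flat below 1 Hz to keep
  the variance finite), SD 1 in arbitrary amplifier units. A 1/f slope of
  1–2 is typical of macroelectrode LFP spectra.
* **Oscillatory peaks are stochastic, not sinusoidal**: each peak is
  narrow-band filtered noise with a Gaussian spectral profile
  (centre, FWHM, component RMS). Beta activity in STN LFPs is bursty;
  spectral tests must not be able to exploit phase coherence. Defaults: a
  dominant low-beta peak at 17.33 Hz (FWHM 4 Hz, RMS 0.6) — the
  across-hemisphere mean rest peak in the off-therapy state — and a weaker
  high-beta peak at 25 Hz (FWHM 5 Hz, RMS 0.42), giving peak-over-background
  spectral ratios of roughly 10× and 5×, consistent with recordings from
  contacts selected for a pronounced beta peak.
* **Condition effects** are multiplicative band-power factors applied to
  the whole neural spectrum: medication multiplies 13–20 Hz power by 0.5;
  DBS multiplies 13–35 Hz power by 0.6. These reproduce the qualitative
  pattern of a low-beta-selective medication effect and a broadband DBS
  effect; the magnitudes are free parameters of the generator (no
  per-frequency effect sizes are available to calibrate against).
* **Movement modulation**: the signal is split (in the frequency domain)
  into the suppression band and the remainder; the in-band part is
  multiplied by $\sqrt{1 - s}$ during tapping blocks ($s$ = suppression
  fraction, default 0.5), with 0.25 s cosine ramps — the down-ramp precedes
  the block onset, as movement-related desynchronisation begins before
  movement, so every tap epoch sits at the suppressed level — and by
  $\sqrt{1 + r}$ for 1 s after each block ($r$ = rebound fraction, default
  0.2) to emulate the post-movement beta overshoot. Suppression bands
  default to 18–28 Hz in M0S0, 8–35 Hz in M1S0 and 5–35 Hz with DBS,
  mirroring the broadening of movement-related desynchronisation under
  therapy.
* **Cardiac contamination**: Mexican-hat (Ricker) biphasic complexes at
  70 bpm (inter-beat jitter SD 20 ms), width 120 ms, peak amplitude 4.
  With this width the artifact's energy concentrates near 5–15 Hz — the
  typical appearance of device-filtered ECG in implanted-system recordings —
  and contributes only a few percent of 13–35 Hz power, so cleaning quality
  can be assessed separately from beta estimation.
* **Line noise**: a 50 Hz sinusoid of amplitude 0.5 with random phase.
* **Taps**: each tap is a biphasic "double sinusoidal" pulse of width
  205.4 ms (the mean full-tap duration) with a faster, stronger opening
  lobe (peak 10 m/s², peaking at 20% of the tap) and a slower closing lobe
  at 70% amplitude; this asymmetry is what allows the analysis side to
  orient the principal axis. Taps are projected on three axes with fixed
  weights plus white noise (SD 0.3 m/s²); `round(tap_rate × 10)` taps per
  block, with per-condition rates 1.31 / 2.13 / 2.32 / 3.17 taps/s
  (off-therapy through combined-therapy means).
* **Hemisphere heterogeneity** (`draw_hemisphere_config()`): peak centres
  jittered with SD 2.31 Hz (the reported across-STN spread), log-normal
  amplitude (sdlog 0.2) and background (sdlog 0.1) factors, and a
  hemisphere-level tap-rate shift (SD 0.3 Hz). The drawn configuration is
  shared across the four conditions of a hemisphere, preserving the paired
  design.
* **Randomness**: one integer master seed; every component (background,
  each peak, ECG, line phase, offsets, noise) draws from a stream derived
  deterministically from the seed and a component label, so sessions are
  bit-reproducible and components are independently controllable.

What the generator does **not** emulate: tremor or dyskinesia artifacts
(tremor-dominant patients are excluded from this paradigm), stimulation
pulse artifacts (at 130 Hz they lie above the analysed 1–90 Hz range),
non-stationary beta bursts with realistic duration statistics, and
electrode-impedance drift. Passing tests therefore demonstrate correctness
of the pipeline's algorithms under the stated statistical structure, not
robustness to every artifact class of real recordings.

## Preprocessing

* `bandpass_lfp()`: zero-phase Butterworth high-pass at 5 Hz and low-pass
  at 90 Hz (order 4 each, forward–backward). Corners are placed in the
  bilinear-warped domain so the *combined* two-pass response is −3 dB at
  the nominal frequencies. Forward–backward filtering is used everywhere in
  offline analysis so that epochs are not time-shifted; ends are padded by
  odd reflection so edge transients decay outside the data.
* `notch_line()`: zero-phase Butterworth band-stop at 48–52 Hz.
* `detect_r_peaks()`: the cardiac complex is emphasised with a 6–12 Hz
  zero-phase band-pass — chosen because the smooth, device-filtered QRS
  complexes this pipeline targets carry their energy there, while beta
  oscillations contribute little — then squared; candidate peaks are local
  maxima above median + 4 MAD with ≥ 0.4 s separation. Candidates are
  screened for cardiac plausibility: heights ≥ 25% of the robust beat
  level, a neighbour within 1.5 s, and a regular rhythm (robust CV of
  inter-beat intervals ≤ 0.2). An implausible train returns an empty
  annotation with a warning rather than fabricating beats.
* `subtract_ecg_template()`: epochs ±200 ms around each R-peak; the
  pointwise average of all complete epochs is the template, subtracted from
  every epoch in place; samples outside epochs are untouched. The cleaning
  report quantifies cardiac-comb power (periodogram power at harmonics of
  the beat frequency in excess of the locally interpolated background)
  and 13–35 Hz power before/after, and grades severity ("not present" /
  "not severe" / "severe") by the artifact-to-beta power ratio
  (thresholds 0.1 and 0.75; configurable, calibrated only on synthetic
  data). By default (`ecg_clean = "auto"`) the subtraction is kept whenever
  an artifact is detected at all; whether cleaning should be restricted to
  severe cases is exposed as a policy option since practice varies.

## Time-frequency decomposition and spectra

* `morlet_tf()`: complex Morlet wavelets with 8 cycles per frequency, 1 Hz
  steps over 1–90 Hz, implemented as an analytic Gaussian filter bank in
  the frequency domain (the exact Fourier transform of the Morlet wavelet)
  with unit gain at each centre frequency — a unit-amplitude sine yields
  power 1 at its frequency. Power is bin-averaged onto a 20 Hz time grid.
  The signal is reflection-padded; samples within half a wavelet
  ($n_{cycles}/2f$ seconds) of either end are flagged invalid per
  frequency.
* `normalize_sum_rescale()`: every time slice is divided by its summed
  53–90 Hz power, which removes electrode-impedance/SNR differences
  between hemispheres; afterwards the reference-band sum is exactly 1, and
  the whole spectral path is invariant to broadband gain to machine
  precision.
* `rest_spectrum()`: the average over the first 30 s of movement-free,
  edge-valid time inside the 60 s rest window (the choice "first valid
  30 s" is one of several defensible readings; it is the default and
  configurable).
* `movement_spectrum()`: the average over the union of per-tap epochs
  (each centred on an opening peak, one tap-duration wide, merged when
  overlapping), per frequency over edge-valid samples — inter-tap pauses
  and the post-movement rebound are deliberately excluded.
* `find_beta_peak()`: the rest peak is the largest point of
  background-detrended log power in 10–35 Hz, where the background is a
  log–log linear fit over 5–45 Hz excluding 10–35 Hz. Detrending prevents
  the 1/f slope from dragging the argmax to the band edge; ties break
  toward the lower frequency; if nothing rises ≥ 0.1 log units above the
  fit, the result is flagged `no_peak` (with the band minimum returned).
* `band_power()`: low beta is averaged over [13, 20) Hz and high beta
  over [20, 35] Hz, so the 20 Hz bin is counted exactly once (in high
  beta).

## Movement metrics

The prepared accelerometer (anti-alias low-passed via a zero-phase
Blackman-windowed-sinc filter, decimated to 250 Hz, 1 Hz high-passed) is
projected onto its first principal component over the tapping blocks; the
sign is chosen so the (sharper, larger) opening accelerations are positive,
using the skewness of the in-block signal. Opening peaks are local maxima
above a prominence threshold — by default the larger of 5× the MAD of the
rest-period signal and 40% of the in-block 99.5th percentile, which adapts
to sensor noise without being inflated when taps occupy most of a block —
with ≥ 150 ms separation. The closing peak is the most negative sample
before the next opening peak; the tap end is the next zero-crossing. Tap
duration runs from the zero-crossing preceding the opening peak (default;
the opening peak itself is the configurable alternative) to the tap end.
Per-block metrics are the tap count, tapping frequency (count divided by
the 10 s block duration — the quantity tabulated in Hz in this design) and
mean opening-peak acceleration, averaged over the three blocks per
condition.

## Statistics

* `paired_permutation_test()`: statistic mean(a − b); the null is built by
  sign-flipping within-pair differences (the hemisphere is the
  exchangeability unit). With $2^n$ ≤ the permutation budget all patterns
  are enumerated and the p-value is exact; otherwise the Monte-Carlo
  p-value includes the observed statistic (+1 convention), so it is never
  zero.
* `cluster_permutation_spectra()`: per-bin paired t statistics; bins with
  |t| above the two-sided α = 0.05 critical value (df = n − 1) form
  contiguous candidate clusters; the cluster mass is the summed |t|; the
  null is the maximal cluster mass under random sign flips, which controls
  the family-wise error across the strongly dependent neighbouring
  frequency bins. The cluster-forming threshold and tested range
  (default 1–35 Hz) are configurable. All clusters are reported with their
  p-values; labelling trends (e.g. p ≈ 0.06) is left to the user. No
  correction is applied across the six condition contrasts, matching
  common practice of reporting uncorrected pairwise p-values in this
  design.
* `fit_power_performance_lme()`: tapping frequency ~ log(beta power) with
  a random intercept per hemisphere and a single fixed slope (lme4, with
  Satterthwaite p-values via lmerTest). Beta power enters on the log scale
  because its distribution is right-skewed (the Lilliefors test,
  `lilliefors_test()`, is provided to check this on data). Reported:
  slope ("CoE"), its p, BIC, and the Spearman correlation between fitted
  and observed responses. A failed mixed fit falls back to pooled
  regression with a warning. Hemispheres are treated as independent units,
  matching the per-STN analysis of this design; a patient-level grouping
  can be supplied instead via the `group` argument.

## Study orchestration

`run_study()` simulates H hemispheres × 4 conditions (default H = 12, the
number of analysed STNs in the motivating design), processes every session,
and produces: the behavioural table, per-condition rest and movement
spectra, the beta-peak table, six pairwise behavioural permutation tests,
cluster contrasts for all six condition pairs in both states, rest-vs-
movement desynchronisation contrasts per condition, and four mixed-model
fits (low/high beta × rest/movement). Everything derives from one master
seed; re-running with the same configuration reproduces the report
bit-identically, and the config hash and seed are embedded in all outputs.

## Validation suite and problem sizes

The `assess_*()` functions re-measure the pipeline's statistical properties
from scratch on synthetic data; `scripts/acceptance.R` runs them and writes
the results as JSON. Chosen problem sizes (the package's own choices,
balancing Monte-Carlo error against desk-scale runtimes): 500 null datasets
× 500 permutations for the cluster test's family-wise error; 50 replicate
studies of 12 hemispheres for effect-pattern recovery; 100 sessions for
beta-peak recovery; 100 runs for tap-count robustness; 200 replicates for
mixed-model CI coverage. Two measurement points deserve comment:

* *Effect-pattern recovery* uses the full waveform pipeline. The 8-cycle
  wavelet has a spectral bandwidth of σ = f/8 (≈ 2.5–3 Hz across the beta
  band), so a band-edged generator effect (e.g. low beta × 0.5 ending
  sharply at 20 Hz) produces a real, measurable power difference 2–4 Hz
  above the band edge. With 30 s of clean stationary rest data per
  condition this leakage is large relative to the estimation noise, and
  the detected medication cluster can extend a few hertz beyond 22 Hz —
  a property of the measurement kernel, not an error of the cluster test
  (at the spectrum level, where no kernel is involved, the same contrast
  localises to the band; see the stats tests).
* *Desynchronisation recovery* places the oscillatory peak inside the
  suppressed band, because the band-power ratio otherwise mixes in wavelet
  leakage from an unsuppressed neighbouring peak and no longer measures
  the generator's suppression fraction.

## Known limitations

Phenomenological generation only — no basal-ganglia circuit model; no
automatic clock-offset estimation (the offset is declared, standing in for
an external synchronisation device); the ECG severity thresholds are
calibrated only on synthetic data; cluster inference assumes exchangeable
hemispheres under the null (patients contributing two hemispheres are
treated as independent units, as in the motivating per-STN design).
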