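---
title: "Models, parameters and design choices in swaepi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and design choices in swaepi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and conventions

`swaepi` quantifies cortical excitability phenotypes in paired-hemisphere
recordings: slow-wave activity (SWA) and its up/down-state structure,
two epileptiform signatures (beta-band bursts and brief hypersynchronous
discharges), a spectral excitation:inhibition proxy, multi-unit activity,
calcium-transient statistics, and sleep-state coupling. Time is continuous
seconds from recording start; all intervals are half-open `[t_start,
t_end)` so shared boundaries are never double-counted; event membership in
an interval set is decided by the event peak time alone. All statistical
tests are two-sided; the paired Wilcoxon drops zero differences and
reports the effective n.

# Signal processing

**Zero-phase filtering.** No time-domain IIR filter toolbox is assumed.
`bandpass()` applies the magnitude response of an order-4 Butterworth
band-pass (−3 dB corners) in the frequency domain with reflect padding.
A real, symmetric transfer function has exactly zero phase, which the
transition-slope metrics require, and the −3 dB convention keeps the
equivalent noise bandwidth of the band at its nominal width (a
forward–backward squared response would shrink it to ~77 %, breaking the
flat-spectrum variance identity used in the tests).

**Welch spectra** use 4 s Hann segments with 50 % overlap and per-segment
mean removal, resolving the 0.5 Hz lower edge of the delta band and
satisfying Parseval within a few percent for stationary input. The
interhemispheric `cross_spectrum()` averages the complex cross density
coherently over segments drawn only from the supplied windows, so
incoherent channels decay toward zero while a shared carrier survives.

**Spectral exponent.** `fit_spectral_exponent()` fits `log10(power)`
against frequency (`semilog_exponential`, exponent in 1/Hz) or against
`log10(frequency)` (`loglog_powerlaw`, dimensionless) over 1–50 Hz with a
45–55 Hz notch. Both models are first-class because the field uses both
conventions and the underlying report is ambiguous; the semilog model is
the default for reporting, while the direction tests use the power-law
model, which targets the generator's `1/f^chi` exponent directly and
separates conditions with far less variance. A flatter spectrum (smaller
exponent) is read as a relatively higher excitation:inhibition ratio.

# Up/down-state segmentation

States are detected on the z-like normalized 0.1–8 Hz trace. Three
choices matter and all were validated against generator ground truth:

1. **Band.** The conventional delta band (0.5–4 Hz) removes the sub-0.5 Hz
   content that encodes the up/down duty-cycle asymmetry; after such a
   high-pass, symmetric thresholds bias the detected duty cycle toward
   0.5. The default boundary band is therefore 0.1–8 Hz (slope metrics
   still use 0.5–4 Hz).
2. **Normalization.** Mean/SD z-scores shift with the duty cycle itself.
   The trace is instead centered on the midpoint of its 10th/90th
   amplitude percentiles and scaled by their half-spread, which places the
   hysteresis thresholds (±0.3) between the two modes of the bimodal
   amplitude distribution regardless of occupancy.
3. **Boundary refinement.** Hysteresis crossings confirm a transition but
   fire late on the low-pass-smoothed ramp. Each boundary is pulled back
   to the preceding midpoint crossing and then to the extremum of the
   smoothed derivative (the inflection point), which for a zero-phase
   filtered ramp sits at the true transition. Residual boundary bias is
   ~1 ms on synthetic ground truth; interval intersection-over-union is
   0.93–0.97.

Minimal durations are 0.15 s (up) and 0.05 s (down, also the merge gap);
with gamma-distributed dwell times a 0.3 s minimum would discard over a
fifth of genuine up states. Polarity is auto-selected by gamma-band
(40–100 Hz) power inside candidate up states, since up states carry the
high-frequency activity; electrode depth and referencing can flip the raw
sign. Per-animal slope summaries are means over up states.

# Event detectors

**Beta bursts** (9–25 Hz) are supra-threshold runs of the smoothed
analytic-signal envelope. The decision threshold is 5 MAD units above a
60 s running median of the envelope: an envelope has heavier-than-Gaussian
tails (3 MAD admits noise runs), and chronic EEG background is
state-dependent, which a running median absorbs. Burst boundaries are then
extended outward to a lower threshold (1 MAD) — the classic two-threshold
scheme — which brings detected durations within ~15 % of the injected
ones instead of clipping the envelope tails. An order-8 band edge plus a
*theta guard* (reject candidates whose excess 5–9 Hz envelope exceeds half
the beta envelope) eliminates REM-theta masquerading as beta bursts while
leaving slow-wave recordings untouched.

**Hypersynchronous spikes** are detected on a 0.05–40 Hz trace: a ~0.2 s
monophasic discharge holds a large fraction of its energy below 1 Hz, and
a 1 Hz corner erodes its peak and width beyond recovery. The threshold is
`max(0.3 mV, 6 robust-z)` with the noise scale taken from a 4–40 Hz
reference band (above the slow oscillation). The amplitude is the signed
peak relative to a pre-event flank baseline (the rise is fast but the
decay is slow, so only the left flank is clean); boundaries sit at 25 % of
the corrected peak, walked outward until a sustained (≥ 20 ms) sub-level
run. Accepted events must satisfy duration bounds (0.05–0.5 s), a 0.5 s
dead time, and a sharpness criterion (max slope ≥ 20 × amplitude per
second): deep down states of comparable amplitude evolve on the slow-wave
time scale, several-fold slower than a discharge, and are rejected.

**Phase locking** is the fraction of event peaks inside the contralateral
hemisphere's up states, with the up-state duty cycle as the chance level;
across animals a one-sample t test compares per-animal fractions to their
chance levels. Phenotype calls use strict thresholds: frequent bursts
above 3/h, hyperexcitable above 5/h.

**Multi-unit activity** uses the classic robust rule: high-pass above
300 Hz, noise scale `median(|x|)/0.6745`, negative threshold at −4 sigma,
spike time at the local trough, 1 ms dead time. The threshold is
scale-equivariant by construction.

**Calcium transients.** dF/F uses a running 10th-percentile baseline
(30 s window) — low enough that the sustained pedestal of very active
neurons is not absorbed into F0 — and detection works on the
median-centered trace with a noise scale from the first difference
(`MAD(diff)/sqrt(2)`), which a heavy signal load cannot inflate. An onset
requires exceeding `3 sigma` *and* rising `3 sigma` above the running
minimum since the last event, sustained for 0.2 s at that level; the event
ends when dF/F falls below `max(1 sigma, 50 % of the event peak)`, and
detection is refractory until then (kernels 0.5 s apart merge; the
relative end keeps the refractory period short enough that rates up to
~18/min remain countable, where a pure noise-level end criterion would
halve them). Onsets are refined back to the start of the rise. "Active"
means ≥ 1 detected transient; frequency statistics are over active
neurons; the hyperactive percentage (> 4/min, strict) is over all analyzed
neurons.

**Sleep scoring** is per 4 s epoch: Wake when the EMG RMS exceeds the
midpoint of its 10th/90th per-epoch percentiles (occupancy-robust, with a
flat-EMG guard that scores everything as sleep when no wake cluster
exists — a deviation from a fixed 60th-percentile rule, which breaks
whenever wake occupancy strays from 40 %); otherwise NREM when
delta/total RMS > 0.45; otherwise REM when theta/delta > 1; otherwise
NREM; then a 3-epoch majority filter. Epoch accuracy on synthetic ground
truth is ~0.95–0.99.

# The synthetic world

The generator is a stated world, not a tuning knob: its defaults encode
the phenotype statistics the pipeline must recover blind, and everything
else is chosen once at physiologically sensible values.

- **States:** gamma dwell times, up 0.5 s and down 0.3 s means (shape 4) —
  urethane-typical; the source data never report dwell statistics.
- **LFP:** logistic up/down transitions (time constant 20 ms control;
  the mosaic injected channel doubles it and scales the 0.3 mV swing by
  0.6), `1/f^2` background (1.6 in the mosaic channel) of 0.05 mV RMS
  with a 0.01 mV white floor, gamma noise (0.03 mV RMS) gated to up
  states, and biphasic unit waveforms (1 ms, 0.08 mV — extracellular
  spikes of realistic SNR) at 30 Hz in up states vs 0.5 Hz in down states
  (18 Hz / 1.5 Hz mosaic).
- **Events:** beta bursts as Hann-enveloped 15 Hz carriers (lognormal
  ~1.5 s), and hypersynchronous events as difference-of-exponential
  templates with 0.49 mV peak and 0.23 s width at 25 % of peak. A
  discharge locally *replaces* the ongoing slow oscillation (raised-cosine
  cross-fade): population discharges interrupt SWA rather than sum with
  it, and without this the ±0.15 mV state level would bias every
  amplitude measurement.
- **Coupling semantics:** an event lands inside the coupled interval set
  (contralateral up states, probability 0.81; NREM epochs, 0.87) and
  uniformly in the complement otherwise, so the measured in-set fraction
  recovers the configured probability directly. `p = NA` places events
  uniformly and is the "chance" configuration.
- **Calcium:** per-neuron rates from a lognormal whose sdlog comes in
  closed form from the median (0.018 Hz) and the target tail above 4/min
  (7.8 % control, 26.1 % mosaic). Rates are drawn by stratified quantile
  sampling (one draw per 1/n probability stratum, shuffled), so a field of
  300 neurons is exactly representative of the configured distribution —
  plain iid sampling leaves the realized tail with a ±2.5-point binomial
  SD, larger than the recovery tolerance itself. Rates are capped at
  0.3 Hz: faster somatic calcium events are unphysiological and not
  resolvable as discrete transients; the cap changes neither the median
  nor the > 4/min tail. Kernels rise in 0.1 s and decay in 1 s; dF/F
  amplitude 0.3 on 0.06 noise (SNR 5).
- **EEG/EMG:** Wake/NREM/REM cycling with gamma dwells (means 240/300/60 s,
  i.e. 40/50/10 % occupancy), NREM delta-dominant, REM theta-dominant
  (6–9 Hz, synthesized with steep band edges so declared bands are
  honored), Wake low-amplitude broadband; EMG variance high in Wake only.
- **Inhibition surrogate:** `background$gaba_rms > 0` adds a steep
  (`1/f^3`) component flattened below 1 Hz, i.e. extra power concentrated
  inside the 1–50 Hz fit band, which raises the fitted exponent — the
  expected signature of increased tonic inhibition.

Everything is deterministic under `(seed, config)`; ground truth records
every state interval, event time and coupling draw.

# What a green test does and does not establish

The synthetic world contains no movement or electrode artifacts, no line
noise, no electrode drift, no spike-waveform diversity (multi-unit only,
by design), no motion or neuropil contamination in the imaging channel,
and stationary state statistics. Green recovery tests therefore establish
that the estimators are correct and calibrated *given* the declared signal
model — not that they are robust to every pathology of real recordings.
The artifact-exclusion hook (`exclude` mask in `extract_units()`, optional
RMS windows) exists but no exclusion is applied by default, matching the
unstated preprocessing of the reference analyses.

Known limitations: the burst and spike detectors share a recording-wide
threshold (within-recording nonstationarity beyond the 60 s running median
is not tracked); transient detection is threshold-based, not
deconvolution, so rates well above ~18/min saturate; the sleep scorer
knows only three states and no artifact epochs; true ictal events are out
of scope.
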