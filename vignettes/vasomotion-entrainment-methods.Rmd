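---
title: "Methods: quantifying vasomotion and its visual entrainment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying vasomotion and its visual entrainment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasoentrain)
```

## The problem

Cerebral vessels dilate and constrict spontaneously on a seconds time
scale (vasomotion, ~0.1 Hz), and this rhythm can be entrained by a slow
oscillating visual stimulus (0.25 Hz in the standard protocol used here).
The package implements the full measurement chain for this phenomenon
from three kinds of raw data:

* **vessel image stacks** (wide-field fluorescence of a dye-filled
  vessel), from which a diameter index and a peak-intensity series are
  read out;
* **fluorescence traces** (photometry or ROI means), on which entrainment
  is quantified spectrally;
* **eye-angle traces**, from which the optokinetic (HOKR) tracking gain
  and phase are measured.

Because the corresponding in-vivo recordings cannot be regenerated at a
desk, every input has a synthetic counterpart with stored ground truth,
and all validation in `tests/` runs against those generators.

## Vessel diameter: the FW10M index

Wide-field imaging gives no optical section, so a vessel's cross-section
profile is the projection of a fluorophore-filled cylinder: column depth
at lateral offset $x$ is $d\sqrt{1-(2x/d)^2}$ for diameter $d$. The
profile therefore has no sharp edge, and the full width at 10% of the
profile maximum (FW10M) is used as the diameter index. For the ideal
projected cylinder the closed form is

$$\mathrm{FW10M} = d\,\sqrt{1 - 0.1^2} = \sqrt{0.99}\,d \approx 0.995\,d,$$

which both anchors the unit tests and provides the bias correction used
when absolute diameters are reported. The processing chain mirrors
standard practice: per-frame scalar background subtraction from two
flank ROIs; a fade baseline from an in-vessel ROI (below); per-frame
division by that baseline; row-averaged cross-section profiles, Gaussian
smoothing along position (default $\sigma$ = 1 px; the near-no-op value
0.05 px remains available), and a slope-flattening step that subtracts
the line through the two flank means (the two sides of a vessel often
sit at different background levels). Threshold crossings are located by
linear interpolation, using the outermost crossings when noise creates
several.

Choices worth knowing about:

* **Basal phase.** "Undilated" is operationalized as the lowest-quartile
  frames of the smoothed first-pass diameter series; the 10% threshold is
  fixed at the basal-profile maximum and reused across frames, so
  dilation reads as a width increase.
* **Edge interpolation bias.** The projected-cylinder edge has infinite
  slope, so a linear-interpolated crossing lands slightly outside the
  true edge; with 1 µm pixels the net bias of the whole chain is a few
  tenths of a micrometre, inside the one-pixel tolerance used in the
  recovery tests. The synthetic generator draws a random sub-pixel vessel
  centre so this bias is averaged over pixel phase rather than frozen at
  one alignment.

## Photobleach handling: two baselines

Two different slow baselines appear in the pipeline and should not be
confused:

* `fade_baseline()` — a strong Gaussian low-pass (half-power 5 mHz) of an
  in-vessel intensity trace, used to *divide the image stack* so images
  are normalized to basal dye intensity. It is implemented as a
  Gaussian-weighted local linear regression: in the interior this is
  exactly the Gaussian smoother, while at the trace ends the local line
  lets a decaying trend extrapolate instead of bouncing back. The
  steady-state rejection of a 0.25 Hz oscillation is below $10^{-3}$;
  within roughly three filter time constants (~110 s at 5 mHz) of either
  end, one-sided estimation is fundamentally less selective and rejection
  degrades to the percent level. Sessions are minutes long, so this edge
  zone is a small fraction of the data.
* `normalize_percent()` — the percent display used for all spectral
  analysis: the trace is divided by its own zero-phase low-pass baseline
  (raised-cosine transition 10 → 50 mHz), minus 1, times 100. The
  transition band is placed so that everything in the vasomotion band
  (0.1–1 Hz) passes with unit gain while the photobleach fade and dye
  dilution are absorbed into the baseline.

All zero-phase filters are realized in the frequency domain with
reflection padding; zero phase matters because the phase-analysis module
interprets lags of a few hundred milliseconds.

## Spontaneous dilation events

Events are near-instantaneous rises followed by exponential decay. The
generator draws inter-event intervals, peak amplitudes and half-widths
from normal distributions truncated at zero — the source statistics are
reported only as mean ± SD with unimodal cumulative curves, so the
distributional form is a modelling choice, with defaults 15.8 ± 4.8 s,
10.4 ± 3.7%, and 1.6 ± 0.4 s. The decay constant is
$\tau = \mathrm{halfwidth}/\ln 2$, making the transient's FWHM equal the
drawn half-width exactly.

The detector thresholds a baseline-normalized trace. Because the
original detection thresholds were set by eye, the package replaces them
with a reproducible rule: threshold $= k \times 1.4826\,\mathrm{MAD}$
(default $k = 3$), with a manual override. Three numerical details are
deliberate:

* **Hysteresis.** An event region closes only when the trace falls below
  half the detection threshold; otherwise noise jitter around the
  threshold during the decay fragments one event into several spurious
  near-threshold detections.
* **Unresolved rises.** When the sample before the half-maximum crossing
  is still below the detection threshold, the rise happened within one
  sampling interval; interpolating across such a step inflates the
  half-width by half a sample (0.1 s at 5 Hz, a systematic +6% on a
  1.6 s event), so the crossing is taken at the first supra-half sample
  instead.
* **Symmetric crossing estimates.** On a noisy decay the *first passage*
  below half-maximum is systematically early (the noise SD is comparable
  to the per-sample decay step at 5 Hz). The half-width therefore
  averages the first-passage and last-exceedance crossings, whose biases
  cancel on a monotone flank.

Inter-event intervals are measured peak-to-peak — peaks localize better
than onsets on noisy data. Overlapping events are split at local minima
that drop below half of the lower adjacent peak.

## Entrainment: PR0.25

Spectra are single-sided rectangular-window FFT amplitudes, scaled so a
sinusoid of amplitude $A$ with an integer number of cycles gives a peak
of exactly $A$; session durations are cycle multiples by design, so the
0.25 Hz stimulus frequency is an exact bin. The entrainment statistic is

$$\mathrm{PR}_{0.25} = \frac{A(0.25\ \mathrm{Hz})}{\overline{A}(0.1\text{–}1\ \mathrm{Hz})},$$

the amplitude at the target bin divided by the band mean *including* the
target bin (so a flat spectrum gives exactly 1; whether the source
excluded the bin is not stated). Spectrograms use the same per-window
scaling; of the standard window/step choices (120/10, 60/4, 40/2 s) the
middle one is the default. The pixelwise PR map smooths each frame with
a spatial Gaussian (default $\sigma$ = 165 µm) before the per-pixel
percent normalization, FFT and PR evaluation.

The generator's entrained channel multiplies a stimulus-locked
modulation (default 3% while locked) by an exponential fade
($\tau$ = 600 s by default; fading is reported without a constant, so
this is a realistic choice) and adds 1% Gaussian noise. Intermittent
locking — vasomotion drifting in and out of frequency lock — is modelled
as alternating locked/unlocked epochs with exponential durations whose
duty cycle is `lock_fraction` (epoch-pair mean 80 s, i.e. 10–20 stimulus
cycles per epoch).

## Phase between channels

The lag between two percent-normalized channels is the lag of the most
negative local minimum of their normalized cross-correlation within one
stimulus period (±4 s), ties broken toward zero lag; pairs with no
negative local minimum in range are excluded. The phase is

$$\varphi = \frac{\Delta t}{T}\cdot 360^\circ + 180^\circ \pmod{360^\circ},$$

the +180° accounting for the anti-phase (shadow) relation the negative
peak encodes. At 5 Hz sampling the lag is quantized to 0.2 s = 18° of
the 4 s cycle; parabolic sub-sample refinement is available but off by
default, matching the quantized lags the method normally reports. The
companion-channel defaults `dyfp_model()` (mean phase 184.4°, i.e. an
almost pure mirror) and `autofluorescence_model()` (246.9°, a mirrored
channel with a ~0.74 s metabolite delay) encode the two reference
conditions.

For stimulus-locked phases, a trace is cut into cycle-length segments
from the window start (75 segments per 5 min at the 4 s cycle), the
segments are averaged, and a fixed-frequency sinusoid is fitted — linear
in the sin/cos basis, hence closed form and exact on noiseless input.
Segments feeding the vasomotion phase estimate are screened with
PR > 3 over 40 s windows (ten stimulus cycles, the shortest standard
spectrogram window).

## HOKR eye analysis

Saccades are inter-frame steps above 1° (at 30 fps); flagged samples
plus a one-frame guard are removed and gap-filled by linear
interpolation (uniform sampling is needed downstream), repeating until
no supra-threshold step remains — a single pass can leave a
supra-threshold interpolated ramp when a large saccade lands on a steep
tracking slope. Drift is removed with a zero-phase band-pass (unit gain
0.1–0.5 Hz). The per-test amplitude locates the peak and trough sample
positions on the cycle-averaged template and reads every cycle at those
fixed positions; averaging per-cycle *extrema* instead would inflate the
amplitude by the expected maximum of the residual noise, a bias that
grows as gain falls. Relative gain divides each test's amplitude by the
first test of the first training session (the spaced protocol gives 10
tests: early/late × 4 sessions + day-2 and day-5 tests, with 3-min eye
and 5-min fluorescence windows, full 2 min for the short tests).

The synthetic eye trace tracks the stimulus with a gain and a 2.3°
default lag, plus slow drift, 0.1° measurement noise, and Poisson
saccades (6/min, amplitudes 2–5°, instantaneous step with 2 s
exponential re-centering). Recovery tests mirror the source procedure:
the per-session phase is averaged over four sessions per animal and then
over five animals — with a single session per animal the saccade-induced
per-session phase scatter (~0.7° SD, consistent with the reported 1.0°
across-animal SD) dominates the five-animal mean.

## What the generators do and do not emulate

The generators reproduce the *statistical structure* the measurements
rest on: projected-cylinder vessel profiles whose centre brightness
scales with diameter, truncated-normal event statistics, exponential
photobleach fade, stimulus-locked modulation with intermittent lock,
mirrored/delayed companion channels, and saccadic eye traces. They do
not model heartbeat pulsation (~10 Hz), respiration, motion artefacts,
vessel curvature or branching, spatially varying bleach, or pupil
geometry — so passing recovery tests demonstrates correctness of the
estimators under the stated noise model, not robustness to every
artefact of in-vivo data.

## Problem sizes and reproducibility

The test suite and the acceptance script use desk-scale problem sizes
chosen to keep runs fast while leaving the statistics well determined:
20 ten-minute event sessions, 13 + 28 five-minute channel pairs, five
animals × four sessions of eye data, five 2-minute vessel stacks, and a
15-minute trace for the spectral checks. Every generator takes an
explicit integer seed and restores the caller's RNG state; identical
arguments and seed give bit-identical outputs and ground truth.
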