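---
title: "Spectral baroreflex sensitivity: models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral baroreflex sensitivity: models, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ambubrs)
```

## The estimation model

Baroreflex sensitivity (BRS) is modeled as the frequency-domain gain from
beat-to-beat arterial pressure fluctuations to heart-period (RR)
fluctuations. Both series live on the irregular beat grid, so the chain
is: place each beat value at its R-peak time, interpolate linearly onto a
uniform 4 Hz grid, remove a first-order (linear) trend, and estimate the
cross- and auto-spectra by Welch averaging. The transfer function is
`H(f) = Pxy(f) / Pxx(f)` with input `x` the SBP series (or a cuffless
surrogate) and output `y` the RR series; the BRS index is the mean `|H|`
over the 0.04–0.15 Hz low-frequency (LF) band, where Mayer-wave activity
and its reflex response live. Magnitude-squared coherence
`|Pxy|² / (Pxx Pyy)` over the same bins measures how much of the RR
variability is linearly explained by the input; a window qualifies when
its mean LF coherence reaches 0.14.

Assumptions worth keeping in mind:

* linearity and (local) stationarity of the pressure→RR relation within
  one analysis window — interventions and ambulatory activity are handled
  by windowing, not by the model;
* an open-loop reading of the gain: the estimator reports the magnitude
  of the conditional linear relation and makes no attempt to separate
  feedback (pressure→RR) from feedforward (RR→pressure) pathways;
* surrogate features (PAT, RDRatio) are useful exactly insofar as they
  are linearly (inversely) coupled to SBP; `|H|` is used so inversely
  coupled inputs still produce positive indices, with the phase retained
  on the `TransferEstimate` for inspection.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `resample_fs` | 4 | Hz | ~4× the highest band edge (0.40 Hz); keeps segments short in samples |
| `detrend_order` | 1 | — | removes slow drifts that would leak into LF |
| `segment_len` | 120 | samples | 30 s segments: LF resolution 0.033 Hz, three bins in band |
| `overlap` | 0.5 | — | standard Welch compromise between variance and correlation |
| `taper` | Hann | — | sidelobe suppression with well-known coherence behavior |
| `coherence_threshold` | 0.14 | — | window qualification level used throughout; a configuration constant of the method, not derived in-package |
| `max_gap_s` | 5 | s | longest beat gap the linear interpolation may bridge; longer gaps reject the window |
| `cuff_pre_s`, `cuff_post_s` | 15, 60 | s | occlusion blanking around a cuff inflation |
| `template_beats` | 5 | beats | morphology template length for the SNR criterion |
| `snr_threshold_db` | 0 | dB | template-to-residual power; 0 dB = noise as strong as signal |
| `path_length_m`, `pwv_min`, `pwv_max` | 0.8, 2, 10 | m, m/s | PAT validity range `[path/pwv_max, path/pwv_min]` = 80–400 ms |
| `max_rel_delta_rr/pat` | 0.25 | — | beat-to-beat ectopy/artifact screen |
| `epoch_s`, `min_beat_fraction` | 60, 0.5 | s, — | epoch persistence rule, inclusive at exactly 50% |

With 120-sample segments at 4 Hz the one-sided grid has spacing 1/30 Hz,
so the LF band contains the bins at 0.0667, 0.1000 and 0.1333 Hz (0.0333
Hz falls below the 0.04 Hz edge). Gain averaging uses all in-band bins;
coherence qualifies the *window*, not individual bins (bin-wise masking
would bias the band average toward lucky bins).

## Fiducial detection and features

Pulse processing follows the first-derivative route: a zero-phase
(forward–backward) order-4 Butterworth low-pass at 10 Hz, then a central
finite difference scaled to units/s. The upstroke is the per-beat
derivative maximum (refined to sub-sample precision with a three-point
parabola); the foot is the last preceding sample where the derivative
drops below a configurable fraction (0.2) of the beat's derivative
maximum; peak, dicrotic notch and secondary peak come from the
derivative's subsequent sign changes, and the shoulder from a
non-crossing derivative maximum during decay. Points a morphology lacks
are reported `NA`, never fabricated. Beats span foot to foot, and
partial beats at the record edges are dropped — edge beats whose waveform
support is clipped by the record boundary are the one place where timing
can be off by more than a sample, which is why recovery checks in the
test-suite exclude the first and last beat.

Feature conventions: PAT pairs each R-peak with the first upstroke within
80% of the current RR (and before the next R-peak) — a pairing window the
data model itself does not dictate, chosen to make cross-beat pairing
impossible. RDRatio measures 10→70% rise against 70→10% decay, both
referenced to the same foot-to-peak amplitude, with crossing times found
by linear interpolation between samples (at 240 Hz, nearest-sample
crossings would alias several percent of the ratio). PPG amplitude is
foot-referenced (the pulsatile component; PPG baselines are arbitrary),
while pressure channels report the absolute systolic value as SBP.

## Qualification criteria

The five ambulatory criteria map to per-beat reason codes (`cuff`,
`snr`, `pat_range`, `variability`, `epoch`). The first four are
independent per-beat screens and commute; the epoch rule runs last by
contract because it consumes their result. Criteria only remove beats
and are idempotent. The template-SNR screen is an open reimplementation
of an idea usually shipped as proprietary device code: beats are
time-normalized to 100 points foot-to-foot, mean-centered, compared to
the pointwise median of five consecutive beats, and scored as
template-to-residual power in dB; its 0 dB default threshold is a
package decision, exposed in `qualityConfig()`. A deliberate
interaction: a PAT or RR spike trips the variability screen on the spike
*and* on the following beat (the return step is also a drastic change);
the constructed-fixture tests assert exactly this set.

## The synthetic generator

`simulateBeats()` is open-loop by design: SBP deviations (LF sinusoid at
0.1 Hz, HF sinusoid at 0.25 Hz, plus broadband beat-to-beat variability)
drive RR through the configured gain with a one-beat delay, so the true
transfer gain equals `gain_ms_per_mmHg` at every frequency and the
estimator has an analytic target. A closed feedback loop would be more
physiological but has no closed-form gain to validate against — that is
the main deliberate departure from reality. Defaults describe a resting
adult: SBP 120 mmHg with 4 mmHg Mayer waves and 2 mmHg respiratory
oscillations, 2 mmHg broadband variability, RR 1000 ms with 10 ms
unexplained noise, gain 8 ms/mmHg, PAT 250 ms at baseline with −1 ms/mmHg
coupling, RDRatio 0.8 with −0.005 /mmHg coupling. Pre-noise series obey
the couplings exactly and are stored alongside the noisy observations.

Rendering uses Gaussian QRS complexes and piecewise-Gaussian pulses with
different rise and decay widths; for that shape the 10–70% crossing
separation is `1.3014 σ` on either limb, so the width ratio realizes the
target RDRatio exactly, and the dicrotic bump is placed at `3.4 σ_d`
past the peak where its contribution at the 10% crossing is negligible.
The upstroke of the rising limb sits at `μ − σ_r`, which anchors PAT
exactly. What the generator does *not* emulate: realistic ECG morphology
beyond R-peak detectability, respiratory sinus arrhythmia mechanisms
beyond the additive HF term, pre-ejection-period variation inside PAT,
baroreflex nonlinearity and saturation, and closed-loop causality.
Passing tests therefore demonstrate correctness of the estimator chain
under the stated statistical structure, not clinical validity on real
patients.

The 24-hour scenario (`scenario24h()`) encodes an office day: 16 h of
desk work with a one-hour and a 15-minute walk (SBP +10%, RR ×0.72,
gain ×0.5, motion artifacts on the pulse channel), 8 h of sleep (SBP
−8%, RR ×1.15, gain doubled, alternating ±8% hour-to-hour as a slow
nocturnal oscillation), and cuff inflations every 15 min by day and
30 min by night — 80 events in 24 h.

## Numerical choices and degenerate inputs

* Welch scaling is one-sided density scaling (`1/(fs Σw²)`, doubled off
  DC/Nyquist); coherence is clipped into [0, 1] against floating-point
  overshoot and defined as 0 where a spectrum vanishes (constant input).
* Filtering operates around the signal mean so forward–backward edge
  transients stay negligible; a constant signal filters to itself.
* `toUniformSeries()` extrapolates by nearest value only at window edges
  (`rule = 2`); interior gaps above 5 s reject the window rather than
  invent data.
* Refractory handling keeps the larger of two detections closer than
  200 ms (R-peaks) / 300 ms (upstrokes); flat local maxima break ties to
  the left.
* Statistics use the sample SD (n−1) throughout; repeats collapse by the
  median (the mean is available via `collapse = "mean"`); Pearson is the
  reported correlation with Spearman computed alongside.
* A hand-check of the intra-participant precision definition on two
  participants with repeats {7, 8, 9}: pooled errors versus participant
  medians are {−1, 0, 1} twice, so the statistic is
  `100·sd(errors)/mean = 100·√(4/5)/8 ≈ 11.18%` — the toy value frozen
  in the tests.
* The ambulatory standard error is computed over the
  coherence-qualified 4-minute windows of each 1-hour span — the same
  set the median uses — which is the self-consistent reading of
  error bars on a 15-minute grid built from 1-hour medians.

## Problem sizes

Validation runs at desk scale by choice: 5-minute records for gain
recovery (50 seeds), a 28-participant × 3-session × 3-intervention cohort
with 3-minute trials for the interventional statistics, and one full
24-hour beat-level scenario (~85 000 beats, 1436 four-minute windows) for
the ambulatory profile. Waveform-level recovery checks use 40–60 s
renderings at 240 Hz; the ambulatory prototype rendering default is
80 Hz, since wearable sampling rates need not match laboratory equipment.

## Known limitations

* The open-loop generator cannot probe closed-loop bias of transfer-gain
  estimators; recovered gains on real (closed-loop) data may differ
  systematically.
* `|H|`-based indices are positively biased when input coherence is low;
  the coherence threshold bounds but does not remove this.
* The template-SNR criterion is a reproducible stand-in for device
  vendors' proprietary quality indices and will not match any of them
  bit-for-bit.
* EDF/WFDB support is deliberately minimal (16-bit, single dialect each)
  — enough for interchange and round-trip testing, not a full
  implementation of either standard.
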