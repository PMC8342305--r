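---
title: "Accelerometric reflux scoring: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accelerometric reflux scoring: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refluxacc)
```

## The measurement model

A uniaxial accelerometer over the sub-xiphoid process senses chest-wall
motion perpendicular to the chest (the z-axis). Refluxate filling the
lower esophagus distends it and produces slow (< 30 Hz), sub-audible
deflections of the overlying wall; feeding peristalsis in preterm
infants is weaker and generally stays below the scoring threshold. The
recorded voltage is treated as a calibrated time series in microvolts at
200 Hz. Three nuisance processes ride on top of the reflux signal and
the pipeline is built around removing each of them explicitly:

* a broadband sensor/skin noise floor, present in every spectral bin;
* 60 Hz mains interference from surrounding NICU equipment;
* transient broadband (> 60 Hz) motion and handling artifacts.

The scoring chain is deliberately simple and fully linear apart from one
step, the spectral noise flooring, whose nonlinearity is the point: it
deletes the noise floor while leaving genuine reflux energy shifted down
by a known constant.

## Stage 1: spectral quality control

**Notch.** A second-order IIR notch at `notch_freq = 60` Hz with
`notch_quality = 30` (≈ 2 Hz bandwidth), applied forward and backward so
the 0–30 Hz band is untouched in amplitude (< 1 % change) and phase.
High-Q notches ring at their own centre frequency when excited by edge
discontinuities, so the signal is extended at both ends by
autoregressive (Burg) extrapolation before filtering: linear prediction
continues narrowband content — the mains tone in particular — phase
continuously, which keeps the forward–backward transient out of the
analysed span. Reflection padding does not have this property (the
carrier phase jumps at the junction) and was measurably worse.

**Segmentation.** Non-overlapping 1024-sample segments (5.12 s at
200 Hz), per-segment mean removal, rectangular window. The rectangular
window keeps the µV amplitude reading exact at bin-centered frequencies,
which is what both the flooring constant and the positivity cut-off are
denominated in; a Hann option exists for spectral inspection, but the
reconstruction path assumes the rectangular analysis and the package
treats it as canonical. Non-overlapping segments keep the excision
semantics unambiguous (a segment is either in or out).

**De-jitter.** Every single-sided bin amplitude is floored by
`dejitter_floor = 200` µV with clamping at zero, interpreted per
segment-spectrum bin, with phases kept for reconstruction. Flooring is
applied between the FFT and the artifact test, so the artifact test sees
"remaining" amplitude.

**Excision.** A segment is discarded whole when any floored bin at a
frequency strictly above 60 Hz exceeds 200 µV (strict inequalities at
both boundaries; the boundary behaviour is not observable from any
worked example, so strictness is a documented, configurable choice).
Excised segments are removed from the timeline rather than zero-filled —
zero-filling would dilute the mean score with silence the sensor never
recorded — and the gap positions are logged so that episode runs can be
broken at the seams.

**Reconstruction and decimation.** Retained segments are
inverse-transformed from the floored spectra with their original phases
and concatenated; the result is low-pass filtered (511-tap Hamming FIR,
cut near 29 Hz, applied zero-phase, > 80 dB effective stopband) and
polyphase-resampled 200 → 60 Hz (× 3/10). An alternative "direct" score
averages the floored stage-1 band amplitudes without reconstructing;
because stage 1 and stage 2 use different bin widths (0.195 vs
0.117 Hz), the direct path divides each segment's 0–30 Hz amplitude sum
by the *stage-2* band bin count (257), making it an estimator of the
canonical score. The two paths agree to within a few percent on
band-limited tones that are bin-centered in both stages (multiples of
0.586 Hz); for broadband signals amplitude is not conserved across bin
widths and only the reconstruction path is meaningful. It is the
canonical one throughout.

## Stage 2: scoring

The clean 60 Hz signal is cut into non-overlapping 512-sample
spectrogram columns (8.53 s) and the score is the arithmetic mean of all
cell amplitudes with frequency in `[focus_low, focus_high]` = [0, 30] Hz
— the DC bin is included; it is ≈ 0 after per-column detrending, and
excluding it would change the denominator for no benefit. The positivity
rule is **score ≥ positive_cutoff**, inclusive, with the default cut-off
at 1 µV.

Episode features are defined per column, not per cell: a column is
active when its band mean reaches the cut-off, episodes are maximal runs
of active columns, and runs are broken at excision gaps, so an artifact
can never bridge two episodes into one. The pattern label applies, in
order: *negative* (no episodes), *continuous* (an episode of at least
`continuous_min_duration` = 1200 s, i.e. > 20 min), *rhythmic*, else
*intermittent*. Rhythmicity (≈ 4 bursts/min) cannot be resolved on
8.53 s columns — the burst period is 15 s — so it is detected on a 1 s
RMS envelope of the clean signal: the envelope autocorrelation must peak
(ACF ≥ 0.25) at a lag within ± 50 % of the configured rate's period
(10–30 s for 4/min). Scores from recordings with less than 30 min of
retained signal are reported but flagged (`short_recording`), since the
score is a long-run mean.

## The pH comparator

Acid episodes are maximal runs of samples strictly below
`acid_threshold = 4.0`, debounced at `min_episode_s = 15` s (probe
spikes; the debounce is configurable since no canonical value exists),
with optional recovery hysteresis. The Boix-Ochoa composite sums six
normalised components, each clamped at zero:
`Σ max((observed − mean) / sd + 1, 0)`, and is positive strictly above
16.6. The published normative means/SDs are *not* bundled:
`component_norms` is required configuration, with `identity_norms()`
(worked examples, tests) and an explicitly synthetic
`placeholder_norms()` provided; every result echoes the norms it used.
Without a postural track both postural components take the total-time
value (infants are nursed supine) and the mode is recorded. Studies
shorter than 24 h are scored but flagged, because the count-based
components are duration-dependent.

## The synthetic generator

`simulate_pair()` emulates exactly the structure the pipeline assumes:
Gaussian baseline noise (30 µV RMS default — per-bin spectral amplitude
≈ 1.7 µV, far under the 200 µV floor), a 60 Hz mains tone (100 µV
default), reflux bursts of amplitude-modulated 0.5–10 Hz noise, optional
4/min gating for the rhythmic pattern, broadband 61–100 Hz artifacts,
and a paired pH trace in which only acid events dip below pH 4 (non-acid
dips are clamped above 4.3 by construction, mirroring the
accelerometry-positive/pH-silent case). Burst and artifact amplitudes
are *per-bin spectral targets* referenced to the 1024-sample analysis
window (`event_amp_uv = 600` → ≈ 400 µV after flooring), because the
flooring rule is denominated in spectral µV; artifacts are centered
inside one reference window so each lands in a single segment, and their
target is duty-cycle-corrected. About 30 % of events are acid
(`acid_fraction = 0.3`), matching the ≈ 70 % non-acid fraction reported
in preterm cohorts. One master seed derives all per-subject streams, so
cohorts are reproducible regardless of generation order.

Default problem sizes are a package choice: 10-minute recordings with
one 20 s event (the 6 events/hour default rate pro rata), and 50-subject
cohorts at 50 % prevalence in the recovery checks. Clinical recordings
of 3–6 h are supported by the same code path.

What passing tests on this generator do **not** show: the generator's
bursts are stationary band-noise with clean edges, its artifacts are
isolated and segment-aligned, and its amplitudes are a synthetic
calibration chosen to straddle the 1 µV cut-off — real chest-wall
signals have cardiac/respiratory components, drifting baselines,
artifacts that straddle segment boundaries, and an unknown µV-per-g
calibration. Recovery rates on synthetic cohorts therefore validate the
*implementation*, not the clinical operating point of the 1 µV rule.

## Numerical and degenerate-input choices

* CSV timestamps must be uniform to within 0.1/fs; worse jitter is
  refused rather than silently resampled. Inferred rates are snapped to
  integers when within 1 ppm (float noise in `median(diff(time))`).
* A trailing part-segment is dropped, never padded; a recording shorter
  than one segment (or one spectrogram column) is an error naming the
  minimum duration.
* An all-excised recording raises an error carrying the first excision
  reason rather than returning an empty score.
* Zero signals propagate to zero scores through every stage (the AR
  padding falls back to constant extension when the edge is flat).
* `classify()` rejects negative scores as a contract violation instead
  of silently returning FALSE.
* Diagnostic rates with a zero denominator are `NA` ("not applicable"),
  never 0; exact rationals are kept internally and rounded to one
  decimal only for reporting.
* In the surgical fixture the cells follow the detailed results
  paragraph (2 both-positive / 8 accelerometry-only / 1 both-negative);
  in the medicated fixture the cells (1/12/0/7) are the unique encoding
  consistent with all stated margins (19/20 pH-negative, 13
  accelerometry-positive, no pH-positive/accelerometry-negative pair).

## Known limitations

* The Boix-Ochoa normative component values must be supplied by the
  user; the package can only guarantee the composite arithmetic and the
  strict 16.6 cut-off.
* Single-axis, single-sensor processing only; no refluxate-height
  estimation and no multi-sensor fusion.
* The rhythmicity detector is a single-lag autocorrelation test; mixed
  patterns (rhythmic bursts inside a continuous episode) resolve to
  *continuous* by the precedence order.
* WAV input carries no physical units; scores from uncalibrated WAV data
  are meaningless unless `volts_per_unit` is correct.
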