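---
title: "Continuous relative phase for lower-limb coordination: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous relative phase for lower-limb coordination: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crpkit)
```

## The measurement model

A trial is a simultaneous recording of sagittal segment angles for the
thigh, shank and foot (degrees, measured from the vertical; negative
clockwise), or 3-D markers from which those angles are derived by
projecting two markers per segment into the sagittal plane, plus the
vertical ground-reaction force (GRF) used to locate foot contact. All
channels share one sampling rate, nominally 120 Hz.

The pipeline runs, per trial:

1. **Smoothing.** Zero-lag Butterworth low-pass, cutoff 6 Hz, order 4 per
   pass, applied forward and backward. The dual pass cancels phase lag and
   squares the magnitude response, so the gain at the cutoff is
   (1/√2)² = 0.5 rather than 1/√2. We do not apply a cutoff-correction
   factor for the double pass; 6 Hz is the conventional kinematic
   smoothing frequency for gait and the attenuation of interest happens
   well above walking's spectral content (&lt; 3 Hz).
2. **Velocity.** Central finite differences on real (pre-normalization)
   time, one-sided at the record ends. Differentiating before time
   normalization keeps velocity in physical deg/s and avoids amplifying
   spline artifacts; the alternative order was considered and rejected
   because normalization warps time trial-by-trial.
3. **Events.** Contact is GRF ≥ 10 N. A purely visual adjunct cannot be
   reproduced, so robustness comes from a 25 ms debounce instead: force
   runs shorter than that are noise, not contacts. Initial contact (IC) is
   the first sample of a qualifying run, toe-off (TO) the first sample
   after it. GRF is baseline-corrected first (median of the lowest decile
   subtracted, clamped at 0) because force plates carry static offsets.
4. **Segmentation and normalization.** Gait: each ipsilateral IC→IC span
   is one cycle, split into stance [IC, TO) and swing [TO, next IC). Hop:
   the span runs from movement onset (first sample with any segment speed
   above 5 °/s — the recording starts with the subject standing, so the
   trial start is a fallback, not the rule) to the record end, split into
   preflight, flight and landing at take-off and touchdown. Each span is
   cubic-spline interpolated onto a 101-point 0–100% base; the whole span
   is normalized once and windows are cut afterwards on the grid
   (boundaries mapped by round-half-up), rather than normalizing each
   phase to a fixed sub-length — the single-normalization reading keeps
   within-cycle timing information intact.
5. **Phase angles.** Angle and velocity are min–max normalized to [−1, 1]
   over the span (velocity can instead be scaled by max |v| via
   `velocity_norm = "maxabs"`; min–max is the default so both axes get the
   same treatment). The phase angle is the quadrant-aware two-argument
   arctangent of (normV, normθ), in degrees, then unwrapped by multiples
   of 360° so successive steps stay within 180°. A single-argument arctan
   would fold the portrait into two quadrants and could never produce the
   continuous multi-revolution phase the unwrapping step presupposes,
   which is why the two-argument form is used. A portrait sample exactly
   at the origin has no defined angle: the previous phase is carried
   forward (flagged); at the first sample it is an error.
6. **CRP and summaries.** CRP = φ(proximal) − φ(distal) per couple
   (TS, SF, TF). Per phase window: RMS of the across-repeat ensemble-mean
   curve (option: mean of per-repeat RMS), and SD as the per-point
   standard deviation across repeats averaged over the window (the
   deviation-phase convention; option: SD of the mean curve's own points,
   for single-trial use).

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `cutoff_hz` | 6 | Hz | conventional kinematic smoothing cutoff |
| `filter_order` | 4 | – | per pass; dual-pass for zero lag |
| `grf_threshold_n` | 10 | N | operationalizes "zero GRF" robustly |
| debounce | 25 | ms | replaces visual event screening |
| `n_points` | 101 | – | the standard 0–100% grid, 1% steps |
| `normalization_scope` | whole_cycle | – | windows cut after one normalization |
| `velocity_norm` | minmax | – | same rule for both portrait axes |
| `sd_mode` | across_trials | – | deviation-phase variability |
| `rms_mode` | ensemble | – | RMS of the mean curve |
| `gait_cycles` | all | – | see below |
| `alpha` | 0.05 | – | significance level, also gates normality |

### Why every complete gait cycle is analyzed

A walkway pass contains several complete cycles, and the across-repeat SD
and couple-lag estimates improve with each one. With per-cycle phase
jitter of σ degrees on two segments, a subject-level mean-CRP estimate
from *k* analyzed cycles has standard error σ·√2/√k: averaging the ~5
cycles of a full pass instead of a single force-plate strike reduces the
error of an 11-subject condition contrast from ≈1.4° to ≈0.6°, which is
what makes ±2° recovery of an injected 8° shift a reliable check. The
single-strike convention remains available (`gait_cycles = "first"`), and
is the right choice when only the plate-contact cycle is trustworthy.

## The synthetic generator

Segment angles are sinusoids, `offset + amplitude·sin(2πt/T + ψ)`, with
the distal segment's base phase leading the proximal's by the configured
couple lag — for equal-frequency sinusoids the phase-portrait angle is
90° − (ωt + ψ), so CRP equals the imposed lag exactly. That analytic
ground truth is the reason sinusoids are the default rather than
realistic multi-harmonic gait templates. The generator emulates:

- segment-specific offsets/amplitudes (defaults echo reported healthy
  sagittal ranges: thigh ≈ 6.7 ± 21.6°, shank ≈ −20.7 ± 38.5°, foot ≈
  37.6 ± 36.3° for gait);
- a stance fraction of 0.62 of the cycle, realized by a smooth unimodal
  GRF bump spanning exactly that fraction (√sin profile, so the 10 N
  threshold is crossed within a fraction of a frame of the true boundary);
- spatiotemporal presets of 136 cm/s velocity and 147.2 cm stride
  (cadence ≈ 110.8 steps/min follows), carried by sacrum and heel marker
  tracks; the cycle duration is quantized to a whole number of samples so
  cycle boundaries fall on the grid (&lt; 0.1% adjustment at 120 Hz);
- per-cycle, per-segment phase jitter (the ground-truth driver of
  across-repeat CRP SD: jitter σ on two independent segments yields SD ≈
  √2·σ) and additive white angle noise (0.5° default);
- a hop with preflight/flight/landing of 0.5/0.25/0.5 s, GRF identically
  zero during flight, body-weight push-off decaying smoothly to zero at
  take-off and a smooth impact bump at touchdown.

It does **not** emulate: realistic multi-harmonic angle waveforms,
kinetic content of the GRF beyond contact timing, soft-tissue artifact,
marker occlusion, asymmetric or pathological gait, or fatigue drift.
Passing the validation suite therefore demonstrates that the *pipeline*
is correct (events, normalization, phase math, statistics), not that any
physiological claim holds for real recordings.

All generator outputs are pure functions of (model, seed, condition,
trial index); cohort generation draws per-subject parameters around the
base models (couple lags SD 3°, offsets SD 1°) and adds named effects to
the sleeve condition only, so injected effects are exact ground truth.

## Statistical layer

Normality is assessed on the paired differences — the paired tests'
assumption concerns differences, not the raw condition values. If
Shapiro–Wilk's p ≥ α the contrast uses the paired *t*-test, otherwise the
Wilcoxon signed-rank with zero differences dropped and average ranks for
ties; the exact distribution is used for n ≤ 25 when no ties remain among
the nonzero |differences|, else the normal approximation with continuity
correction (the exact distribution is undefined under ties). All
differences zero returns p = 1 with a degenerate flag. No multiplicity
correction is applied by default, each parameter being judged on its own
at α = 0.05; Holm adjustment is available (`adjust = "holm"`). The
adaptive procedure holds its size: at n = 11 under a normal null its
empirical type-I error over 2000 simulations stays within [0.03, 0.07]
(re-computed by `scripts/acceptance.R`, not quoted from anywhere).

## Numerical choices and degenerate inputs

- `signal::filtfilt` applies no end-point treatment of its own, so the
  filter demeans the series and pads it by odd reflection before the dual
  pass, trimming afterwards; residual end transients are below 10⁻⁵ for a
  constant input.
- Spline interpolation preserves the span's end points exactly; spans
  shorter than 4 samples are an error.
- Percent-to-grid boundaries use round-half-up, making window partitions
  deterministic; every window must keep ≥ 2 grid points.
- A constant channel cannot be amplitude-normalized (degenerate-signal
  error); coincident markers have no segment angle (degenerate-geometry
  error).
- Cycle repeats within one analysis may disagree at the record ends by
  ~1° (filter start-up, one-sided derivatives); this is visible as a
  floor of ≈0.05–0.15° in the across-repeat SD when jitter and noise are
  both zero.

## Validation problem sizes

The test suite and acceptance script use: 2–6-cycle gait trials and
1.25 s hops at 120 Hz; lags 10–90°; 1000 randomized trials for unwrap
continuity; 20 seeds per jitter level for the variability ordering; 2000
Monte-Carlo replicates for the type-I rate; and an 11-subject, 5-trial
cohort for effect recovery. These sizes give stable estimates (the
effect-recovery SE analysis above) while keeping the whole suite fast.

## Known limitations

- Segment angles only; joint (inter-segment) angles and non-sagittal
  planes are out of scope.
- Event detection is force-based only; kinematic event detection (for
  treadmills or unplated walkways) is not provided.
- The C3D motion-capture container is not read; trials arrive as CSV
  (`load_trial_csv`) or are generated.
- Min–max amplitude normalization is sensitive to single-sample extrema;
  heavy outliers should be filtered before analysis (the default low-pass
  does this for kinematic noise).
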