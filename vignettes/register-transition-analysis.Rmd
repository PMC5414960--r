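---
title: "Quantifying vocal register transitions from EGG and high-speed-video-derived signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vocal register transitions from EGG and high-speed-video-derived signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(passaggio)
```

## The problem

When a singer glides upward through a *passaggio* — a fundamental-frequency
region where vocal register events typically occur — the vocal folds may
change their oscillation pattern smoothly, abruptly, or with brief episodes
of lost contact. `passaggio` quantifies such events from two signal
families that are routinely recorded together:

* the **electroglottographic (EGG) signal**, proportional to relative
  vocal-fold contact area, sampled at audio rates (20 kHz in the emulated
  protocol); and
* **glottal segmentation outputs** of high-speed videoendoscopy: the
  glottal area waveform (GAW) and the medio-lateral glottal width per
  anterior–posterior (A-P) position per frame.

The package starts from these signals; video pre-processing and glottal
segmentation are upstream concerns of dedicated imaging software and are
out of scope.

## The analysis chain

### Cycle separation

Glottal cycles are delimited at **contacting events**, the positive peaks
of the dEGG (first derivative of the EGG). Peak picking uses an adaptive
threshold at 20% of the running local peak amplitude within a ±50 ms
neighbourhood (a high quantile instead of the maximum would sit at the
noise level when the contact phase is short), a global floor of 10% of the
overall amplitude so silent stretches stay peak-free, and a greedy
minimum-spacing rule at `fs/fo_max` that keeps the larger of two
conflicting peaks. Admissible fundamental frequencies default to
[150, 1200] Hz, covering A3–A5 with margin. A periodicity check (median
relative jump of consecutive periods below 20%) rejects aperiodic input.

Two numerical details matter more than they may appear to:

* **Sub-sample boundary refinement.** Peak positions are refined on a
  Gaussian-kernel-smoothed signal whose bandwidth is 1/24 of the *local
  period*. Because the smoothing scale is proportional to the period, the
  small systematic peak shift it introduces is constant in units of cycle
  phase across a pitch glide; a fixed-width smoother would rotate the
  cycle-shape descriptors as fo changes and masquerade as a shape change.
  The kernel average also suppresses noise-induced boundary jitter, the
  dominant noise path into the descriptors.
* **Phase-grid resampling.** Each cycle is resampled at 64 points of
  glottal *phase* (a monotone cubic interpolant through the cycle
  boundaries), not of time. Within the 50 ms fo transition of the emulated
  tasks, fo changes by up to ~12% within a single cycle; on a uniform time
  grid that skews the waveform and registers as a spurious shape change.

Cycles are normalized to zero mean and unit peak-to-peak amplitude, making
everything downstream a pure shape analysis: overall EGG amplitude and fo
cancel by construction.

### Fourier descriptors and sample entropy

Each normalized cycle is reduced to its first two DFT components (scaled
by `1/n`, DC excluded): a 4-dimensional descriptor (Re1, Im1, Re2, Im2).
Real/imaginary parts are kept instead of magnitude/phase to avoid
phase-wrap discontinuities; anchoring the cycle at the contacting event
makes the phases meaningful.

Cycle-to-cycle instability is measured by the **sample entropy** of the
descriptor sequence: the negative natural logarithm of the conditional
probability that two subsequences similar for `m` points remain similar at
the next point, self-matches excluded, max-norm similarity. Defaults are
the field-standard `m = 2`, `r = 0.2` SD. Two deliberate choices:

* **Tolerance floor.** The similarity tolerance per component is
  `max(r * SD, 0.005)`. An SD-relative tolerance is ill-posed for a
  numerically constant series, where the SD consists of interpolation
  residue; the floor (about 1% of the descriptor scale of peak-to-peak
  normalized cycles, an order of magnitude above the measured numerical
  residue of the chain) makes sub-resolution differences count as
  identical. This is what gives the exact fo-invariance of the
  stereotypical control below.
* **Fixed tolerance across blocks.** The cycle-based trace FDSE_c is the
  entropy over a sliding block of 40 cycles (hop 1, value at the block
  centre), but the tolerance is computed once from the whole phonation's
  descriptor SD. If each block scaled its own tolerance, a regime change
  inside a block would widen that block's tolerance and mask itself; with
  a fixed tolerance, block values are mutually comparable and instability
  registers where it occurs. When no template pair stays similar at
  `m + 1`, the entropy is reported at its measurable ceiling `ln(B)`
  rather than infinity.

The block length of 40 cycles resolves 25 ms windows at fo ≥ 220 Hz while
retaining enough templates for stable counts.

### Window alignment

The phonation is divided into consecutive 25 ms segments anchored at the
signal start; FDSE_w of a segment is the mean of the defined FDSE_c values
whose block-centre cycle midpoint falls inside it. The segment with the
global maximum (ties: earliest, for determinism) becomes **window 0**, and
the 11 segments indexed −5…+5 centred there are the analysis windows all
other measures report on. Windows clamped off a signal edge, or without
defined values, are flagged missing and excluded rather than imputed.

### Open quotient and its between-window variation

The per-cycle open quotient of the GAW is the fraction of cycle samples
whose area exceeds the cycle minimum by more than 2% of the cycle
peak-to-peak amplitude. The threshold absorbs segmentation noise on the
closed phase; the baseline is per cycle because endoscope drift moves the
apparent closed-glottis area. GAW-native cycle boundaries are placed at
the last near-minimum sample (5% threshold crossing) before each opening —
the literal minimum wanders on a flat noisy closed phase. Per window, the
mean OQ over cycles (midpoint rule as above), the 10 between-window
differences ΔOQ, and their standard deviation `sd_delta_oq` summarize how
unevenly the glottal configuration changes through the transition.

### Opening/closing contours

For every A-P position and cycle, the opening instant is the first frame
whose local width exceeds 0.5 px (segmentation quantization makes exact
zero unreliable) and the closing instant the first subsequent frame at or
below it. Instants are divided by the cycle duration and averaged per
window and position, with coverage counts published; positions that never
open give missing pairs, positions open through the whole cycle give
(0, 1) with a never-closed flag. Scalar summaries per window: mean open
duration, the least-squares slope of the opening contour versus position
(the A-P "zipper" delay), and the fraction of never-closed positions.

### Cohort statistics

`compute_icc()` implements the Shrout–Fleiss two-way ANOVA forms directly
from mean squares (no ICC package is required); the default ICC(2,k) —
two-way random effects, absolute agreement, average of k raters — is the
conventional choice for a fixed panel of raters scoring all stimuli, and
the form is recorded with the value. Regressions are first-order
polynomial fits reporting r² as the squared Pearson correlation. The
per-stimulus rating aggregate defaults to the mean across raters (median
available).

## What the synthetic generator emulates

The generator reproduces the study conditions the analysis was designed
for: 1-second pitch glides at 20 kHz, fo 220→440 Hz (lower task) or
440→880 Hz (upper task), with the fo change concentrated in a 50 ms
sigmoid interval centred at 0.5 s. The EGG pulse is a raised-cosine
contact pulse with a faster contacting than de-contacting phase (rise
fraction 0.3 of the contact phase) — any shape-stable pulse family serves
the invariance argument; this one also gives the dEGG the right asymmetry
for polarity detection. Five strategies modulate the per-cycle open
quotient and amplitude:

* `stereotypical` — fixed shape; the fo-invariance control.
* `smooth_oq_up` / `smooth_oq_down` — linear OQ ramp across the
  transition interval (defaults 0.55→0.75 and 0.75→0.55).
* `abrupt` — a hard fo and OQ step (0.50→0.85) plus a transient burst of
  per-cycle OQ/amplitude jitter within ±1.5 transition widths of the
  break. The burst is part of the model because register breaks show
  abortive oscillation-mode switches around the jump; a perfectly clean
  two-regime step has almost no conditional surprise and would be nearly
  invisible to sample entropy.
* `contact_loss` — two ~15 ms episodes near the transition in which
  contact collapses (EGG amplitude ×0.15, OQ 0.95) and no A-P position
  closes.

The displacement field realizes a zipper: position `p` opens at normalized
time `cq + slope*p` and closes at `1 − slope*p`; position 0 (anterior)
spans the whole open phase, so the GAW row sum preserves the programmed
OQ. Measurement noise is additive Gaussian at a relative SD (default 1%
for "realistic" runs, 0 for controls). Every generator returns its ground
truth (exact fractional-sample cycle boundaries, per-cycle OQ and
amplitude, loss cycles, programmed contour instants).

The cohort generator plants a joint effect: a severity 1–5 per phonation
selects the strategy and the OQ excursion and serves as the true
perceptual score. Two calibrations mirror reported cohort-level behaviour
rather than being free parameters: task-level OQ endpoints are set so the
cohort-mean OQ rises by about 10% (lower) and 18% (upper) across the
glide, and rater noise (SD 1.8 score units, rater bias SD 0.4) is set so
the 12-rater ICC(2,k) is about 0.85.

What the generator does **not** emulate: vocal-tract acoustics and
source–filter interaction, left–right fold asymmetry, endoscope motion,
mucosal-wave detail, or rater idiosyncrasies beyond additive bias. Passing
tests therefore demonstrate that the measures recover what they claim to
measure under controlled conditions — not that any physiological
interpretation of real recordings is correct.

## Numerical choices and degenerate inputs

* Ties for the maximum FDSE_w segment resolve to the earliest segment.
* Degenerate (flat) cycles: excluded from shape analysis, rendered as 0.5
  in wavegrams with a warning, OQ flagged missing.
* Undefined sample entropy (no template matches) is `NA` and excluded
  from window means; a window with no defined values is flagged missing.
* Cycles whose implied fo leaves the configured band are kept in the
  boundary list but flagged invalid; downstream measures use valid cycles
  only. Contact-loss cycles may legitimately evade the dEGG detector —
  their contacting slope is the thing that vanished.
* The EGG is preconditioned with a zero-phase Butterworth high-pass at
  20 Hz (reflect-padded to keep filter transients out of the edge
  cycles); electrode drift otherwise contaminates the lowest descriptor
  components.
* WAV I/O covers PCM16 and float32 RIFF; EGG polarity is auto-detected
  from the skewness of the first difference (contacting slopes are
  steeper), overridable.

## Problem sizes used in the shipped checks

The test-suite and the verification script run on 1 s phonations
(~330 cycles) at 20 kHz, fields of 32 A-P positions, cohorts of
10 participants × 2 tasks, and 10 seeds per property; these sizes keep the
statistical properties stable while the whole suite completes in a few
minutes.

## Known limitations

* The entropy tolerance floor (0.005) is an absolute constant on the
  peak-to-peak-normalized descriptor scale; descriptor families with a
  very different scale would need it revisited.
* The abrupt/contact-loss severity ordering produced by the pipeline is a
  property of the generator's parameterization; on the OQ-variability
  marker alone, episodic contact loss can outrank an abrupt break (its
  OQ excursions are larger by construction), so strategy separability is
  asserted on maximum FDSE_w and on the composite of both markers.
* Window alignment assumes one dominant instability; phonations with two
  equally strong events keep only the earlier one as window 0.
* Per-phonation values from the original study are not recomputable from
  public data (raw recordings were not deposited); all signal-level
  verification is property-based on synthetic data, plus regression
  machinery that can reproduce published summary statistics if the
  deposited per-figure CSVs are supplied locally.
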