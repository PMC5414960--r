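# passaggio

Quantitative analysis of vocal register transitions (*passaggi*) in pitch
glides, from electroglottographic (EGG) recordings and from the outputs of
high-speed-videoendoscopy glottal segmentation (glottal area waveform and
per-position glottal width).

## Who this is for

Voice scientists and clinical researchers who record EGG alongside
high-speed laryngeal imaging and want reproducible, cycle-level measures
of *how* and *when* the vocal-fold oscillation pattern changes as a singer
traverses a register transition — instead of judging dEGG wavegrams and
kymographic plots by eye alone.

## What it computes

For each phonation (a ~1 s pitch glide, e.g. A3→A4 at 220→440 Hz):

* **Cycle separation** from dEGG contacting peaks, with sub-sample
  boundary refinement and per-cycle fundamental frequency
  (`detect_cycles`).
* **Fourier-descriptor sample entropy (FDSE)**: each normalized cycle is
  reduced to its first two DFT components `c_k = (1/n) * sum_j x_j
  exp(-2*pi*i*k*j/n)`, k = 1, 2, and the sample entropy
  `-ln(A/B)` of the 4-D descriptor sequence (templates of length m = 2,
  tolerance r = 0.2 SD, max-norm, self-matches excluded) is traced over
  sliding 40-cycle blocks (`fdse_cycle_trace`). Low values mean a stable
  waveform; instability around a register event raises it.
* **Window alignment**: mean entropy per consecutive 25 ms segment
  (FDSE_w); the maximal segment becomes window 0 of eleven aligned
  analysis windows −5…+5 (`fdse_windows`, `max_fdse_w`).
* **Open quotient statistics** from the GAW over those windows: per-cycle
  OQ (time-normalized open duration), per-window means, between-window
  differences ΔOQ and their SD (`open_quotient`, `window_oq`).
* **Spatio-temporal opening/closing contours**: cycle-normalized instants
  at which each anterior–posterior position opens and closes, averaged
  per window, with zipper-slope and never-closed summaries
  (`local_open_close_instants`, `normalize_and_average`,
  `contour_summary_metrics`).
* **EGG/dEGG wavegrams** for visual documentation (`build_wavegram`,
  `render_wavegram`).
* **Cohort statistics**: inter-rater ICC(2,k) from two-way ANOVA mean
  squares and first-order regressions (r²) of perceptual rating vs
  maximum FDSE_w and of OQ variability vs maximum FDSE_w
  (`compute_icc`, `fit_regression`, `cohort_report`).

A synthetic-data module (`glide_spec`, `synth_egg`, `synth_gaw_field`,
`synth_ratings`, `synth_cohort`) generates EGG/GAW/displacement-field
triplets with programmable transition strategies (smooth OQ ramps, abrupt
breaks, episodic contact loss) and full ground truth, and is used by the
entire test suite.

## Worked example

```r
library(passaggio)

spec <- glide_spec(fo_start = 220, fo_end = 440, strategy = "abrupt",
                   noise_sd = 0.01, seed = 42)
eg <- synth_egg(spec)
gf <- synth_gaw_field(spec)

res <- analyze_phonation(eg$egg, gf$gaw, gf$field)
res$seg
#> <cycle_segmentation> 319 cycles (317 valid) from degg, fo 212.2-479.7 Hz
res$windows
#> <window_set> 11 x 25 ms windows; window 0 at 0.5250-0.5500 s, FDSE_w = 0.7918
res$oq
#> <window_oq> mean OQ 0.429-0.843 across windows, SD(delta OQ) = 0.0782
res$contour_metrics[res$contour_metrics$window == 0, ]
#>          mean_open_duration ap_delay_slope never_closed_frac n_positions window
#> window_0             0.7438          0.004                 0          32      0
```

Reading the output: the abrupt register break programmed at 0.5 s is
localized by window 0 (0.525–0.550 s, within one 25 ms window of the
break) with a maximum FDSE_w of 0.79 — far above the ~0 of a smooth
glide — while the open quotient swings between 0.43 and 0.84 across the
eleven windows (SD of the between-window change 0.078). The window-0
contour recovers the generator's A-P opening-delay slope (0.004 per
position) exactly, with no never-closed positions outside contact-loss
episodes.

For cohort-level output:

```r
co <- synth_cohort(seed = 1)   # 10 participants x 2 tasks, 12 raters
results <- lapply(co$phonations, function(ph)
  analyze_phonation(ph$egg, ph$gaw, participant = ph$participant,
                    task = ph$task))
cohort_report(results, co$ratings, out_dir = "report")
#> <cohort_report> 20 phonations, ICC(ICC2k) = 0.882
#>   lower: r^2(rating, max FDSE_w) = 0.772
#>   upper: r^2(rating, max FDSE_w) = 0.611
#>   lower: r^2(SD delta OQ, max FDSE_w) = 0.148
#>   upper: r^2(SD delta OQ, max FDSE_w) = 0.257
```

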