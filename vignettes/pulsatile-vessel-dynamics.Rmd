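---
title: "Methods: quantifying pulsatile vessel dynamics in free-breathing lung MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying pulsatile vessel dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsevessel)
```

# The measurement model

A fast spoiled gradient-echo cine of a single coronal lung slice, acquired
during free breathing, samples two superimposed physiologic processes:

* **cardiac** (~1–1.5 Hz): each pressure pulse transiently expands the
  pulmonary vessels, and inflow of unsaturated spins raises the
  intravascular signal (flow-related enhancement). The signal maximum
  precedes the area maximum within each cycle;
* **respiratory** (~0.2–0.3 Hz): the lung outline scales with tidal
  breathing.

Per-frame lung and vessel segmentation converts the image series into
three curves — vessel area $A_v(t)$ (voxels), lung area $A_l(t)$ (voxels)
and mean vessel signal $S(t)$ (a.u.) — from which five parameters are
computed by `vessel_dynamics()`:

$$\mathrm{CV} = \frac{\sigma}{\mu} \times 100\%,$$

applied as follows. For vessel area and vessel signal, the numerator
$\sigma$ is the SD (sample, $n-1$) of the series after a zero-phase
high-pass at 0.6 Hz, and the denominator $\mu$ is the mean of the *raw*
series: the filtered series is centred on zero, so its own mean cannot
normalise anything. For lung area, the CV is taken on the unfiltered
series — it measures tidal breathing depth, which the high-pass would
remove. The SE-delay pairs every peak of the filtered signal curve with
the earliest peak of the filtered area curve at the same or a later time,
averages those lags, and divides by the mean inter-signal-peak interval
(RR); it is reported in percent of RR. Heart rate is $60/\overline{RR}$
(`heart_rate()` also exposes a peak-count variant; for evenly spaced peaks
the two coincide, and the interval form is the default because it is less
sensitive to a single spurious edge peak).

## Filtering

The high-pass is a 4th-order Butterworth applied forward–backward
(zero-phase), with odd-symmetric reflection padding at both ends to
suppress boundary transients. The cutoff (default 0.6 Hz = 36 bpm) sits
between the respiratory and cardiac bands and is reused as the lower edge
of the cardiac search band in peak detection, so a single
respiratory/cardiac boundary governs the whole analysis. Zero phase
matters: any phase distortion of one curve relative to the other would
bias the SE-delay directly. At 0.25 Hz the filter attenuates by more than
99%; at 1.2 Hz it passes with under 1% loss.

## Peak detection near the sampling limit

At the default 384 ms frame interval the Nyquist frequency is 1.30 Hz
(78 bpm): a 75 bpm heart is sampled at barely 2.1 frames per cycle. Local
maxima of the raw samples would then fall up to a quarter cycle from the
true systolic peaks, and a 3-point parabola fitted to samples spanning
more than a full cycle is meaningless — integer-frame peak times would
quantise the SE-delay in steps of roughly half an RR-interval.
`detect_cardiac_peaks()` therefore

1. estimates the dominant cardiac frequency $\hat f_c$ from a zero-padded
   periodogram restricted to $[0.6\,\mathrm{Hz}, f_{Nyq})$;
2. upsamples the filtered series by band-limited (FFT zero-padding)
   interpolation to at least 16 samples per cycle — exact for any tone
   below Nyquist;
3. takes local maxima with a minimum separation of $0.6/\hat f_c$ seconds
   (greedily, tallest first);
4. refines each peak by 3-point parabolic interpolation on the upsampled
   series.

Cardiac frequencies **above** Nyquist cannot be recovered by any method:
the apparent frequency aliases to $f_s - f_c$ and the apparent delay
reflects to $1 - d$. The generator warns in this regime rather than
erroring, because the acquisition it emulates genuinely operates there for
faster heart rates; accuracy statements over heart-rate ranges straddling
Nyquist are therefore median-based.

# The synthetic phantom

`generate_phantom()` provides ground truth for every downstream stage.
Design choices:

* **Geometry.** Two lung fields are superellipses
  ($|x/a|^{2.5} + |y/b|^{2.5} \le 1$, $a = 0.16\,\mathrm{cols}$,
  $b = 0.33\,\mathrm{rows}$) — the simplest smooth shape with an analytic
  area — dark (15% of the vessel signal) on a bright mediastinum/chest-wall
  background (50%). Each lung contains 12 elliptical vessels (aspect 1.6,
  long axis cranio-caudal) in a fixed layout with area shares skewed toward
  a few central vessels, totalling 250 voxels by default — about 3% of the
  lung bounding box, consistent with the default 97th-percentile vessel
  threshold.
* **Waveforms.** All oscillations are sinusoids
  $\mu(1 + \sqrt{2}\,(\mathrm{CV}/100)\sin 2\pi f t)$, so the sampled CV
  over integer cycles equals the requested CV exactly (the RMS of a unit
  sine is $1/\sqrt 2$) and peak times are analytic. An asymmetric
  fast-upstroke variant is available and is renormalised numerically to
  unit RMS so the CV calibration is preserved. The vessel-signal wave
  leads the vessel-area wave by `se_delay_frac` of the RR-interval.
* **Cardiac area scaling.** The total vessel area follows the cardiac
  waveform; each ellipse's semi-axes scale by the square root of the area
  factor, distributing the change proportionally.
* **Respiration and compensation.** The lung outline scales isotropically
  at the respiratory frequency. Because the reported lung area is the lung
  field *minus* the vessels, the respiratory amplitude is solved from the
  target lung-area CV with the cardiac vessel-area variance subtracted in
  quadrature, so the compound series hits its target.
* **Vessels ride with the parenchyma.** Vessel centres scale with the
  breathing lung outline. This reproduces the sub-pixel respiratory drift
  real vessels show, and it matters numerically: with centres frozen on
  the pixel grid, the thresholded mask area responds to the continuous
  area waveform through a fixed staircase whose local slope can deviate
  substantially from one, biasing the vessel-area CV; the respiratory
  drift dithers the staircase, and what remains of it is
  respiratory-locked and removed by the 0.6 Hz high-pass.
* **Rasterisation.** Shapes are anti-aliased by sub-pixel supersampling
  (2× per axis for lungs, 4× for vessels); truth masks threshold coverage
  at 0.5. Images get additive Gaussian noise (default SD 5% of the vessel
  signal); truth masks are noise-free. All randomness flows through the
  seed stored in `phantom_truth`, so identical inputs give bit-identical
  phantoms.

What the phantom does **not** model: MR physics (no k-space, parallel
imaging or coil profiles), through-plane motion, vessel branching
geometry, artery/vein distinction, or cardiac waveform variability.
Passing recovery tests on the phantom therefore demonstrates that the
time-series machinery is unbiased under the stated sampling and noise
conditions — not that segmentation of real anatomy is solved.

# Segmentation baselines

The published analysis used two learned (U-Net) segmenters whose weights
are not public; their role in this package is played by classical
baselines behind the same interface, and `segment_series()` accepts any
`function(frame) -> mask` / `function(frame, roi) -> mask` pair so learned
models can be slotted in.

* **Lungs** are the large dark connected components: pixels below
  `q01 + 0.4 (q99 - q01)` of the frame's robust intensity range
  (scale-invariant — MRI intensities are non-quantitative and depend on
  coil sensitivity and receiver gain), components under 200 px dropped, at
  most two kept. Bright in-lung vessels stay above the threshold and are
  preserved as excluded holes. Whether to normalise intensities before a
  learned segmenter is left to the plug-in; the baseline's relative
  threshold makes normalisation a no-op.
* **ROI.** The bounding box of the lung mask (per frame — segmentation is
  independent frame by frame), optionally expanded by a margin and clipped
  to the image, restricts the vessel search and excludes false positives
  outside the thorax.
* **Vessels** are the bright structures within the ROI at or above the
  97th percentile of in-ROI intensities (ties included, so the rule is
  deterministic), with components under 3 px removed.

A known limitation of the percentile rule: it selects a roughly fixed
*fraction* of the ROI, so the measured vessel area partially tracks the
ROI rather than the true pulsation, damping the vessel-area CV relative to
truth-mask analysis. The baselines exist to exercise the pipeline and to
set a plausibility scale (their Dice against phantom truth is in the same
range as published U-Net scores against expert truth); quantitative work
on real data should plug in a learned segmenter. `overlap_metrics()`
reports Dice, sensitivity and specificity, with both-empty masks defined
as perfect agreement (Dice 1).

# Repeatability statistics

A test–retest design with two scan sessions and two repetitions each
(A1, A2, B1, B2) is summarised by:

* **ICC(2,1)** — two-way random-effects, single-measurement, absolute
  agreement:
  $$\mathrm{ICC} = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}$$
  The consistency form (dropping the column-variance term) is exposed as
  an option; absolute agreement is the default since between-session level
  shifts are real disagreement for a clinical metric. Interpretation
  bands are made total with half-open intervals: poor < 0.50, moderate
  [0.50, 0.75), good [0.75, 0.90), excellent ≥ 0.90.
* **SEM and MDC** — $\mathrm{SEM} = SD_{pooled}\sqrt{1 - \mathrm{ICC}}$,
  with $SD_{pooled}$ the SD of all measurements, and
  $\mathrm{MDC} = 1.96\sqrt{2}\,\mathrm{SEM}$. The SEM-from-ICC convention
  (rather than $\sqrt{MS_E}$) is the one conventionally paired with
  ICC(2,1) and with this MDC formula, whose fixed ratio
  $\mathrm{MDC}/\mathrm{SEM} = 2.77$ the implementation preserves exactly.
* **Pooling.** Intra-session repeatability pools the (A1, A2) and
  (B1, B2) pairs into one two-column matrix (subjects × pairs rows);
  inter-session pools (A1, B1) and (A2, B2). This mirrors
  "without leaving the scanner" vs. "after repositioning" and doubles the
  effective sample per comparison.
* **Friedman + Dunn–Šidák** across all four sessions (tie-corrected;
  pairwise z-tests on within-subject mean ranks with
  $p_{adj} = 1-(1-p)^m$, $m = k(k-1)/2$), and **Bland–Altman** bias with
  1.96·SD limits of agreement per pooled pair.
* **Missing cells** are excluded listwise (the two-way ANOVA needs a
  complete grid) and the excluded count is reported rather than silently
  dropped.

# Cohort statistics

Group comparisons use the **Kruskal–Wallis** test (tie-corrected, as the
metrics are not reliably normal) with the rank effect size
$\eta^2_H = (H - k + 1)/(n - k)$, clamped at zero for labelling
(negligible < 0.01, small [0.01, 0.06), moderate [0.06, 0.14],
large > 0.14 — made total at the boundaries), and **Dunn** pairwise
z-tests with tie-corrected pooled-rank variance and Šidák adjustment.
Across the family of five metrics, p-values are additionally
Bonferroni-adjusted with $m = 5$ by default (the family size is
configurable, since the analysis family is a reporting decision).

The regression layer fits, per metric, ordinary least squares on
status + gender + age + BSA with Healthy and male as reference levels
(contrasts "Status [PH]", "Status [COPD]", "Gender [F]"), BSA from the
Dubois formula $0.007184\,h^{0.725}w^{0.425}$, per-coefficient t/p from
the fit and per-term F from the extra-sum-of-squares comparison against
the model without that term. Rank-deficient designs error naming the
collinear term. `simulate_cohort()` generates covariate-complete
synthetic cohort tables (log-normal metrics with group-specific medians,
plausible demographics) as a statistical stand-in where real cohort data
would be loaded; it makes no claim to reproduce published cohort values,
which require the original patient data.

# Numerical choices and problem sizes

* Degenerate inputs: constant frames give empty lung masks (not errors);
  an empty lung mask stops ROI construction with "no lung found"; an empty
  per-frame vessel mask makes the vessel signal undefined and errors
  naming the frame; series with relative pulsatility below $10^{-6}$ are
  reported as having no detectable cardiac frequency; complete ties give
  Friedman/Kruskal–Wallis statistics of 0 with p = 1 rather than 0/0.
* Ties at the vessel threshold are included; ICC/η² label boundaries are
  half-open; peak selection breaks ties tallest-first.
* The acceptance-scale simulations use 20 phantoms of 250 frames
  (128 × 128) for parameter recovery and one noise-free phantom for
  segmentation Dice; unit tests use 96 × 96 phantoms of 40–120 frames at
  0.3 s, where the 72 bpm default is comfortably below Nyquist. The ICC
  variance-ratio convergence property is checked at 500 subjects.
* The generator's defaults (78 bpm, 15 breaths/min, CVs of 3/8/4%,
  SE-delay 0.63 RR, noise 5% of vessel signal) are fixed, physiologically
  representative study conditions; tests vary them only where a property
  explicitly concerns another regime.

# Known limitations

* Heart rates above the Nyquist equivalent of the frame interval
  (78 bpm at 384 ms) are aliased in both the emulated acquisition and the
  analysis; the implementation warns and reports the apparent values, as
  any method operating on such data must.
* The stated acquisition timing (250 frames at 384 ms) spans 96 s; the
  frame count and interval are treated as independent inputs and no
  attempt is made to reconcile them with any nominally shorter scan time.
* The classical segmentation baselines are pipeline stand-ins, not
  clinical segmenters (see above); artery/vein separation and regional
  analysis are out of scope.
* DICOM support is a minimal explicit-VR little-endian reader/writer for
  single-frame uncompressed MR images, sufficient for instance-number
  ordering and round trips; compressed or implicit-VR archives should be
  converted to NIfTI first.
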