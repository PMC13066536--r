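# pulsevessel

Quantitative analysis of **pulsatile vessel expansion** in free-breathing
dynamic (2D+t) lung MRI.

With every heartbeat, the pulmonary vessels briefly dilate as the pressure
wave passes, and the inflow of unsaturated spins transiently raises the
vessel signal in spoiled gradient-echo imaging (flow-related enhancement).
In a fast single-slice cine acquired during free breathing (e.g. 250 frames
of a 128 × 128 coronal slice at 384 ms per frame), per-frame lung and
vessel segmentation turns these effects into three time series — vessel
area, lung area and mean vessel signal — from which five physiologic
parameters are derived:

| Parameter | Definition | Units |
|---|---|---|
| CV vessel area | SD of the high-pass-filtered vessel-voxel count / mean count | % |
| CV lung area | SD/mean of the raw lung-voxel count (tidal breathing depth) | % |
| CV vessel signal | SD of the filtered mean vessel signal / mean signal | % |
| SE-delay | mean lag from each signal peak to the next vessel-area peak, / RR | % of RR |
| Heart rate | 60 / mean interval between signal peaks | min⁻¹ |

CV is the coefficient of variation (SD divided by mean, as a percentage);
the 0.6 Hz zero-phase high-pass separates cardiac from respiratory content.
The SE-delay captures the phase between blood inflow (signal) and vessel
expansion (area) within the cardiac cycle and is expressed as a percentage
of the RR-interval. Reduced signal pulsatility and a prolonged SE-delay
accompany airway and vascular disease (COPD, pulmonary hypertension),
making these parameters candidate contrast-agent-free markers of pulmonary
hemodynamics.

The package provides, for researchers working on dynamic lung MRI:

* `generate_phantom()` — a synthetic 2D+t phantom with known cardiac and
  respiratory ground truth (and truth masks), so every downstream stage is
  testable without patient data;
* `segment_lungs_baseline()`, `segment_vessels_baseline()`,
  `segment_series()` — classical per-frame lung → rectangular ROI → vessel
  segmentation, with a plug-in protocol for learned segmenters;
* `vessel_dynamics()` — the core analysis returning the five parameters as
  a classed fit with `print`/`summary`/`coef`/`plot` methods;
* test–retest repeatability statistics — `icc_2_1()` (ICC(2,1)),
  `sem_mdc()` (SEM, MDC = 1.96·√2·SEM), `bland_altman()`,
  `friedman_dunnsidak()`, assembled by `repeatability_table()`;
* cohort statistics — `kruskal_eta()` (Kruskal–Wallis with η² and
  Dunn–Šidák post hocs), `fit_linear_model()` (OLS with per-term F),
  `bsa_dubois()`, `bonferroni()`, `cohort_comparison()`;
* NIfTI and (minimal) DICOM I/O plus JSON/CSV writers, and a thin CLI
  (`inst/cli/pulsevessel.R`) with `simulate`, `segment`, `analyze`,
  `repeatability` and `compare` subcommands.

## Worked example

Simulate a healthy-like acquisition (72 bpm, SE-delay 40% of RR, 3% vessel
area CV, 8% lung area CV, 5% image noise) and analyse it on the generator's
own masks:

```r
library(pulsevessel)

cfg   <- acquisition_config()          # 250 frames, 128 x 128, 384 ms
truth <- phantom_truth(heart_rate = 72, se_delay_frac = 0.4, seed = 42)
ph    <- generate_phantom(cfg, truth)
fit   <- vessel_dynamics(ph$images, ph$lung_truth, ph$vessel_truth)
summary(fit)
```

```
Dynamic vessel analysis
  250 frames, dt = 0.384 s, high-pass cutoff 0.6 Hz
  cv_vessel_area    3.12 %
  cv_lung_area      8.02 %
  cv_vessel_signal  3.92 %
  se_delay          39.6 % of RR-interval
  heart_rate        71.9 min^-1
  115 signal peaks, 115 area peaks, mean RR 0.834 s
```

The analysis recovers the generative parameters: vessel-area CV 3.12% vs.
the 3% target, lung-area CV 8.02% vs. 8%, SE-delay 39.6% vs. 40% of RR, and
heart rate 71.9 vs. 72 bpm. Replacing the truth masks with the classical
baselines (`vessel_dynamics(ph$images)`) runs the full
segment-then-analyse pipeline; `plot(fit)` draws the filtered signal and
area curves with the detected systolic peaks, and `write_metrics(fit,
"metrics.json")` serialises the parameters with their units.

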