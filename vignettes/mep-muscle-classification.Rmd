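---
title: "Classifying motor evoked potentials by muscle: models and methods"
author: "mepmuscle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying motor evoked potentials by muscle: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mepmuscle)
```

# The problem

During supratentorial neurosurgery, motor evoked potentials (MEPs) are
recorded from several muscles at once — typically extensor digitorum (EXT)
and abductor pollicis brevis (APB) on the arm, tibialis anterior (TA) and
abductor hallucis (AH) on the leg. A mislabeled electrode can silently turn
a clinically meaningful signal change into a false alarm, or hide a real
one. `mepmuscle` implements a supervised-learning pipeline that asks: given
a single 100 ms recording window, which muscle produced it?

The pipeline has five stages, each an exported module:

1. **Synthetic cohort generation** (`generateCohort`) — patient EMG is
   protected data, so the package ships a calibrated simulator.
2. **Preselection** (`preselectCohort`) — decide which windows contain an
   MEP at all, remove the stimulation-artifact segment, and normalize per
   patient (`normalizePatients`).
3. **Representation** — raw 1650-sample traces, PCA scores at 95%
   explained variance (`fitPca`/`applyPca`), or 7 engineered features
   (`extractFeatures`).
4. **Learning** (`runExperiment`) — patient-disjoint 28:8 split, SMOTE
   class balancing, grid-search tuning by stratified cross-validation, and
   three classifier families (random forest, k-nearest neighbors, ridge
   logistic regression) over three muscle-comparison paradigms.
5. **Evaluation** — accuracy, macro F1, macro one-vs-rest ROC AUC,
   row-normalized confusion matrices, and limb-level aggregation
   (`extremityReport`).

# Signal model of the synthetic generator

Each window is 100 ms at 20 kHz (2000 samples) and is the sum of three
components:

* **Stimulation artifact train.** Five alternating-sign triangular pulses,
  2 ms apart starting at 2 ms, with amplitude well above the MEP scale.
  All pulses lie before 17.5 ms (sample 350), the cutoff the preselection
  stage removes; their only role is to exercise that logic.
* **MEP complex** (absent in *blank* windows). One to three damped-cosine
  bursts `exp(-t/tau) * cos(2*pi*f*t)`. The first burst starts — at its
  first peak — at the onset latency `L`, drawn from a normal distribution
  truncated to `[17.5, latMaxMs]` ms. Subsequent bursts follow at ~5–7 ms
  gaps with amplitude fractions U(0.35, 0.7). The whole complex is rescaled
  so its peak-to-peak size equals the drawn amplitude, then multiplied by
  the patient gain.
* **Baseline noise.** White Gaussian noise smoothed with a 3-sample moving
  average (a crude stand-in for a band-limited recording chain) and
  rescaled to `noiseSd`.

A lognormal per-patient gain (log-SD 0.4) models electrode placement and
anesthesia differences. Because the gain multiplies the whole trace and
normalization later divides by a per-patient maximum, it cancels
downstream by design; it matters only for workflows that skip
normalization.

## What the generator is calibrated to

The per-muscle defaults in `muscleDefaults()` were fixed once by iterative
large-n simulation so that the **post-preselection, per-patient-normalized
cohort statistics** reproduce the reference summary the pipeline is built
around:

| muscle | mean normalized amplitude | mean first-peak latency (ms) | median peaks |
|--------|--------------------------:|------------------------------:|-------------:|
| EXT    | 0.09 | 17.53 | 1 |
| APB    | 0.34 | 20.01 | 2 |
| TA     | 0.20 | 24.69 | 2 |
| AH     | 0.11 | 31.03 | 2 |

Three design choices deserve explanation:

* **Amplitudes are lognormal with a saturation cap** (`ampCapSds` log-SDs
  above the log-mean). The normalization denominator is a per-patient
  *maximum*, so the upper tail of the amplitude distribution — not its
  mean — sets the scale of every normalized quantity. A light-tailed
  (truncated-normal) amplitude law cannot push the patient maximum far
  enough above the bulk to reproduce a mean normalized APB amplitude of
  0.34; an uncapped lognormal pushes it too far and makes the denominator
  extremely variable. The capped lognormal interpolates, and the cap
  stabilizes the denominator across patients.
* **EXT latency sits at the cutoff.** A mean first-peak latency of
  17.53 ms, only 0.03 ms above the 17.5 ms detection cutoff, forces the
  truncated latency distribution into its extreme-truncation regime, where
  the post-truncation law is nearly exponential with both mean excess and
  SD ≈ 0.03 ms. No distribution bounded at 17.5 ms can simultaneously
  have mean 17.53 ms and an SD of several milliseconds, so the generator
  matches the means and lets the SDs fall where the truncation puts them.
* **Class imbalance comes from blank windows.** Lower-extremity muscles
  are stimulated near threshold more often, so TA/AH windows are blank
  (no MEP) at rates of ~0.69/0.71 versus ~0.02/0.28 for EXT/APB. Blanks
  are rejected by the preselection gate, reproducing per-muscle
  preselection survival near the reference ratios
  (0.75/0.71/0.30/0.21) and the downstream imbalance the learning stage
  has to cope with.

The calibration itself exploits two structural facts: normalized
amplitude means are invariant under a global amplitude rescaling (so
per-muscle scales only set the *ratios*, and the saturation cap sets the
*level*), and the measured first-peak latency equals the drawn onset up
to grid rounding (so the underlying location parameter can be solved for
each target mean directly).

## What the generator does not model

Acquisition cadence (real MEPs arrive irregularly over hours of surgery),
volume conduction between muscles, anesthetic drift within a patient,
hardware filter ringing, powerline or cautery interference, and any
amplitude–latency correlation. Passing the package's tests on synthetic
cohorts therefore demonstrates that the *pipeline* is correct and that the
classes are separable under the calibrated statistics — it does not
certify classifier accuracy on real intraoperative data, and the headline
accuracies reported on the original patient cohort are deliberately not
asserted anywhere in this package.

# Preselection

A window is assumed to contain an MEP if the rectified trace has between 1
and 10 peaks after 17.5 ms with topographic prominence above 2 standard
deviations of the rectified post-cutoff segment. Numerical conventions,
fixed so the 350-sample cutoff is unambiguous:

* sample indices are 0-based; `time_ms = index / 20` at 20 kHz;
* peaks are found on the **whole** rectified trace and then filtered to
  `index >= 350`, so a burst landing exactly on the cutoff sample is still
  eligible (on the cut segment alone it would be a boundary sample and
  invisible);
* the prominence threshold uses only the post-cutoff segment, because the
  artifact train would otherwise dominate the SD and silence real peaks;
* plateau maxima take the leftmost sample; a constant post-cutoff segment
  (SD 0) yields no peaks and the window is rejected as `no_peaks`.

Rectification makes both polarities count. Blank windows are rejected in
practice because rectified noise has *many* small prominent maxima — far
more than 10 — while a genuine burst inflates the SD threshold above the
noise prominences.

Accepted windows are cut to samples 350–1999 (dimension 1650) and then
divided by the patient's largest rectified sample over all accepted
traces, across muscles (the natural reading of normalizing by "each
patient's highest peak MEP value"; a per-(patient, muscle) denominator is
the plausible alternative and would change the amplitude scale of every
muscle except the dominant one). After normalization the per-patient
maximum is exactly 1.

# Features

`extractFeatures` computes, per accepted trace: onset latency, first-peak
latency, end of signal, maximum, minimum, rectified trapezoidal AUC
(units × ms), and the number of detected peaks — 7 values.

* **Onset latency**: first sample at/after the cutoff deviating from the
  baseline mean by more than 2 baseline SDs, where the baseline is the
  final 20 ms of the window. The SD is the *baseline segment's* (the
  whole-trace alternative would let the MEP inflate its own detection
  threshold). With a zero baseline SD, the first nonzero deviation is the
  onset. A trace that never leaves the band has its onset imputed at the
  cutoff (and the imputation counted), keeping the feature matrix
  rectangular.
* **End of signal**: the onset latency of the time-reversed trace mapped
  back to forward time — effectively the last excursion beyond the band
  defined by the reversed trace's terminal segment. The alternative
  reading ("inverse" as negated signal) would measure the onset of the
  negative phase, not an end, and is rejected. Undefined ends are imputed
  at the window end.
* **Peak latency** is stimulus-relative (measured from the window origin),
  not onset-relative, and comes from the preselection record so the
  full-window peak context is retained.

PCA (`fitPca`) retains the smallest number of mean-centred components
reaching 95% cumulative explained variance, always fitted on training rows
only.

# Learning

* **Split**: whole patients are assigned at random, 28 training / 8 test;
  no patient contributes to both sides. Two-muscle paradigms (EXT vs APB
  within the arm; EXT vs TA across limbs) are built by dropping rows of
  the *same* split, never by re-splitting.
* **SMOTE**: every training class is raised to the majority count with
  synthetic rows `x + u (z - x)`, `u ~ U(0,1)`, `z` one of the `k = 5`
  nearest same-class neighbors. Balancing happens strictly on the training
  side, after the split and per representation.
* **Tuning**: exhaustive grid search scored by mean stratified k-fold CV
  accuracy, ties broken by first-in-grid order. The shipped grids (random
  forest: trees {100, 300, 500} × depth {unbounded, 10, 20}; kNN: k {1,
  3, 5, 11, 21} × {euclidean, manhattan}; ridge logistic regression:
  lambda {1, …, 1e-4}) are declared substitutes bracketing common
  implementation defaults — the original study's exact grids are not
  public.
* **Models**: random forest via `ranger` (score = tree-vote fractions),
  kNN on explicit cross-distances (score = neighbor-vote fractions; this
  in-package implementation exists because no installed kNN exposes full
  per-class vote vectors under both metrics), and ridge-penalized
  logistic/multinomial regression via `glmnet` (score = model
  probabilities; fitted along a short decreasing lambda path because
  single-lambda fits are unreliable, with convergence notes logged rather
  than fatal).

# Evaluation

Accuracy is exact rational arithmetic; macro F1 uses per-class one-vs-rest
`2TP/(2TP+FP+FN)` with the zero-division convention F1 = 0; ROC AUC is the
rank (Mann–Whitney) statistic with ties counted half, macro-averaged
one-vs-rest for multiclass — the convention is recorded in every report
because the alternative (one-vs-one) is not distinguishable from the
published scores. Confusion matrices are counts, optionally row-normalized
and rounded; limb-level aggregation sums the four muscle cells into a
2×2 UPPER/LOWER matrix, conserving totals. Limb accuracy can only gain
from within-limb confusions, so it is never below muscle accuracy.

# Problem sizes and reproducibility

Default cohorts are 36 patients × (112, 137, 134, 112) windows per muscle
(~17.8k windows, ~8.8k surviving preselection), echoing the reference
cohort's counts. The bundled experiment runs and tests use deliberately
smaller configurations — a 36-patient cohort at roughly one fifth of the
default trace counts, the reduced grids of `defaultGrids(reduced = TRUE)`
and 3-fold tuning — sizes chosen so a complete 27-cell experiment remains
a desk-scale computation while still exceeding chance in every cell.
Calibration checks use two pooled default cohorts (≥ 5000 preselected APB
traces) and compare means within three Monte-Carlo standard errors,
computed with patient-level clustering (per-patient normalization makes
amplitudes within a patient correlated, so the naive iid SE would be too
small).

Everything is reproducible from `(config, seed)`: one global seed is
expanded into per-stage seeds by `deriveSeed()` (a documented integer
derivation), so stages can be rerun in isolation. `runPipeline()` persists
the configuration, its MD5 hash, per-stage counts, rejection logs, feature
tables, tuned parameters and the score summary.

# Known limitations

* Synthetic realism is limited to the statistics the pipeline consumes
  (see above); directional claims — which algorithm wins, how much feature
  engineering rescues logistic regression — depend on the real data's
  structure and are reported but never asserted.
* Reference-scale SDs of amplitude and AUC are echoed only approximately;
  the latency SDs cannot be matched at all given the 17.5 ms bound (the
  EXT row is internally inconsistent with that bound).
* EDF support covers the classic 16-bit EDF layout used by the archive
  convention (one channel per patient–muscle pair, one window per data
  record); EDF+ annotations and vendor formats are out of scope.
* No digital band-pass filtering is applied anywhere; emulating the
  hardware filter chain is deliberately left out.
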