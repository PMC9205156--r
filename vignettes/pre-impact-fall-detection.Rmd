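---
title: "Cohort-specific pre-impact fall detection from wearable IMUs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cohort-specific pre-impact fall detection from wearable IMUs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Wearable airbags mitigate fall injuries by inflating *before* ground impact.
The embedded detector must classify a fall from inertial data early enough to
leave the hardware its lead time — the interval between the deploy decision
and the impact — and it must do so for the population actually wearing the
device.  Post-stroke individuals fall often and fall differently (impaired
postural control, asymmetric gait, weaker compensatory stepping), so a
detector trained on able-bodied movement may miss their falls.  `prefall`
implements the full analysis pipeline for studying this question: how much
does cohort-specific training data matter for pre-impact fall detection, and
how do non-fall composition, impairment severity and the lead-time parameter
shape the answer?

Because raw recordings from such studies are rarely redistributable, the
package pairs the analysis stages with a parametric synthetic generator whose
defaults define the reference study design: 20
stroke subjects (5 labelled unstable ambulators) and 15 controls; 842 falls
(610 lateral, 232 anterior–posterior) and 961 non-falls (562 activities of
daily living, 399 near-falls); three pelvis-worn IMUs (each ±16 g
accelerometer and ±2000 deg/s gyroscope) sampled at 500 Hz.  Every event
count, label and kinematic parameter is ground truth, so each downstream
stage can be tested against construction.

## Pipeline

1. **Simulate** (`generate_cohort_dataset()`): per-subject 18-channel
   recordings containing the requested events in randomised order.
2. **Preprocess** (`filter_recording()`, `detect_impact()`,
   `extract_fall_window()`, `extract_nonfall_window()`): band-pass filter the
   accelerometer channels, locate the impact, cut the evaluation windows.
3. **Features** (`build_feature_matrix()`): 7 statistics per channel over
   each 250-frame window — 126 features per event.
4. **Evaluate** (`evaluate_loso()`, `evaluate_control_trained()`,
   `evaluate_logo_severity()`, `lead_time_sweep()`): adaptive-boosting
   classifiers under subject-disjoint schemes.
5. **Compare** (`compare_models()`): paired two-tailed t tests per metric and
   fall family with Holm–Bonferroni family-wise error control.

`run_experiment()` chains the stages and stamps every artifact with a
configuration hash and the master seed, so a rerun reproduces identical CSVs.

## Windowing and lead time

With impact frame $t_p$, lead time $t_l$ and window length $w = 250$ frames
(500 ms at 500 Hz), the evaluation window spans

$$t_s = t_p - t_l - w, \qquad t_e = t_p - t_l,$$

half-open $[t_s, t_e)$ with 0-based frames.  Milliseconds convert to frames
by `ceiling(t_l / 2)`, so the realised lead is never shorter than requested —
the conservative choice for a deploy decision (75 ms, the device's minimal
lead, becomes 38 frames rather than 37.5).  The impact frame is
operationalised as the maximum filtered acceleration-vector magnitude across
the three sensors within the event region, ties resolving to the earliest
frame; on synthetic falls this recovers the generator's ground-truth impact
within 50 ms for well over 95% of events.  Non-fall windows are drawn
uniformly from the latter half of the event region, where the movement is
nearest its maximal instability; regions shorter than one window are used
clipped to their first 250 frames, and events whose fall window would start
before the recording begins are excluded and logged rather than silently
dropped.

## Filtering: what zero-phase costs

Accelerometer channels pass through a fourth-order 0.1–50 Hz band-pass
Butterworth design, applied forward–backward (zero-phase) because the
analysis is offline.  Gyroscope channels are left raw.  Two numerical
points deserve record:

* **DC and the 0.1 Hz edge.**  The high-pass edge settles over roughly 10 s,
  the length of a typical recording segment, so a step (the gravity offset)
  rings through the whole record if filtered naively; we subtract the series
  mean before filtering, which is exact for a zero-DC-gain band-pass and
  removes the transient entirely.
* **Acausal bleed.**  Forward–backward filtering smears the impact spike
  *backward* in time through the slow 0.1 Hz pole: windows that end well
  before the impact still carry a low-frequency residue of it.  This is a
  property of any zero-phase offline pipeline, not of the generator.  It
  inflates long-lead separability slightly, which is why the lead-time-sweep
  study condition (`config_short_signature()`) uses moderate impact peaks and
  a noise floor above the bleed amplitude; a deployed (causal) detector would
  not see this information, and the package treats causal filtering as the
  relevant deployment caveat.

## Features

Seven statistics per channel — min, median, max, interquartile range,
standard deviation, skewness, kurtosis — over 18 channels give 126 named
features (`{location}_{modality}_{axis}_{stat}`, C-locale sorted for a stable
column order).  Conventions are centralised in one routine: sample standard
deviation ($n-1$), biased Fisher–Pearson skewness, excess kurtosis
(normal → 0), linearly interpolated quartiles, and skew = kurtosis = 0 for
zero-variance channels.  These conventions are choices, not facts inherited
from any particular prior implementation, and tests pin them to direct
textbook formulas.

## The classifier

The detector is adaptive boosting (SAMME) over depth-1 decision stumps, 50
rounds at learning rate 1 — the configuration standard in this literature.
No installed R package provides AdaBoost, so the package implements it with
an exact vectorised weighted-stump search: every round evaluates the weighted
error of every feature, threshold midpoint and polarity via cumulative sums
over cached sort orders, taking the global minimiser with deterministic
tie-breaks (lowest feature index, then lowest threshold).  Training is
therefore fully deterministic; the `seed` argument exists only for interface
symmetry.  A perfect stump ends boosting (it decides alone); a round that
cannot beat chance ends it too.  The continuous decision score is the
alpha-weighted stump vote normalised to $[-1, 1]$; ROC curves and AUC are
built from this score, never from hard labels.  Tests verify the first-round
stump against a brute-force enumeration oracle and the AUC against pairwise
Mann–Whitney concordance.

## Evaluation schemes

* **LOSO (stroke-trained):** each stroke subject held out once, the model
  trained on the remaining stroke subjects.
* **Control-trained:** one model on all control rows, tested per stroke
  subject, so iterations pair one-to-one with LOSO.
* **LOGO (severity-stratified):** 5-subject stroke subgroups labelled by
  their count $k$ of unstable ambulators; the stroke model trains on the
  stroke subjects outside the subgroup, the control model on all controls.
  With 5 unstable / 15 other subjects there are 100 sampled subgroups for
  $k \le 3$ and exhaustively 75 and 1 for $k = 4, 5$.

Subject-level train/test disjointness is asserted inside every scheme.
Undefined metrics are flagged, not forced: precision when nothing is
predicted positive, recall without true falls, AUC on single-class test
sets.  Flagged values are excluded from report means and from paired tests
(pairwise-complete deletion), with defined-iteration counts logged — the
alternative (imputing 0 or 1) would bias small single-subject test sets.

## Statistics

Model pairs are compared by two-tailed paired t tests on per-iteration
metrics, one test per fall family (all / lateral / AP), and the
Holm–Bonferroni step-down applied within each metric's three-test family:
sort the P values ascending and reject while
$P_k < \alpha / (m + 1 - k)$, stopping at the first failure.  One could read
the procedure's prose description elsewhere as an ascending scan that turns
significant at the first satisfied inequality; the step-down implemented here
is the standard Holm procedure and the only reading that controls the
family-wise error rate, which tests verify by brute force and by simulation.
All-zero paired differences give P = 1; constant nonzero differences (possible
with discrete metrics on tiny test sets) have no within-pair variance and are
reported as NA and treated as non-significant — conservative under the null.

## The generator

Falls follow four phases: **instability** (angular velocity about the fall
axis growing at `instab_growth_dps`, roll-dominant for lateral and
pitch-dominant for AP falls, with the gravity vector tilting accordingly),
**descent** (acceleration magnitude ramping from 1 g to `descent_min_g` as
the body approaches free fall while the tilt completes), **impact** (a
20–60 ms spike reaching exactly `impact_peak_g`, capped at the 16 g sensor
range) and **rest** (static ~1 g in the terminal orientation).  Near-falls
share the instability phase, then a compensatory burst scaled by `comp_gain`
and a recovery to upright.  ADLs are template-based: walking at the
subject's gait frequency with hip-asymmetry modulation, sitting,
lying (static), sit-to-stand, and jumping — a deliberate hard negative with
a sub-1 g flight phase and a landing spike.  Quiet standing between events
is the same static-plus-noise process as static ADLs, so windows without
event signal are genuinely uninformative.

Stroke defaults differ from control in gait speed (0.88 vs 1.22 m/s, the
study's cohort means), cadence, asymmetry, instability duration and onset,
descent depth and compensatory gain; magnitudes are free parameters of the
generator, not estimates of any real cohort.  Severity (`unstable`) shifts
the same parameters further.  Two per-direction parameters —
`ap_tilt_gain`/`ap_gyro_gain` and their lateral twins — interpolate between
topple-type falls (full rotation) and collapse-type falls (vertical sinking
with little rotation until impact); they exist because a cohort effect that
only rescales one amplitude is recoverable from the shared rotation
signature, whereas altered fall initiation (e.g. over the paretic side)
plausibly changes the kinematic shape itself.

Randomness: one master seed; per-subject parameter and signal streams are
derived deterministically from it (subject-index hashing), so a subject's
data do not change when dataset-level counts do.  Identical configuration
and seed reproduce the dataset bit for bit.

### What the generator does not emulate

Real IMU turbulence, soft-tissue artefact, sensor bias drift and the
within-subject variety of natural falls are absent; waveforms are smooth
templates plus white noise.  Passing tests therefore demonstrate that the
*pipeline* recovers what the generator planted under realistic event
structure — not that any particular accuracy would be attained on real
recordings, whose headline performance this package makes no claim to
reproduce.

## Calibration and effect-recovery study conditions

The package ships four named generator configurations used by its
acceptance studies; their cohort sizes (5–8 subjects per cohort, 8–12 events
per subject) keep a replicate in the low seconds so hundreds can run per
study, while preserving the design's structure (both cohorts, both fall
directions, ADLs and near-falls, at least two repetitions per subtype).

* `config_null_calibration()` draws both cohorts from identical
  distributions and hardens the task (shallow descent, damped rotation,
  strong noise) so per-iteration metrics vary; across 200 replicates the
  Holm-corrected family-wise rejection rate of the cohort comparison stays
  at or below the nominal level.
* `config_planted_ap()` makes stroke AP falls collapse-type while drawing
  everything else cohort-identically; the stroke-trained model's recall
  advantage on AP falls appears in the large majority of replicates, and
  lateral falls — generated cohort-identical — show no such gap.
* `config_severity_gradient()` concentrates the altered signature in
  unstable ambulators; control-trained recall decreases monotonically in the
  number of unstable members of the LOGO test subgroup.
* `config_short_signature()` compresses instability and descent to roughly
  the final 300 ms before impact with static ADL negatives, so only
  short-lead windows see fall signal; the sweep's AUC at 50 ms lead is at
  least that at 500 ms.

## Known limitations

* The boosting implementation is binary and stump-based; deeper base
  learners would require a different search.
* The severity label is generator-assigned; `derive_severity_labels()`
  offers a surrogate re-derivation (gait speed and lower-trunk angular
  range thresholds) but no clinical criterion.
* Zero-phase filtering leaks post-window impact energy backward (see above);
  deployment-grade evaluation should re-run with causal filtering.
* Performance numbers obtained on synthetic cohorts characterise the
  pipeline, not any device or population.
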