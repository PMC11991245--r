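---
title: "Methods: T-wave morphology parameterization and LQT3 discrimination"
author: "lqtmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: T-wave morphology parameterization and LQT3 discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lqtmorph)
```

## The problem

Long QT syndrome (LQTS) is an inherited channelopathy with delayed
ventricular repolarization. Its three principal genotypes differ in their
arrhythmia triggers: LQT3 events cluster around rest and sleep, and
beta-blockade — protective in LQT1/LQT2 — is of debatable value for LQT3
carriers. Separating LQT3 from LQT1/LQT2 on the surface ECG is therefore
clinically useful, and repolarization morphology carries genotype
information: a broad-based T-wave is typical of LQT1, a low-amplitude,
often bifid T of LQT2, and a long isoelectric ST segment followed by a
late, narrow, peaked T of LQT3.

`lqtmorph` implements an end-to-end pipeline for this discrimination task
from long single-lead ECG recordings (nominally Lead I at 200 Hz): resting
segment selection, geometric parameterization of the ST-T complex,
nonparametric selection of a feature triad, and a class-weighted
Gaussian-kernel SVM with exact Shapley attribution. Because the clinical
Holter database the method was developed against is access-restricted, the
package includes a genotype-conditioned synthetic generator that emits
records with ground-truth fiducials, so that every stage is testable.

## Resting segment selection

Only signal between 10:00 and 20:00 wall-clock time is considered
(half-open window, `[10:00, 20:00)`). The LF/HF sympathovagal ratio is
computed in sliding windows of 200 beats advanced by 100 beats; windows at
or below the empirical 25 % quantile of LF/HF are declared resting,
overlapping or adjacent resting windows are merged into maximal resting
sections, and from the two most extended sections (ties to the earlier
start) the 60 beats centred on the section's floor midpoint are kept.

The LF/HF recipe is fixed and normative for this package: RR intervals
outside [0.3, 2.0] s are excluded; the tachogram is linearly detrended,
resampled at 4 Hz by cubic spline, and analyzed with a Welch periodogram
(64-s Hann segments, 50 % overlap); LF is the trapezoidal band power over
0.04–0.15 Hz and HF over 0.15–0.40 Hz. Fixing the recipe makes window
ranking deterministic and testable; any consistent PSD estimator would
order windows the same way for the band-limited modulations of interest.
Two rules the underlying study leaves open are decided here explicitly:
resting windows merge when their beat ranges overlap or abut, and the
"middle" of a section is its floor midpoint with the segment spanning
`[mid − 30, mid + 30)` beats.

## Fiducials and delineation

All features are computed on per-beat fiducials (R peak, QRS end, T onset,
T apex, T offset; 0-based sample indices; durations are index differences
divided by the sampling rate). The pipeline consumes fiducials from a file
— the intended path when an external delineator is available — or from a
deliberately simple baseline delineator: QRS end is the first point after
R where the absolute slope stays below 10 % of the maximal QRS slope for
at least 20 ms; the T apex is the extremum of the baseline-subtracted
amplitude in `[QRS_end + 80 ms, next R − 160 ms]`; T onset and offset come
from the tangent method (maximum-slope tangent of each flank intersected
with the QRS-end baseline). Beats whose T window stays within twice the
local noise floor are excluded.

Note that threshold-based and tangent-based onset definitions differ
systematically: for a Gaussian flank of width sigma the tangent crosses
the baseline two sigmas before the apex, whereas a 1 % amplitude threshold
(the synthetic generator's ground-truth convention) crosses at about 3.03
sigmas. Delineation accuracy is therefore asserted against each rule's own
analytic construction; the pipeline is internally consistent as long as
one convention is used throughout a study, which is also why the two
sources of fiducials are never mixed within a record.

## The 20 morphology features

Group A (times/amplitudes): `tDuration`, `tDurationUp`, `tDurationDown`,
`stDuration`, `st_rrRatio`, and `stRise_perc = (A(T_on) − A(QRS_end)) /
(A(T_peak) − A(QRS_end))`.

Group B (sign-clipped rectangle areas, mV·s): each limb is shifted so its
outer anchor sits at zero — `tAreaUpc` over `[T_on, T_peak]` with the
T-onset amplitude as baseline, `tAreaDownc` over `[T_peak, T_end]`
anchored at the T offset, `stAreac` over `[QRS_end, T_on]` anchored at QRS
end — values on the wrong side of the baseline are clipped to zero, and
rectangles of width 1/fs are summed walking outward from the peak-side
endpoint. Signs follow the T polarity (for the T areas) or the ST
direction (for `stAreac`). `tAreac` is the sum and `tAreacUpDownRatio`
the quotient of the two T areas. Two decisions where the construction is
underdetermined: the descending baseline is the T-offset amplitude
(mirroring the ascending construction on its own anchor), and rectangle
anchoring at the peak-side sample — any Riemann variant differs by one
rectangle, i.e. O(1/fs), which is the tolerance the tests use.

Group C (unit-circle transform): a limb between an anchor fiducial and
the T apex is mapped affinely so the anchor lands at (−1, 0) (ascending)
or (1, 0) (descending), the point (time of apex, anchor amplitude) at
(0, 0), and the apex at (0, 1). The area under the transformed curve
(`oneAreaUp`, `oneAreaDown`, and `oneSTTAreaUp` for the whole ST-T ascent
anchored at QRS end, plus their ratios) is then a pure *shape* descriptor
— a measure of convexity/concavity invariant to amplitude gain/offset and
to uniform time dilation, hence largely rhythm-independent. A linear limb
gives exactly 1/2; a circular-arc limb gives pi/4.

Group D (rates): the three T areas and the ST area divided by their own
durations, suppressing residual RR influence.

Per beat, every feature of a negative-polarity T (apex below onset) is
replaced by its absolute value; per signal, the 20 % of beats with the
highest RMSE against the R-aligned, length-normalized mean-beat template
are discarded (`ceil(0.2 n)`, no filtering below 5 beats), features are
averaged over the retained beats with missing ratios excluded pairwise,
and when several resting segments are available the one retaining the
most beats is kept (tie to the first) — a deterministic replacement for
manual best-signal selection.

## Feature selection

Discrimination of LQT3 against the pooled LQT1+LQT2 group uses the
two-sided Wilcoxon rank-sum test (exact enumeration for small groups,
which stays exact under ties; tie-corrected normal approximation with
continuity correction otherwise). Features with p < 0.005 are candidates;
they are ordered by ascending p (ties to the larger absolute median
difference, then name), and accepted greedily while the absolute Spearman
rank correlation with every accepted feature stays below 0.6, stopping at
three. Greedy acceptance is the minimal reading of "most discriminating
uncorrelated triad"; an exhaustive search over triads is deliberately out
of scope. No multiple-testing correction is applied — the screening
replicates the source methodology rather than improving on it. Selection
operates on the full feature table (as in the source study's statistical
analysis); only classifier fitting and evaluation respect the train/test
split, a leakage caveat worth remembering when interpreting test metrics.

## Classification and explanation

The classifier is a soft-margin SVM with kernel
\(K(x, x') = \exp(-\lVert x - x' \rVert^2 / KS^2)\) — the kernel scale
divides the distance, so the usual radial-kernel parameter is
\(\gamma = 1/KS^2\); this convention is stated explicitly because
implementations differ by a factor of two. Features are standardized on
the training split (kernel scales near 1 presuppose standardized inputs).
Class imbalance is handled by weighting the per-example box constraint:
the LQT3 weight is `(n_LQT1 + n_LQT2) / n_LQT3`, rounded to one decimal
(9.3 for a 137/58/21 training cohort; the balanced LQT3 count is then
`round(21 × 9.3) = 195`). Hyperparameters come from a grid search —
C over {0.25, 0.5, 0.8, 1, 1.3, 2, 4}, KS over {0.5, 0.7, 0.9, 1.1, 1.2,
1.3, 1.5, 2}, centred on the configuration the method's development
identified as optimal (C = 1, KS = 0.9) — scored by weighted 5-fold CV
accuracy on random non-stratified folds fixed by the seed, ties to the
smaller C then smaller KS.

Evaluation weights LQT3 test examples by the test-cohort weight
(`(68 + 28)/10 = 9.6` for the reference test table): precision and
accuracy respond to the weight while recall, being class-internal, does
not. The ROC sweeps the decision threshold over the weighted samples and
the AUC is the trapezoidal area — one concrete choice for a
"weighted AUC", flagged as such.

Explanation uses exact interventional Shapley values: with three features
all \(2^3\) coalitions are enumerated, the value of a coalition being the
mean decision score over background rows with the coalition's features
fixed to the explained row. Local accuracy
\(\sum_i \phi_i = f(x) - v(\emptyset)\) holds to machine precision, and
the symmetry and dummy axioms are asserted in tests. The interventional
(rather than path-dependent) expectation is a documented choice. Reports
give the mean absolute \(\phi\) per feature, grouped by predicted class.

## The synthetic generator

`generateCohort()` emits genotype-conditioned records with ground truth:

* **Morphology.** Each beat is a stylized QRS (R spike with Q/S dips, QRS
  end fixed 35 ms after R), an ST segment of the drawn duration rising
  smoothly to a small ST amplitude (`stRiseMv`), and a T-wave with
  generalized-Gaussian flanks. Flanks are parameterized by their
  1 %-threshold width (so `tDurationUp`/`tDurationDown` are exact
  construction quantities) and a per-subject convexity exponent (2 =
  Gaussian) drawn without genotype dependence — wave *shape* varies
  independently of wave *width*, as it does across real subjects. LQT2
  adds a second hump (bifid T) 60 ms after the first at 75 % amplitude.
  Ground-truth fiducials are the exact construction points, with T
  onset/offset at the 1 % envelope threshold — an unambiguous,
  resolution-independent convention.
* **Archetypes.** LQT1: short ST (0.050 ± 0.045 s), broad T (ascending
  width scale 0.075 s), amplitude 0.33 mV. LQT2: low amplitude
  (0.15 mV), bifid. LQT3: long ST (0.155 ± 0.060 s), late narrow T
  (0.038 s), amplitude 0.42 mV, slightly higher ST rise (0.036 mV vs
  0.016 mV). The between-subject spreads are deliberately wide enough
  that genotypes overlap — mirroring the documented partial overlap of
  LQT1 and LQT3 repolarization patterns — so that the statistical stages
  face a realistic rather than trivially separable cohort. The spreads
  were calibrated once against the package's own design requirements
  (rank-sum separation of `stAreac` and `tDurationUp` at p < 0.005 for 20
  subjects per genotype; mutual Spearman correlation of the designed
  triad below 0.6) and then frozen.
* **Rhythm.** RR intervals follow
  \(RR(t) = RR_0 + a_{LF}\sin(2\pi\,0.1\,t) + a_{HF}\sin(2\pi\,0.25\,t)\)
  plus small white jitter, alternating 350-beat active blocks (base RR
  0.85 s, LF/HF target 5) and resting blocks (base RR 1.0 s, LF/HF target
  0.3); the amplitude split is chosen so the band-power ratio matches the
  regime's target. Records are stamped with a start clock inside
  10:00–20:00.
* **Noise.** Additive white Gaussian noise, default sd 0.02 mV.
* **Determinism.** One RNG stream per cohort, seeded once; identical
  specs give bitwise-identical cohorts.

Default study conditions are 40 records per genotype, 0.25 h per record
at 200 Hz (roughly 950–1000 beats, giving 8 LF/HF windows of which the
resting block supplies the lowest quartile). These sizes keep a ten-seed
end-to-end run comfortably within a few minutes while leaving every
stage's preconditions (200-beat windows, 60-beat segments, 5-fold CV)
non-degenerate.

What the generator does **not** emulate: ectopy and arrhythmia, baseline
wander and electrode artefacts, notched/flat T-waves beyond the bifid
archetype, QT-interval dynamics, and any within-genotype clinical
covariates. Passing synthetic tests therefore demonstrates that the
pipeline recovers the designed morphological contrasts under realistic
noise and rhythm variability — not that it reproduces clinical accuracy
on real Holter data, which would require the restricted source database.

## Numerical choices and degenerate inputs

* Fiducials are 0-based; index arithmetic uses half-open intervals while
  durations use closed-endpoint index differences over fs.
* `clippedRectArea` tolerances are one rectangle (O(1/fs)); convergence
  to the analytic integral is asserted at fs ∈ {100, 200, 1000}.
* Zero denominators (flat T, vanished descending area, zero durations)
  yield `NA` for the affected per-beat feature, excluded pairwise from
  the signal mean; an entirely degenerate signal is excluded with a log
  entry.
* Zero HF power reports LF/HF as `Inf` with a warning; such windows can
  never fall below the rest quantile.
* Exact rank-sum enumeration is used when both groups are smaller than 9
  and the assignment count is feasible (≤ 2·10^5); tests compare it
  against a brute-force oracle for all group sizes with n ≤ 10.

## Worked example

```{r example, eval = FALSE}
cfg <- defaultPipelineConfig(seed = 1)
res <- runPipeline(cfg)
selectedTriad(res$selection)
res$report
```

The README shows the output of this exact run.
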