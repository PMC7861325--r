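---
title: "Classifying vigilance impairment from eye- and face-tracking indices"
author: "vigileye"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying vigilance impairment from eye- and face-tracking indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vigileye)
```

## The problem

Sustained wakefulness degrades vigilant attention long before an operator
notices. The laboratory standard for quantifying that degradation is the
psychomotor vigilance task (PVT): a 10-minute reaction-time test in which a
stimulus appears at random 2–10 s intervals and the subject responds as
fast as possible. Responses slower than 500 ms are *lapses*, responses
slower than 1000 ms are *major lapses*, and responses without a stimulus
are *false starts*.

`vigileye` implements a complete analysis pipeline for the question: can
remote, camera-based measurements — blink and fixation behaviour from an
eye tracker, and the 21 facial action-unit/affect/head-pose channels a
webcam expression engine exports — classify a person's PVT performance as
*normal* or *impaired*? The pipeline covers:

1. a synthetic-study generator with known ground truth,
2. extraction of 25 predictive indices per session (4 eye-tracking,
   21 facial),
3. PVT scoring and per-subject normalization,
4. a group-level impairment threshold from session statistics,
5. per-index class statistics (Welch *t*, Fisher score),
6. five feature-selection regimes, and
7. a 14-classifier leave-one-subject-out (LOSO) evaluation grid.

Because raw recordings of this kind are rarely public, the generator is a
first-class, tested component: every downstream stage is exercised against
data whose true impairment structure is known.

## The synthetic study

The default design mirrors a sustained-wakefulness protocol: 20 subjects,
13 PVT sessions at two-hour spacing starting one hour after waking (1 h to
25 h awake), 10-minute sessions, gaze sampled at 50 Hz, facial channels at
30 Hz, and about 3% of subject-sessions lost to technical malfunction.
Session 1 is flagged for exclusion to avoid task-learning effects.

Ground truth is an impairment *drive* per session: zero before the
subject's onset (default 17 h awake), then increasing by one unit per
session. The drive moves every signal in the direction sleep-deprivation
studies report:

* **Reaction times.** The RT body is lognormal with a median near 280 ms —
  the standard alert-PVT shape; no distributional form is identifiable
  from threshold counts alone, so only the threshold-crossing behaviour
  matters downstream. A lapse mixture adds mass above 500 ms with
  probability `min(1, base + slope × drive)`; part of that tail crosses
  1000 ms, producing major lapses. False starts are Poisson per session.
* **Blinks** are runs where both eyes' coordinates drop to (0, 0) — the
  signal-loss encoding of glasses-type trackers. Blink duration and rate
  increase with drive.
* **Fixations** follow a fixation–saccade process (piecewise-constant
  centres, small jitter, instantaneous saccades); fixation duration
  increases with drive.
* **Facial channels** are Gaussian noise around
  `mean + shift × tanh(drive)`, clipped to [0, 1]. The tanh saturation
  keeps each channel inside `[mean, mean + shift]` at any drive. Shifts
  are positive for eye closure, brow raise, mouth open, lip pucker, inner
  brow raise, lip press, head pitch and nose wrinkle; negative for smile
  and head roll; near zero elsewhere.

Two variability layers keep the data honestly noisy: subjects differ in
all baselines (drawn once per subject from their own random substream),
and every session adds day-to-day wander to the blink, fixation and
facial-channel means. Effect magnitudes were set so that a full study
yields top-feature Welch |*t*| scores of roughly 5–15 and a dozen
significant indices — the order of magnitude a real study of this size
reports — rather than the near-separable data a noiseless generator would
produce. Each subject-session draws from a seed derived from the master
seed and its own coordinates, so enlarging a study never perturbs earlier
draws, and a fixed seed reproduces the study bit for bit.

What the generator does **not** emulate: circadian modulation (the
two-process model), pupil dynamics, saccade kinematics, gradual tracker
drift, or correlated facial-channel structure (channels are conditionally
independent given the drive). Passing tests on synthetic data therefore
demonstrate that the *pipeline* recovers known structure under realistic
noise — not that any particular accuracy transfers to real recordings.

## Index extraction

The per-sample eye-activity signal is the ensemble-averaged magnitude
`(sqrt(xL² + yL²) + sqrt(xR² + yR²)) / 2`. **Blinks** are maximal runs
below a near-zero magnitude threshold lasting strictly longer than 20 ms;
a run of exactly 20 ms is not a blink, and a run touching the end of the
recording is closed at the last sample. The threshold defaults to 5% of
the session's median magnitude: a visually chosen cutoff is not
reproducible, a relative one is; an absolute override is available.

**Fixations** use the dispersion-threshold algorithm (I-DT), the standard
choice when only coordinates (not velocities) are trusted: blink samples
are excluded first, the signal is split at the resulting gaps (so no
fixation spans a blink), and a window grows while
`(max−min x) + (max−min y)` of the averaged-eye position stays within the
dispersion threshold (default 1% of the coordinate range); windows of at
least 100 ms become fixations. Commercial trackers do not document their
fixation algorithm; I-DT with these defaults is a documented, configurable
stand-in.

Session indices are mean blink duration (ms), blinks per minute, mean
fixation duration (ms) and fixations per minute, plus the arithmetic mean
of each facial channel. Head-pose and interocular-distance channels are
treated like probability channels (the generator emits them in [0, 1];
real exports can be min-max rescaled via `ft_indices(rescale = TRUE)`).
A session with no detected events has frequency 0 and a *flagged-missing*
mean duration, imputed as 0 with a warning before model training.

## PVT score, threshold and labels

The session score is `lapses + major lapses + false starts`; a response
above 1000 ms counts in both lapse tallies, giving major lapses double
weight. The alternative reading — disjoint bins — is rejected because the
score is explicitly a *modification* of the lapse + false-start count to
weight major lapses more heavily. Scores are raw counts (all sessions are
10 minutes, so no rate conversion is needed) and each subject's 12
analyzed sessions are divided by their Euclidean norm, removing
between-subject scale differences. Missing sessions are excluded from the
norm, not imputed.

The *impairment threshold* is derived at the group level: a one-way ANOVA
across sessions, Tukey–Kramer pairwise comparisons, and then the earliest
session whose mean normalized score exceeds every baseline session's mean
*and* differs from every baseline session at p < 0.05. "Early sessions"
defaults to the first three analyzed sessions (3–7 h awake, inside the
initial stable window of wakefulness); requiring significance against
*all* of them is the stricter of the two readings and is configurable.
The threshold τ is the across-subject mean normalized score of that onset
session, and an observation is *impaired* iff its score is strictly above
τ — a score exactly at τ is normal. A subject who degrades early is
correctly labeled early; no per-subject threshold is fitted.

## Feature statistics and selection

Per index, the package reports Welch's unequal-variance *t* (sign
convention `normal − impaired`, so indices elevated under impairment get
negative *t*), Welch–Satterthwaite df (rounded to integers only for
display), the two-sided *p*, and the Fisher score
`(n₀(μ₀−μ)² + n₁(μ₁−μ)²) / (n₀σ₀² + n₁σ₁²)`. The two-class variant
`(μ₀−μ₁)²/(σ₀²+σ₁²)` is available behind a switch; with only summary
statistics published, neither variant can be singled out, so the
grand-mean (Li et al.) convention is the default. A 1e-12 variance floor
guards degenerate channels.

Five selection regimes are provided: all-inclusion (control),
significance filter (p < α, ranked by |*t*|), Fisher filter (top scores,
lexicographic tie-break), sequential forward selection, and a genetic
algorithm. Both wrappers maximize LOSO balanced accuracy. The feature
budget is one per 20 observations; the default of 12 corresponds to the
planned 240 observations (233 usable observations would give 11 — the
budget is an explicit parameter precisely because the two readings
differ). SFS breaks ties toward the earliest feature for determinism. The
GA uses 25-bit chromosomes, tournament selection (size 3), uniform
crossover (p = 0.8), per-bit mutation (p = 0.02), elitism (2) and a hard
budget repair that randomly clears surplus bits; population 40 and 50
generations are desk-scale defaults, not optimized settings.

Wrapper selection defaults to **nested** mode: features are chosen inside
each training fold, so selection never sees the held-out subject. The
selection is computed once per fold (with a single-iteration objective)
and reused across the undersampling iterations — recomputing it per
iteration would multiply the search cost fivefold for no change in the
leakage guarantee. A `"paper"` mode selects once on the full dataset, the
protocol most plausibly used when wrapper selection is reported alongside
a single cross-validation; it is optimistic and flagged as such.

## Evaluation protocol

Fourteen classifiers are evaluated: linear/quadratic/cubic/Gaussian-kernel
SVMs, LDA, QDA, k-NN, a CART tree, Naive Bayes with box, Epanechnikov,
normal and triangular kernels, and one- and two-hidden-layer MLPs.
Hyperparameters are common defaults (k = 5; cost 1 with the median
pairwise-distance kernel-scale heuristic; Gini splitting grown to purity;
Silverman bandwidths; 10 and (10, 5) logistic hidden units, 500 epochs) —
the original MATLAB defaults are not recoverable, so all are configurable
and none is claimed to reproduce them. The kernel Naive Bayes variants
and the two-hidden-layer MLP are implemented in the package (class-wise
univariate kernel densities with a small evaluation floor; BFGS on
cross-entropy with analytic backprop gradients) because no installed
library exposes those exact models.

Evaluation is leave-one-subject-out: all of a subject's sessions form one
test fold, preventing within-subject leakage. Training folds are balanced
by randomly undersampling the majority class; because that discards rows,
the procedure runs for five iterations and the confusion counts are
**pooled** over folds and iterations. Pooling (rather than averaging
per-iteration metrics) weights subjects by row count and is exactly
reconstructible from the stored counts; an averaging mode exists for
comparison. Features are z-scored with training-fold statistics only —
scaling is a stated convention here because distance-based models require
one. Metrics: sensitivity to impairment (positive class), specificity,
balanced accuracy `sqrt(sens × spec)`, and bias `sens − spec`. Every cell
satisfies the geometric-mean identity and the AM–GM bound by
construction, and the entire grid is bit-reproducible under a fixed
master seed, because every stochastic step draws from a substream seeded
by its own coordinates.

## Numerical and degenerate-input choices

* Blink rule strict (> 20 ms); threshold 5% of median magnitude.
* I-DT dispersion is range-x + range-y of the averaged eyes; window
  duration counts samples × sampling period, so a constant 600 s
  recording is one 600 s fixation.
* All-zero score vectors normalize to zeros with a warning (norm
  undefined).
* Sessions with fewer than two observations are excluded from the ANOVA
  with a warning; a failed grid cell (e.g., singular QDA covariance) is
  recorded missing and the run continues.
* Constant-label training data yields a constant predictor rather than an
  error, so degenerate undersamples cannot crash a grid run.
* Kernel-density evaluation uses linear interpolation with a 1e-9 floor;
  zero-variance features fall back to a fixed small bandwidth.

## Problem sizes used by the tests and the acceptance script

Checks that need many replicates run at reduced, stated sizes chosen so
the full suite stays desk-scale: onset recovery uses 50 full-design
PVT-only studies; the nested-wrapper grid invariants use one 6-subject
study with 2 undersampling iterations, a budget of 3, GA population 6 ×
4 generations and shortened MLP training; the selector-ordering check
averages 6-subject grids over 10 seeds with full-data ("paper") wrapper
selection; the acceptance script runs the full 20 × 13 study for scoring,
thresholding and index statistics, and an 8-subject study for a
6-classifier grid. Reduced settings change none of the protocol's
invariants — they only shrink the search and the fold counts.

## Worked example

```{r example, eval = FALSE}
study <- generate_study(study_config(seed = 1))
scores <- score_study(study)
threshold <- derive_threshold(scores)
threshold
#> Impairment threshold: impairment detected
#>   onset session 9 (17 h awake), tau = 0.1597
#>   ANOVA F(11, 221) = 394.80, p = 1.34e-138

dataset <- build_labeled_dataset(extract_features(study),
                                 label_observations(scores, threshold))
head(rank_report(index_stats(dataset)), 3)
loso_evaluate("NBNRM", dataset,
              features = select_filter_fisher(index_stats(dataset))$features,
              config = eval_config(seed = 1))
```

## Known limitations

* Synthetic facial channels are conditionally independent; real action
  units co-activate, which filters (blind to redundancy) would feel more
  than these tests show.
* The impairment drive is a deterministic hinge; real impairment onset is
  gradual and partially reversible within a night.
* Classifier hyperparameters are sensible defaults, not tuned; reported
  accuracies on synthetic data say nothing about accuracies on real
  recordings.
* `"paper"`-mode wrapper results are optimistically biased by design;
  nested mode is the defensible protocol and the default.
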