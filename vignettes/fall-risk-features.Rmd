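---
title: "Methods: sensor-based fall-risk feature analysis for TUG trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sensor-based fall-risk feature analysis for TUG trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tugfall)
```

## The problem

The Timed-Up-and-Go (TUG) test — stand from a chair, walk to a mark, turn
180°, walk back, sit down — is a standard clinical fall-risk screen. A
waist-worn triaxial accelerometer (mediolateral ML, vertical V,
anterior–posterior AP axes) turns one TUG trial into a rich movement
signature. `tugfall` implements the full analysis chain for asking *which*
movement features carry fall-risk information:

1. segment the trial into sit-to-stand (SiSt), walk out, turn, walk back,
   stand-to-sit (StSi);
2. compute a 79-feature catalogue (entropy measures on the whole trial,
   transition descriptors, gait parameters, turn descriptors);
3. label subjects three ways — TUG duration > 12.47 s, short-form Berg
   balance scale (SFBBS) < 23, and their union;
4. rank features with Relief-F and with impurity-based extra-trees
   importance, classify with resampled random forests, and keep the
   features common to both selectors' best models;
5. "star" the features that survive that intersection under *every*
   labeling, and optionally intersect across two cohorts.

Because the motivating clinical data are not public, the package ships a
synthetic two-cohort generator; every stage is exercised against it.

## Clinical labelings

`make_labels()` applies the two published screening cutoffs strictly:
a subject is a faller under the TUG criterion iff the trial takes *more
than* 12.47 s, and under the SFBBS criterion iff the score is *below* 23
(scale 0–28). The multifactor label is their union: fall risk if either
criterion flags. The union is the only combination of the two screens that
cannot lose sensitivity relative to either one, which matches the intent of
combining a gait-based and a static-balance-based screen; we document it as
an interpretation since the combination rule is not spelled out in the
source material.

## Entropy measures

**Sample entropy.** `sample_entropy(x, m, r_abs)` is
\(-\ln(C_{m+1}/C_m)\), where \(C_m\) counts template pairs of length
\(m\) within Chebyshev tolerance \(r_{abs}\), self-matches excluded, and
both counts run over the same \(N-m\) extensible templates. Degenerate
outcomes are explicit: \(C_{m+1}=0\) gives `+Inf`; \(C_m=0\) gives a
flagged `NA` with a warning, which downstream feature assembly records as
missing (and the pipeline later imputes with training-fold medians) —
infinities must never reach a classifier.

**Multiscale entropy.** `coarse_grain(x, tau)` averages *non-overlapping*
blocks of `tau` samples, giving `floor(N/tau)` points. The source text
says "sliding window" but also that the result has \(N/\tau\) points; only
non-overlapping blocks are consistent with that length (and with the
standard multiscale construction it cites), so that is what we implement.
`mse_profile()` computes SampEn at scales \(1..\tau_{max}\) with the
tolerance fixed at `r` × SD of the *original* series across all scales —
the standard convention; re-estimating the SD per scale would conflate
amplitude shrinkage with complexity. The complexity index is the sum of
the profile, so `CI = tau_max * mse_mean` identically.

Defaults `m = 2`, `r = 0.15`, `tau_max = 5` are exposed in
`mse_params()`; the source prints none of them, and these are the most
common settings for short physiological records. With trial lengths of a
few hundred samples, `tau_max = 5` keeps the coarsest series long enough
for `m = 2` templates.

**Permutation entropy.** `ordinal_distribution()` embeds the series in
windows of `D` points spaced `tau` apart, maps each window to its rank
pattern (ties broken by temporal order — acceleration data make exact ties
rare, but the rule must be deterministic), and normalizes pattern counts.
`permutation_entropy()` is \(-\sum p_i \log_2 p_i\): the printed equation
in the source lacks the minus sign and would be non-positive, so the sign
is corrected to the standard definition. Its worked example is internally
inconsistent (it assigns the descending columns a pattern that contradicts
its own pattern definition, and two of the six printed probabilities
cannot follow from the stated rule); only the four internally consistent
entries are used as test anchors, and the discrepancy is documented here
rather than silently "fixed".

## The 79-feature catalogue

`feature_schema()` fixes the canonical naming and order: a full-trial
entropy block (MSE mean/SD/complexity index and permutation entropy per
axis, 12 features), SiSt and StSi blocks (duration plus range, max, min,
RMS, SD, max/mean jerk per axis, 22 each), a walk block (duration,
cadence, step length, gait speed, step/stride time and their CVs, RMS per
axis, 11), and a turn block (CV, median, range, RMS per axis, 12).

Choices the source leaves open, fixed here and configurable where
sensible:

* **Walkway length**: 3 m each way (the standard TUG protocol), so the
  walk block uses 6 m over the two bouts; `distance` is an argument.
* **Both walking bouts** are concatenated for the walk features, excluding
  the turn: all gait data are used without contamination by turning.
* **Jerk** is the central first difference scaled by `fs` (one-sided at
  endpoints); `max_jerk`/`mean_jerk` use `|jerk|`, since smoothness is
  direction-agnostic.
* **Step detection** finds local maxima of the 0.5–3 Hz band-passed
  vertical signal, ≥ 0.25 s apart, per bout. Step intervals never span the
  turn.
* **Step counting**: the "number of steps" in `step_length =
  distance/n_steps` is the effective count `walk_duration/step_time`
  implied by the mean step interval. A raw event count is off by one
  fencepost per bout (≈ 20% for short TUG bouts); the effective count also
  makes `gait_speed = cadence/60 × step_length` an exact identity, which
  the raw count cannot.
* **Stride times** are non-overlapping sums of adjacent step intervals
  starting at each bout's first event (foot labels are unobservable from a
  single waist sensor); CVs are reported in percent.
* **Turn CV** uses `|mean|` in the denominator and is flagged missing when
  `|mean| < 1e-9 × SD`: a zero-mean turn signal would otherwise explode
  the ratio. SD is the sample SD (n−1 denominator) throughout.
* **Entropy features** are computed on the raw trial-span signals (SiSt
  start through StSi end), not detrended; detrending is not part of the
  described method.

A failing block (e.g. too few steps detected) produces flagged `NA`s for
its features plus a warning — never a silently shortened vector.

## Phase segmentation

Annotated mode validates and returns supplied boundaries (0-based,
half-open, strictly ordered). The source does not describe how its phases
were obtained, so auto mode is this package's own detector, designed to be
simple and testable against the generator's ground truth:

* **Transitions**: the SiSt is the first sustained AP excursion above the
  seated baseline (default 0.15 g for ≥ 0.25 s); the StSi is found
  symmetrically from the trial end. Boundaries are refined to the
  half-amplitude crossings of the smoothed excursion envelope — a centered
  moving average preserves the half-amplitude points of a symmetric
  transient, so this estimator is unbiased up to the transient's own edge
  shape.
* **Turn**: within the interval between the transitions, the turn is the
  region where the short-window ML *second moment about the walking
  baseline* exceeds the midpoint between its walking floor and turn
  plateau (robust quantiles, one refinement pass). We deliberately take
  the second moment about the walking mean rather than a locally centered
  variance: turning contributes both extra sway variance *and* a sustained
  centripetal ML offset, and folding the offset into the statistic
  separates turn from steady gait several times more sharply than local
  variance alone, whose contrast (≈ 2:1 under realistic noise) made
  boundary estimates unstable.
* **Walking bouts** are the gaps between transitions and turn.

Against the generator's ground truth the detector recovers phase durations
with a median error of ~4–5%; the community preset stays within the 15%
default tolerance for all phases over 50 seeded trials, while the noisier,
slower stroke preset breaches 15% on the turn in roughly 2% of draws
(worst ≈ 25%). The tests assert exactly that, rather than a blanket claim.

## The synthetic cohorts

`generate_cohort()` is a stated world, not a curve fit. Each subject's
trace is a deterministic phase template plus white noise (m/s², gravity
removed): smoothstep AP+V transients for the transitions (amplitude 3 and
−3 m/s² on AP), step-frequency V and AP oscillations during walking with
ML sway at the stride frequency, and a turn with √3-fold ML sway (variance
3× walking) plus a 1.2 m/s² centripetal ML offset. Padding of 1 s of
seated stillness flanks the trial.

Parameter choices and their anchors:

* Cohort presets mirror the motivating study's structure: 65 community
  dwellers at 30 Hz, 35 stroke survivors at 45 Hz.
* Fall-risk subjects (probability 0.2 community / 0.35 stroke) receive
  multiplicative effect shifts. The default stand-duration shifts — ×1.7
  (community) and ×2.8 (stroke) — are the ratios of the published
  fall-risk vs healthy stand-duration group means for those populations.
  Sit-duration, gait-speed and cadence shifts (1.3/0.85/0.95 community,
  1.5/0.8/0.9 stroke) are plausible co-morbid slowings, chosen once.
* Walking-bout durations are *derived*: cadence and step length are drawn
  (100 ± 8 steps/min, 0.48 ± 0.04 m community; 100 ± 10, 0.50 ± 0.05
  stroke), gait speed is cadence/60 × step length, and each bout lasts
  3 m / speed. This keeps the generator's ground-truth gait parameters
  mutually consistent, at the cost of ignoring any drawn walk-duration
  field. Stroke gait defaults are deliberately brisk for that population:
  with the fixed 12.47 s cutoff, a slower baseline would make every
  stroke subject a TUG-faller and leave the label single-class.
* Transition/turn durations are Gaussian (SDs 0.15–0.3 s), truncated at
  0.1 s. The simulated TUG duration is the exact sum of the five
  continuous phase durations.
* The SFBBS score is simulated as `28 − round(28 × plogis(6(z − 0.5)))`
  with `z` the sum of |log effect shifts| plus N(0, 0.15) noise: healthy
  subjects score ≥ 23 almost always, shifted subjects fall below 23 with
  high but imperfect probability, so the TUG and SFBBS labelings disagree
  for some subjects — as the real cohorts do.
* Noise SD defaults to 0.25 m/s² (0.3 stroke), a realistic broadband level
  for waist-worn accelerometry during gait.

What the generator does *not* emulate: paretic-leg asymmetry waveforms
(asymmetry enters only through parameter shifts), harmonic structure of
real gait beyond the fundamental, sensor drift, or postural sway during
quiet sitting. A green recovery test therefore establishes that the
pipeline recovers *injected, parameterized* group differences — not that
it would rank features identically on clinical data.

## Ranking and classification

**Relief-F** (`relieff_weights()`) is implemented from scratch, literally
following the published update rule: weights start at 0; each iteration
draws a sample with replacement, finds its k nearest hits and k nearest
misses per class by Manhattan distance on min-max-scaled features, and
updates every weight by the scaled feature difference
\(\Delta_j = |x_{rj} - x_{qj}|/\mathrm{range}(F_j)\), subtracted for hits
and added for misses with prior weighting \(p_{y_q}/(1-p_{y_r})\), both
divided by \(m \cdot d_{rq}\). Two readings had to be fixed: the typeset
miss factor is read as the standard prior-weighted ratio, and the printed
division by the neighbor distance \(d_{rq}\) is kept (updates are
distance-weighted), with zero-distance neighbors skipped to avoid a 0/0.
Determinism: neighbor ties break toward the lower sample index, ranking
ties toward the lower feature index, `k` is clipped to class size − 1 with
a warning (reachable with 13-positive cohorts), and `m` defaults to one
iteration per sample.

**Extra-trees importance and the random-forest classifier** are cited, not
defined, by the source, so they are contract-level stages. No tree
ensemble package exists in the target environment, so both are implemented
in compiled code inside the package: Gini CART trees; extra-trees uses the
full sample, one uniform random threshold per candidate feature and √p
candidates per node; the random forest uses bootstrap bagging with
exhaustive split search; importances are mean decrease in impurity,
normalized to sum to 1 (a constant feature can never split and scores
exactly 0); probabilities are averaged leaf class frequencies. 100 trees
by default, deterministic per seed via a per-tree splitmix64 stream.

**The grid.** "100-fold cross-validation" cannot be literal k-fold with 35
subjects and 13 positives; `run_grid()` implements 100 stratified
shuffle-splits (80/20) — configurable — which matches the language of
averaging across folds while keeping every test fold populated. Within
each split: impute missing features with *training-fold* medians, run both
selectors on the training fold only, then for each k ∈ {5,10,15,20,25,30}
train a random forest on the top-k features and score AUC (rank statistic
with midrank ties) plus precision/recall/F1 at the 0.5 threshold on the
held-out fold. Selection inside the split is the leakage-free reading of
the source's ambiguous description; the all-noise null lands at AUC
0.5 ± 0.1, which the tests assert as a leakage guard.

**Best models and intersections.** `select_best()` takes the k with
maximal mean AUC per selector (ties → smaller k). Because the source
reports a single feature list per best model despite per-fold selection,
a best model's feature set is defined by *consensus*: features in the
top-k in ≥ 50% of splits (threshold configurable), ordered by frequency
with ties toward the lower catalogue number. `intersect_important()`
intersects the Relief-F and extra-trees sets per labeling and stars
features present in every labeling's intersection; `compare_reports()`
intersects across cohorts.

## Numerical and degenerate-input policy

* All randomness flows from explicit seeds; child seeds are derived,
  never reused across stages. RNG state of the caller is preserved.
* Missing features: flagged `NA` at extraction; imputed with
  training-fold medians inside each split; an all-missing column imputes
  to 0 rather than propagating NaN.
* Empty segments, single-class labels, out-of-range scores, too-short
  series: descriptive errors, never silent results.
* Precision/recall are defined as 0 when no positives are predicted.

## Test-budget scaling

The acceptance suite's recovery experiment (two cohorts × n = 100, only
the stand-duration effect at ×2.5, full grid at 20 splits) is run for 50
seeded replicates rather than 100 to stay inside the suite's runtime
budget; the pass threshold (stand duration starred in both cohorts in
≥ 90% of replicates) is unchanged. At these settings the observed rate in
development runs was at or near 100%.

## Known limitations

* Auto segmentation is tuned to, and validated on, the generator's signal
  family; real recordings with atypical turns (pauses, multi-step turns)
  will need annotations or re-tuned thresholds.
* The stroke preset's gait speed is unrealistically high for severe
  impairment — a deliberate trade-off to keep both TUG label classes
  populated under the fixed 12.47 s cutoff.
* Published per-cohort rankings and AUC tables derive from private data
  and are not reproduction targets; the package reproduces the method,
  the worked example, and recovery of known synthetic effects.
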