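---
title: "Recognising activities of daily living and falls from waist-IMU data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognising activities of daily living and falls from waist-IMU data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(falladl)
```

## The problem

Waist-worn inertial measurement units (IMUs) — a tri-axial accelerometer
plus a tri-axial gyroscope near the body's centre of mass — are a practical
basis for recognising activities of daily living (ADL) and detecting falls
in free-living conditions. Public waist-IMU datasets are individually small
and mutually incompatible: they differ in sampling rate (roughly 20-238 Hz
across the well-known corpora), sensor axis conventions, units (g vs m/s²,
rad/s vs deg/s), sensor ranges and labelling vocabularies. `falladl`
implements a complete, tested pipeline for the standard study design on
such data:

1. **Harmonisation** of heterogeneous recordings to a canonical stream;
2. **Sliding-window segmentation** with mode labelling;
3. A **199-feature bank** per window;
4. **Feature-selection ranking**, including a PCA "resultant component"
   procedure that also caps the number of candidate features;
5. A **progressive benchmarking protocol** over classical classifiers and
   small neural baselines, scored by confusion-matrix metrics with the
   multiclass Matthews correlation coefficient (MCC) as headline metric;
6. A **synthetic corpus generator** that emulates the statistical structure
   of a merged multi-dataset corpus, so that every stage is testable with
   no external downloads.

The 20-class taxonomy (`class_taxonomy()`) spans 8 periodic activities and
static postures (walking, standing, sitting, lying, stairs up/down,
jumping, jogging), 8 postural transitions (lying-to-stand, stand-to-sit,
sit-to-stand, stand-to-pick-to-stand, stand-to-lying, position change
while lying, turning, bending) and 4 fall types (forwards, backwards,
lateral, syncope).

## Harmonisation

Each source dataset carries a manifest (`sensor_mapping()`): a signed
assignment of native axes to the canonical anteroposterior (AP),
mediolateral (ML) and vertical (V) body axes, its units, native rate and
optional saturation range. The assignment must be a *proper* rotation
(determinant +1); a reflected mapping is almost always a configuration
mistake and is rejected.

`reorient()` applies the signed permutation and converts units
(g → m/s² by 9.81; rad/s → deg/s). `resample_50hz()` then linearly
interpolates every channel onto the uniform half-open grid
`t_first + k/50, k = 0 … floor(T·50) − 1`, which makes the output length a
deterministic function of the recording duration. Two deliberate choices:

* **No anti-alias filtering.** The pipeline operates on raw inertial data
  throughout; when downsampling (e.g. 238 → 50 Hz) aliasing of
  above-25 Hz content is accepted and documented. Body-motion energy is
  predominantly below ~20 Hz, and all later stages see the same
  convention.
* **Label transfer by nearest sample** (ties to the earlier sample).
  Interpolation-side rules would systematically shorten brief, rare events
  such as fall impacts; nearest-sample transfer preserves them.

## Segmentation and the mode label

`segment_streams()` cuts each stream into windows of
`L = round(window_s · 50)` samples with hop `H = round(L·(1 − overlap))`
(minimum 1). Defaults are 1 s windows at 80% overlap (L = 50, H = 10);
0.5, 1.5 and 2 s are the other standard sizes. Windows never span
recording boundaries. Each window takes the **mode** of its per-sample
labels; ties are resolved in favour of the tied label whose last
occurrence is latest, biasing toward the activity being entered — the
variant that behaves best for transitions and falls.

## The feature bank

`extract_window()` computes 199 features per window from eight derived
signals: the six axis channels plus the per-sample vector magnitude
(SumVM) of each sensor. The bank covers window-terminal values,
population-moment skewness and kurtosis (Pearson, non-excess), order
statistics and dispersion, inter-axis Pearson correlations, kinematic
summaries (signal magnitude area and its mean-removed variant, total
angular change, peak angular acceleration, double-integrated displacement
and sway, horizontal displacement), amplitude measures (peak-to-peak, RMS,
ratio index), waveform-shape counts (mean crossings, slope changes,
waveform length), one-sided DC-excluded spectral summaries (energy
satisfying Parseval against mean-removed power, power-weighted mean
frequency, peak frequency and magnitude), SumVM aggregates, an
exponential moving average (α = 0.1), the SumVM rotation angle, a
terminal-sample Z-score and the integrated angular displacement magnitude.

Degenerate inputs follow fixed conventions: correlation, skewness,
kurtosis and Z-score are defined as 0 whenever a required variance is 0,
so constant windows produce finite features. Several bank entries are
intentionally redundant (e.g. per-axis gravity components equal per-axis
means); the bank is a fixed contract and redundancy is left to the
feature-selection stage. Feature ids run contiguously 1…199 in row-group
order; ties anywhere downstream are broken by ascending feature id.

Every feature is verified against an independently coded brute-force
oracle (explicit loops, naive DFT) at 1e−9 relative tolerance in the test
suite.

## Scaling and feature selection

`scale_features()` min–max scales each feature to [0, 1] either
**per dataset** — replicating the published protocol in which each source
corpus is normalised separately to absorb device differences; note this
mixes information across any later train/test split — or in **train-fit**
mode, which fits scaling parameters on the training partition only, clips
unseen values into [0, 1], and stores the parameters for reuse. Train-fit
is the leakage-safe mode and is what the leakage-guard tests exercise.

`rank_features()` implements Relief-F (k = 10 neighbours per class, all
instances, range-normalised Manhattan distances), mutual information and
mRMR (20 equal-width bins), CFS (greedy forward merit
$k\,\bar r_{cf} / \sqrt{k + k(k-1)\bar r_{ff}}$, with the correlation
ratio as feature-class correlation) and LASSO (entry order on the
one-vs-rest L1 logistic path via glmnet, earliest entry across classes).
Niche research selectors can be attached through `register_ranker()`
without touching the core.

`pca_rank()` implements the resultant-component procedure: PCA on the
scaled matrix (covariance, no re-standardisation — the inputs are already
on a common [0, 1] scale), retain the smallest m components reaching 70%
cumulative explained variance, combine their absolute loadings weighted by
their share of the retained variance ("resultant and proportional"), and
normalise to sum to 1. Features whose resultant loading strictly exceeds
the uniform share 1/F are counted; twice that count is the **feature cap**
used by the progressive sweep. The weighted (rather than unweighted)
combination is a documented choice; with near-equal retained eigenvalues
the two coincide.

## Benchmarking protocol

The protocol is: 70/30 stratified hold-out (`make_holdout()`; a
subject-wise mode is available for stricter generalisation claims) →
progressive feature-count sweep under 5-fold CV on the training partition
(`progressive_sweep()`, argmax MCC, ties to fewer features) → repeated
5-fold CV for the finalists → `gridsearch()` over declared hyperparameter
grids (nearest-neighbour: neighbours {1,3,5,7,9} × distance
{Euclidean, city-block, Minkowski p ∈ {0.5, 3}} × weighting {uniform,
inverse, squared inverse}; bagged ensemble: 10–100 cycles plus 37) →
`final_test()` on the untouched test partition with wall-clock timing.

Classifiers: LDA/QDA (MASS), a nearest-neighbour classifier implemented in
the package (fractional Minkowski exponents are accepted as
dissimilarities — p = 0.5 violates the triangle inequality but ranks
neighbours fine; with inverse weighting, zero-distance neighbours take all
the weight), bagged deep rpart trees (majority vote, smallest class id on
vote ties), and single rpart trees. MCC is the multiclass (Gorodkin)
generalisation computed on the whole confusion matrix — not a macro
average of binary MCCs — because it remains informative under the strong
class imbalance here. Sensitivity/specificity/precision/F1 are one-vs-rest
per class with unweighted macro means; precision of a never-predicted
class is 0 by convention, and classes absent from both truth and
prediction are excluded from the macro mean.

`window_size_study()` re-runs segmentation → extraction → scaling →
ranking (training partition only) → hold-out evaluation per window size at
fixed 80% overlap, for chosen (model, selector, n-features) combinations.

## Neural baselines

`net_train_eval()` trains four small networks — CNN (two 1-D convolution
blocks: 32 then 64 filters, kernel 3, ReLU, max-pool 2), LSTM (one
recurrent layer, 150 hidden units by default), BiLSTM, and CNN-LSTM (one
convolution block feeding the recurrent layer) — all ending in a 20-way
softmax. The input is the *engineered feature vector treated as a
length-F single-channel sequence*, mirroring the benchmarked protocol
(training on raw windows is out of scope). The training regime is fixed
across architectures: 100 epochs, batch 64, Adam at a constant 0.001,
cross-entropy. Layers, backpropagation and Adam are implemented directly
on base-R matrices; the test suite validates all gradients against finite
differences. Treating an unordered feature vector as a sequence gives the
convolutional front-end little structure to exploit, and its weaker
results relative to the recurrent baselines are expected.

## The synthetic corpus generator

`synth_corpus()` emulates the statistical structure the analysis assumes
while remaining a kinematic sketch, not a biomechanical simulation:

* **Virtual datasets** with native rates spanning 20–238 Hz, mixed signed
  axis conventions, g/rad-based units and optional saturation clipping;
  harmonisation therefore has real work to do, and the generator applies
  the *inverse* of each dataset's mapping so a round-trip is testable.
* **Class structure**: static postures are gravity orientations plus
  noise; gait classes add harmonics at class-specific step frequencies
  (walking 1.5–2.5 Hz); transitions rotate the gravity vector smoothly
  between postures with consistent gyroscope signatures and
  class-specific vertical centre-of-mass bumps; falls have a short
  quiescent lead-in, a fast rotation with partial free-fall (specific
  force well below 1 g), a 3–8 g impact spike (3–4.5 g for syncope, which
  is also slower), a decaying settling oscillation and post-fall
  stillness.
* **Imbalance**: activities are scheduled by a corpus-wide quota ledger so
  emitted per-sample shares converge to the configured mix (walking
  ≈ 30%, lying ≈ 18.5%, fall-by-syncope ≈ 0.3% — the rarest class); a
  greedy largest-deficit scheduler keeps every class within about one
  segment of its quota, which is what makes the ±2-percentage-point share
  check feasible at ~50k samples.
* **Non-stationarity**: sustained activities contain brief motion
  artifacts (postural adjustments) at a fixed expected rate of 0.12
  events/s. Because the rate is per second, a 2 s window is roughly four
  times as likely as a 0.5 s window to be contaminated — the same
  dilution mechanism that penalises large windows on real data, where
  short transitions and artifacts are averaged away.

The **easy** preset (the default) is calibrated so that the 20 classes are
separable by the full pipeline: distinct posture angles (sitting reclined
~30°, bending ~50°, picking ~78°), distinct transition signatures, free
fall + impact for falls, and cyclic bouts of 8–16 s so that only a modest
fraction of windows straddle an activity boundary. Those
boundary-straddling windows are intrinsically ambiguous under mode
labelling and bound the achievable accuracy; this is a property of the
protocol, not of the generator. The **realistic** preset adds noise
(0.8 m/s² accelerometer SD), overlapping class parameters (bending toward
sitting inclination, reduced jogging amplitude) and per-session sensor
gain mismatch, to exercise confusion behaviour rather than to certify
performance.

What passing tests on synthetic data do **not** show: robustness to real
sensor artifacts (drift, temperature, detachment), true biomechanical
variability across subjects and pathologies, or real-world fall
morphology. The generator fixes the *structure* of the problem, not its
clinical content.

## Numerical choices and degenerate inputs

* Gravity constant 9.81 m/s² for unit conversion and the vertical
  reference.
* Resampling requires strictly increasing timestamps; recordings shorter
  than one output sample are errors (dropped with a warning at corpus
  level); streams shorter than one window contribute zero windows.
* Constant feature columns scale to 0; double scaling is a contract
  violation.
* All ranking ties (duplicated columns, equal scores) break by ascending
  feature id; sweep ties by smaller feature count; grid-search ties by
  the simpler model; vote ties by smaller class id.
* The strict `> 1/F` inequality in the PCA cap means an exactly uniform
  resultant yields a cap of 0.
* Random-number use is localised: every seeded entry point saves and
  restores the global RNG state.

## Problem sizes used in the shipped checks

The test suite and the acceptance script regenerate everything from seeds:
the end-to-end corpus uses the default generator conditions (3 virtual
datasets × 4 subjects × 2 sessions ≈ 45 s, about 5,500–6,000 one-second
windows); the window-size study uses a 2-subject variant of the same
conditions (~10,000 windows across sizes). These sizes give stable
metrics (repeat-to-repeat CV standard deviations well under one
percentage point) while keeping a full run in a few minutes on one CPU.

## Known limitations

* Per-dataset scaling replicates the published protocol but leaks
  information across the hold-out split; train-fit mode is provided and
  tested, and is the right choice for new work.
* Window-wise splits share subjects between train and test; the
  subject-wise mode gives the honest generalisation estimate and will
  score lower.
* The nearest-neighbour classifier stores its training set; prediction
  cost grows linearly with it (the classical trade-off the timing fields
  make visible).
* ILFS, UFSOL, FSASL and FSV are exposed only as plugin hooks.
* The CNN consumes unordered feature vectors; its architecture is a
  documented convention, not a tuned design.
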