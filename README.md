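# falladl

Recognition of activities of daily living (ADL) and falls from
waist-worn inertial sensors, as a tested, end-to-end R pipeline.

## The problem

A waist IMU delivers tri-axial acceleration and angular velocity near the
body's centre of mass — enough, in principle, to recognise everyday
activities and detect falls. Studies that want a large training corpus
must merge heterogeneous public datasets that disagree on sampling rate
(20–238 Hz), axis conventions, units and sensor ranges. `falladl`
implements the full study design for this setting, for researchers who
want to reproduce, stress-test or extend it:

* **Harmonisation** — signed axis reorientation (proper rotations only),
  unit conversion, linear resampling to a canonical 50 Hz six-channel
  stream (`sensor_mapping()`, `reorient()`, `resample_50hz()`,
  `harmonize_corpus()`).
* **Segmentation** — sliding windows (default 1 s, 80% overlap), one label
  per window by the mode of its per-sample labels with a
  latest-occurrence tie rule (`segment_streams()`, `mode_label()`).
* **Features** — a fixed 199-feature bank per window over the six axis
  channels and the two per-sample vector magnitudes (SumVM): moments,
  order statistics, correlations, signal-magnitude areas, displacement and
  sway, waveform-shape counts, spectral summaries and more
  (`feature_registry()`, `extract_features()`).
* **Selection** — per-dataset or train-fit min–max scaling; Relief-F,
  mutual information, mRMR, CFS and LASSO rankings; and the PCA
  resultant-component procedure whose above-uniform loading count, times
  two, caps the candidate feature set (`scale_features()`,
  `rank_features()`, `pca_rank()`).
* **Benchmarking** — 70/30 stratified (or subject-wise) hold-out,
  progressive feature-count sweeps under 5-fold CV, grid search, final
  test with timing, and a window-size study; metrics include the
  multiclass (Gorodkin) Matthews correlation coefficient

  MCC = (c·s − Σₖ tₖpₖ) / √((s² − Σₖpₖ²)(s² − Σₖtₖ²))

  on the full 20-class confusion matrix (`make_holdout()`, `run_cv()`,
  `progressive_sweep()`, `gridsearch()`, `final_test()`,
  `window_size_study()`, `compute_metrics()`).
* **Neural baselines** — CNN, LSTM, BiLSTM and CNN-LSTM over the feature
  vector treated as a sequence, trained under a fixed regime (100 epochs,
  batch 64, Adam 0.001, cross-entropy), implemented in base R with
  gradient-checked backpropagation (`net_spec()`, `net_train_eval()`).
* **Synthetic corpus** — a seeded generator producing 20-class labelled
  waist-IMU recordings across virtual datasets with heterogeneous rates,
  axis maps, units and saturation, with realistic class imbalance
  (walking ≈ 30%, fall by syncope ≈ 0.3%), so the whole pipeline runs
  with no external data (`generator_config()`, `synth_corpus()`).

## Worked example

```r
library(falladl)

corpus  <- synth_corpus(generator_config(), seed = 1)
streams <- harmonize_corpus(corpus$recordings, corpus$manifests)
windows <- segment_streams(streams, segmentation_config(window_s = 1,
                                                        overlap = 0.8))
windows
#> <window_set> 5915 windows of 50 samples x 6 channels (1.0 s @ 50 Hz, hop 10)

features <- extract_features(windows)
scaled   <- scale_features(features, "per_dataset")

ranking <- rank_features(scaled, "relieff")
ranking
#> <ranking_result> relieff over 199 features; top 5: 94, 197, 76, 194, 66

pca_rank(scaled)
#> <pca_rank_outcome> 6 PCs (72.2% explained), 79 features above 1/199, cap 158

run_cv(scaled, model_spec("knn"), ranking, n_features = 85, k = 5, seed = 1)
#> <eval_report> ACC 96.23 | Sens 91.61 | Spec 99.80 | Prec 91.78 | F1 91.65 | MCC 95.65
```

Reading the numbers: 5,915 one-second windows come out of a ~24-minute
synthetic corpus; six principal components reach the 70% explained-variance
target and 79 features carry more than a uniform share of the resultant
loading, capping the sweep at 158 features; a 1-nearest-neighbour
classifier on the top 85 Relief-F features reaches 96.2% cross-validated
accuracy and 95.7% multiclass MCC — the easy synthetic preset is designed
to be separable, and the residual errors sit almost entirely in windows
that straddle two activities, which mode labelling makes intrinsically
ambiguous.

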