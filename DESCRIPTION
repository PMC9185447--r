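Package: falladl
Title: Waist-IMU Activity of Daily Living and Fall Recognition Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and benchmarking recognisers of activities of
    daily living (ADL) and falls from waist-worn inertial measurement units.
    Heterogeneous tri-axial accelerometer and gyroscope recordings are
    harmonised to a canonical 50 Hz six-channel stream (axis reorientation,
    unit conversion, resampling), segmented into overlapping sliding windows
    labelled by the mode of their per-sample labels, and summarised by a
    199-feature bank of time- and frequency-domain statistics. Feature
    ranking is provided via Relief-F, mutual information, mRMR, CFS, LASSO
    and a PCA resultant-component procedure that also sets a feature-count
    cap. A progressive benchmarking protocol (hold-out split, k-fold
    cross-validated feature-count sweeps, grid search, final test, window
    size study) compares discriminant, nearest-neighbour, bagged-tree and
    decision-tree classifiers as well as small CNN/LSTM networks, scored by
    confusion-matrix metrics including the multiclass Matthews correlation
    coefficient. A configurable synthetic-corpus generator emulates the
    statistical structure of merged public fall datasets (20 activity
    classes, strong class imbalance, heterogeneous sampling rates and axis
    conventions) so the whole pipeline can be exercised without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    rpart,
    glmnet,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
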