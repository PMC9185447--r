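# A small separable 4-class feature matrix used across protocol tests:
# class centroids far apart in the first 3 columns, the rest noise.
sep_fm <- function(W = 200L, n_class = 4L, seed = 31L) {
  set.seed(seed)
  y <- rep(seq_len(n_class), length.out = W)
  centers <- matrix(c(0, 0, 0, 5, 0, 0, 0, 5, 0, 0, 0, 5, 5, 5, 5),
                    ncol = 3, byrow = TRUE)
  X3 <- centers[y, ] + matrix(rnorm(W * 3, 0, 0.2), W)
  vals <- cbind(X3, matrix(runif(W * 196), W))
  feature_matrix(vals, labels = y,
                 subject_ids = paste0("s", rep(1:10, length.out = W)),
                 dataset_ids = rep("d", W))
}

test_that("stratified hold-out preserves per-class proportions within 1", {
  fm <- sep_fm(1000L)
  sp <- make_holdout(fm, ratio = 0.70, seed = 5)
  expect_length(sp$train_idx, 700L)
  expect_length(sp$test_idx, 300L)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0L)
  expect_setequal(c(sp$train_idx, sp$test_idx), seq_len(1000L))
  for (cl in unique(fm$labels)) {
    n_cl <- sum(fm$labels == cl)
    n_tr <- sum(fm$labels[sp$train_idx] == cl)
    expect_lte(abs(n_tr - 0.70 * n_cl), 1)
  }
  # determinism
  sp2 <- make_holdout(fm, ratio = 0.70, seed = 5)
  expect_identical(sp$train_idx, sp2$train_idx)
  sp3 <- make_holdout(fm, ratio = 0.70, seed = 6)
  expect_false(identical(sp$train_idx, sp3$train_idx))
})

test_that("subjectwise split keeps whole subjects on one side", {
  fm <- sep_fm(200L)
  sp <- make_holdout(fm, mode = "subjectwise", seed = 2)
  tr_subj <- unique(fm$subject_ids[sp$train_idx])
  te_subj <- unique(fm$subject_ids[sp$test_idx])
  expect_length(intersect(tr_subj, te_subj), 0L)
})

test_that("a singleton class lands in train with a warning", {
  fm <- sep_fm(101L)
  fm$labels[101] <- 19L
  expect_warning(sp <- make_holdout(fm, seed = 1), "single window")
  expect_true(101 %in% sp$train_idx)
})

test_that("perfect and independent confusion matrices give the boundary
           metric values", {
  C <- diag(c(10, 20, 30))
  r <- compute_metrics(C)
  expect_equal(unname(r$macro), rep(100, 6), tolerance = 1e-12)
  # predictions independent of truth -> MCC 0
  C2 <- matrix(25, 2, 2)
  expect_equal(compute_metrics(C2)$macro[["mcc"]], 0)
  expect_equal(compute_metrics(C2)$macro[["acc"]], 50)
  expect_error(compute_metrics(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("multiclass MCC equals the direct-formula oracle", {
  C3 <- matrix(c(5, 1, 0, 1, 4, 1, 0, 1, 5), 3, byrow = TRUE)
  expect_equal(mcc_multiclass(C3), oracle_mcc(C3), tolerance = 1e-12)
  set.seed(33)
  for (i in 1:100) {
    K <- sample(2:8, 1)
    C <- matrix(rpois(K * K, 3), K)
    if (sum(C) == 0) C[1, 1] <- 1
    expect_equal(mcc_multiclass(C), oracle_mcc(C), tolerance = 1e-12)
  }
})

test_that("per-class metrics match a brute-force tally; macro is the
           unweighted mean", {
  set.seed(34)
  for (i in 1:20) {
    n <- 200L
    K <- sample(3:6, 1)
    truth <- sample(seq_len(K), n, replace = TRUE)
    pred <- ifelse(runif(n) < 0.6, truth, sample(seq_len(K), n, TRUE))
    C <- table(factor(truth, levels = 1:K), factor(pred, levels = 1:K))
    r <- compute_metrics(unclass(C))
    tallies <- oracle_perclass(truth, pred, 1:K)
    sens <- prec <- f1 <- numeric(K)
    for (k in 1:K) {
      tl <- tallies[[k]]
      sens[k] <- if (tl["tp"] + tl["fn"] == 0) 0 else
        tl["tp"] / (tl["tp"] + tl["fn"])
      prec[k] <- if (tl["tp"] + tl["fp"] == 0) 0 else
        tl["tp"] / (tl["tp"] + tl["fp"])
      f1[k] <- if (prec[k] + sens[k] == 0) 0 else
        2 * prec[k] * sens[k] / (prec[k] + sens[k])
    }
    expect_equal(r$per_class$sens, 100 * sens, tolerance = 1e-12)
    expect_equal(r$per_class$prec, 100 * prec, tolerance = 1e-12)
    expect_equal(r$macro[["sens"]], 100 * mean(sens), tolerance = 1e-12)
    expect_equal(r$macro[["f1"]], 100 * mean(f1), tolerance = 1e-12)
    expect_equal(r$macro[["acc"]], 100 * sum(truth == pred) / n,
                 tolerance = 1e-12)
  }
})

test_that("every classifier family fits and predicts the separable set", {
  fm <- sep_fm(160L)
  sc <- scale_features(fm, "per_dataset")
  X <- sc$values[, 1:10]; y <- sc$labels
  for (mid in c("lda", "qda", "knn", "ensemble_bag", "dtree")) {
    spec <- model_spec(mid)
    fit <- fit_model(spec, X, y, seed = 3)
    pred <- predict_model(fit, X)
    expect_gt(mean(pred == y), 0.9)
  }
})

test_that("knn honours distance and weighting options", {
  X <- matrix(c(0, 0, 1, 1, 10, 10), 3, byrow = TRUE)
  y <- c(1L, 2L, 3L)
  q <- matrix(c(0.4, 0.4), 1)
  for (d in list(c("euclidean", 2), c("cityblock", 1), c("minkowski", 0.5),
                 c("minkowski", 3))) {
    spec <- model_spec("knn", n_neighbors = 1, distance = d[1],
                       exponent = as.numeric(d[2]))
    fit <- fit_model(spec, X, y)
    expect_equal(predict_model(fit, q), 1L)
  }
  # zero-distance neighbours take all weight under inverse weighting
  spec <- model_spec("knn", n_neighbors = 3, weighting = "squared_inverse")
  fit <- fit_model(spec, X, y)
  expect_equal(predict_model(fit, matrix(c(10, 10), 1)), 3L)
})

test_that("cross-validation tests each window exactly once per repeat", {
  fm <- sep_fm(100L)
  sc <- scale_features(fm, "per_dataset")
  # instrument via fold assignment directly
  set.seed(9)
  folds <- falladl:::stratified_folds(sc$labels, 5L)
  expect_equal(sort(unique(folds)), 1:5)
  expect_equal(length(folds), 100L)
  for (cl in unique(sc$labels)) {
    tab <- table(folds[sc$labels == cl])
    expect_lte(max(tab) - min(tab), 1)
  }
  rep1 <- run_cv(sc, model_spec("knn"), NULL, n_features = 5, k = 5,
                 repeats = 1, seed = 4)
  expect_equal(sum(rep1$confusion), 100)
  rep10 <- run_cv(sc, model_spec("knn"), NULL, n_features = 5, k = 5,
                  repeats = 3, seed = 4)
  expect_equal(sum(rep10$confusion), 300)
  expect_false(is.null(rep10$macro_sd))
  expect_named(rep10$macro_sd, c("acc", "sens", "spec", "prec", "f1", "mcc"))
})

test_that("run_cv rejects more features than exist", {
  sc <- scale_features(sep_fm(60L), "per_dataset")
  rk <- structure(list(method = "id", order = 1:199,
                       scores = rep(0, 199)), class = "ranking_result")
  expect_error(run_cv(sc, model_spec("knn"), rk, n_features = 200),
               "exceeds")
})

test_that("progressive sweep returns a complete grid and best_n <= cap", {
  sc <- scale_features(sep_fm(120L), "per_dataset")
  rk <- rank_features(sc, "mutinf")
  sw <- progressive_sweep(sc, list(knn = model_spec("knn")),
                          list(mutinf = rk), cap = 6L, stride = 2L,
                          seed = 5)
  expect_equal(nrow(sw$grid), 3L)  # n = 2, 4, 6
  expect_true(all(sw$best$n_features <= sw$cap))
  # informative features only in the top ranks: best_n stays small
  expect_lte(sw$best$n_features[1], 6L)
  # single candidate n
  sw1 <- progressive_sweep(sc, list(knn = model_spec("knn")),
                           list(mutinf = rk), cap = 3L, stride = 3L)
  expect_equal(sw1$best$n_features, 3L)
  expect_error(progressive_sweep(sc, list(), list(mutinf = rk), cap = 5),
               "non-empty")
})

test_that("gridsearch returns a member of the declared grid, ties to the
           simpler model", {
  sc <- scale_features(sep_fm(100L), "per_dataset")
  best <- gridsearch(sc, "knn", n_features = 3, cv = 3, seed = 6)
  expect_s3_class(best, "model_spec")
  expect_true(best$hyperparameters$n_neighbors %in% c(1, 3, 5, 7, 9))
  expect_true(best$hyperparameters$distance %in%
                c("euclidean", "cityblock", "minkowski"))
  # fully separable data: every spec scores 100, so the simplest (1-NN) wins
  expect_equal(best$hyperparameters$n_neighbors, 1L)
  expect_false(is.null(attr(best, "cv_mcc")))
  # the protocol's published specs are representable grid members
  grid <- falladl:::model_grid("knn")
  has <- any(vapply(grid, function(g) {
    hp <- g$hyperparameters
    hp$n_neighbors == 1 && hp$distance == "minkowski" &&
      hp$exponent == 0.5 && hp$weighting == "squared_inverse"
  }, TRUE))
  expect_true(has)
  cyc <- vapply(falladl:::model_grid("ensemble_bag"),
                function(g) g$hyperparameters$n_cycles, 0)
  expect_true(37 %in% cyc)
  # grid of size one returns that spec
  expect_equal(gridsearch(sc, "dtree", n_features = 3, cv = 3)$model_id,
               "dtree")
})

test_that("final_test reports on the untouched partition with timing", {
  fm <- sep_fm(200L)
  sc <- scale_features(fm, "per_dataset")
  sp <- make_holdout(sc, seed = 7)
  rep <- final_test(sc, sp, model_spec("knn"), NULL, n_features = 3,
                    seed = 7)
  expect_equal(sum(rep$confusion), length(sp$test_idx))
  expect_equal(rep$macro[["acc"]], 100)  # trivially separable clusters
  expect_named(rep$macro, c("acc", "sens", "spec", "prec", "f1", "mcc"))
  expect_true(is.numeric(rep$train_time_s))
  expect_equal(rep$test_time_per_window_s,
               rep$test_time_s / length(sp$test_idx))
  # overlapping plans are rejected
  sp_bad <- sp
  sp_bad$test_idx <- c(sp_bad$test_idx, sp_bad$train_idx[1])
  expect_error(final_test(sc, sp_bad, model_spec("knn"), NULL, 3),
               "overlap")
})
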