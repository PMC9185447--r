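# Helper: a feature_matrix with chosen values in the first columns and the
# remainder zero-padded to the 199-column contract.
fm_from <- function(X, labels, datasets = NULL) {
  W <- nrow(X)
  vals <- cbind(X, matrix(0, W, 199L - ncol(X)))
  feature_matrix(vals, labels = labels,
                 subject_ids = rep("s", W),
                 dataset_ids = if (is.null(datasets)) rep("d", W) else datasets)
}

test_that("min-max scaling maps columns to [0,1] with stated conventions", {
  X <- cbind(c(2, 4, 6), c(5, 5, 5), c(-1, 0, 3))
  fm <- fm_from(X, labels = c(1L, 1L, 2L))
  sc <- scale_features(fm, "per_dataset")
  expect_equal(sc$values[, 1], c(0, 0.5, 1))
  expect_equal(sc$values[, 2], c(0, 0, 0))  # constant column -> 0
  expect_equal(sc$values[, 3], c(0, 0.25, 1))
  expect_equal(sc$scaling_state, "minmax_per_dataset")
  expect_error(scale_features(sc, "per_dataset"), "already scaled")
})

test_that("per-dataset grouping scales identical raw values differently", {
  X <- matrix(c(0, 10, 0, 5), 4, 1)  # value 10 in ds1, 5 in ds2
  fm <- fm_from(cbind(X, seq_len(4)), labels = rep(c(1L, 2L), 2),
                datasets = c("ds1", "ds1", "ds2", "ds2"))
  sc <- scale_features(fm, "per_dataset")
  # raw 10 (ds1 max) and raw 5 (ds2 max) both scale to 1
  expect_equal(unname(sc$values[2, 1]), 1)
  expect_equal(unname(sc$values[4, 1]), 1)
})

test_that("train-fit scaling uses only the fit rows and clips unseen data", {
  X <- cbind(c(0, 10, 20, -5), c(1, 2, 3, 4))
  fm <- fm_from(X, labels = c(1L, 2L, 1L, 2L))
  sc <- scale_features(fm, "train_fit", fit_idx = 1:2)
  expect_equal(sc$values[1:2, 1], c(0, 1))
  expect_equal(unname(sc$values[3, 1]), 1)  # 20 clips to the train max
  expect_equal(unname(sc$values[4, 1]), 0)  # -5 clips to the train min
  expect_equal(sc$scaler$mins[1], 0, ignore_attr = TRUE)
  expect_equal(sc$scaler$maxs[1], 10, ignore_attr = TRUE)
  # stored parameters reproduce the transform on unseen rows
  fm_new <- fm_from(cbind(c(5, 15), c(0, 0)), labels = c(1L, 2L))
  applied <- apply_scaler(fm_new, sc$scaler)
  expect_equal(applied$values[, 1], c(0.5, 1))
})

test_that("rankings are permutations with deterministic tie-breaks", {
  set.seed(20)
  X <- matrix(runif(60 * 8), 60)
  X <- cbind(X, X[, 1])  # duplicated column
  y <- sample(1:3, 60, replace = TRUE)
  for (m in c("relieff", "mutinf", "mrmr", "cfs", "lasso")) {
    r <- rank_features(X, m, labels = y)
    expect_setequal(r$order, seq_len(ncol(X)))
    expect_length(r$scores, ncol(X))
  }
  # duplicated columns earn equal scores; ascending-id tie-break
  r <- rank_features(X, "mutinf", labels = y)
  expect_equal(r$scores[1], r$scores[9], tolerance = 1e-12)
  expect_lt(which(r$order == 1), which(r$order == 9))
  rr <- rank_features(X, "relieff", labels = y)
  expect_equal(rr$scores[1], rr$scores[9], tolerance = 1e-12)
})

test_that("single-class input is rejected; unknown methods error", {
  X <- matrix(runif(20), 10)
  expect_error(rank_features(X, "relieff", labels = rep(1L, 10)),
               "2 classes")
  expect_error(rank_features(X, "no_such_method", labels = rep(1:2, 5)),
               "unknown ranking method")
})

test_that("custom ranking backends can be registered", {
  register_ranker("reverse", function(X, y, seed) {
    list(order = rev(seq_len(ncol(X))), scores = seq_len(ncol(X)))
  })
  r <- rank_features(matrix(runif(40), 10), "reverse",
                     labels = rep(1:2, 5))
  expect_equal(r$order, 4:1)
})

test_that("Relief-F puts planted informative features on top and matches
           the O(W^2) oracle score for score", {
  set.seed(21)
  W <- 200L
  y <- sample(1:4, W, replace = TRUE)
  informative <- sapply(1:3, function(j) y / 4 + rnorm(W, 0, 0.05))
  noise <- matrix(runif(W * 10), W)
  X <- cbind(informative, noise)
  X <- apply(X, 2, function(c) (c - min(c)) / (max(c) - min(c)))
  r <- rank_features(X, "relieff", labels = y)
  expect_true(all(1:3 %in% r$order[1:5]))
  oracle <- oracle_relieff(X, y, k = 10L)
  expect_equal(r$scores, unname(oracle), tolerance = 1e-12)
})

test_that("Relief-F equals the brute-force oracle on varied small sets", {
  set.seed(22)
  for (i in 1:3) {
    W <- sample(30:100, 1)
    F <- sample(4:12, 1)
    y <- sample(seq_len(sample(2:5, 1)), W, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- 1:2
    X <- matrix(runif(W * F), W)
    r <- rank_features(X, "relieff", labels = y)
    expect_equal(r$scores, unname(oracle_relieff(X, y)), tolerance = 1e-12,
                 info = paste("case", i))
  }
})

test_that("mRMR starts from max relevance, CFS from max class correlation", {
  set.seed(23)
  y <- rep(1:2, each = 30)
  strong <- y + rnorm(60, 0, 0.1)
  weak <- rnorm(60)
  X <- cbind(weak, strong, rnorm(60))
  rm <- rank_features(X, "mrmr", labels = y)
  expect_equal(rm$order[1], 2L)
  rc <- rank_features(X, "cfs", labels = y)
  expect_equal(rc$order[1], 2L)
  rl <- rank_features(X, "lasso", labels = y)
  expect_equal(rl$order[1], 2L)
})

test_that("PCA rank on an analytic two-feature toy", {
  set.seed(24)
  # independent features with variances ~9 and ~1: PC1 explains ~90%
  X2 <- cbind(rnorm(4000, 0, 3), rnorm(4000, 0, 1))
  pr <- pca_rank(X2, target = 0.70)
  expect_equal(pr$n_components, 1L)
  expect_gt(pr$cum_explained, 0.85)
  expect_equal(pr$order[1], 1L)
  expect_equal(sum(pr$resultant_loading), 1, tolerance = 1e-12)
  expect_equal(pr$cap, 2L * pr$n_above_uniform)
})

test_that("PCA outcome invariants hold on random matrices", {
  set.seed(25)
  for (i in 1:5) {
    W <- 150L; F <- sample(5:30, 1)
    X <- matrix(rnorm(W * F), W) %*% diag(runif(F, 0.1, 3))
    pr <- pca_rank(X, target = 0.70)
    expl <- prcomp(X)$sdev^2
    cum <- cumsum(expl) / sum(expl)
    # minimal-m property
    expect_gte(pr$cum_explained, 0.70)
    if (pr$n_components > 1) expect_lt(cum[pr$n_components - 1], 0.70)
    expect_true(all(pr$resultant_loading >= 0))
    expect_equal(sum(pr$resultant_loading), 1, tolerance = 1e-12)
    expect_equal(pr$cap, 2L * sum(pr$resultant_loading > 1 / F))
    expect_setequal(pr$order, seq_len(F))
  }
})

test_that("exactly uniform resultant loadings count as zero above-uniform", {
  # two identical-variance independent features: loadings are symmetric and
  # the resultant is exactly uniform (strict inequality -> count 0)
  X <- cbind(c(1, -1, 1, -1), c(1, 1, -1, -1))
  pr <- pca_rank(X, target = 0.99)
  expect_equal(pr$resultant_loading, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(pr$n_above_uniform, 0L)
  expect_equal(pr$cap, 0L)
})

test_that("pca_rank is invariant to row order", {
  set.seed(26)
  X <- matrix(rnorm(600), 60)
  p1 <- pca_rank(X)
  p2 <- pca_rank(X[sample(60), ])
  expect_equal(p1$resultant_loading, p2$resultant_loading, tolerance = 1e-9)
  expect_equal(p1$order, p2$order)
  expect_error(pca_rank(matrix(1, 10, 3)), "zero-variance")
})
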