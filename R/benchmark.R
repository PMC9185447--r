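# Comparative benchmarking protocol: hold-out split, cross-validated
# progressive feature sweeps, grid search, final test, window-size study.

#' Make a hold-out split plan
#'
#' @param fm A [feature_matrix()].
#' @param ratio Training fraction (default 0.70).
#' @param mode `"windowwise_stratified"` (per-class proportions preserved to
#'   within one window) or `"subjectwise"` (whole subjects on one side).
#' @param seed Integer seed; the same seed always yields the same plan.
#' @return A `split_plan` with disjoint `train_idx` / `test_idx` covering
#'   all windows.
#' @export
make_holdout <- function(fm, ratio = 0.70,
                         mode = c("windowwise_stratified", "subjectwise"),
                         seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  mode <- match.arg(mode)
  W <- nrow(fm$values)
  train <- integer(0)
  with_seed(seed, {
    if (mode == "windowwise_stratified") {
      for (cl in sort(unique(fm$labels))) {
        idx <- which(fm$labels == cl)
        if (length(idx) == 1L) {
          warning("class ", cl, " has a single window; assigned to train",
                  call. = FALSE)
          train <- c(train, idx)
          next
        }
        idx <- sample(idx)
        n_tr <- round(ratio * length(idx))
        n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
        train <- c(train, idx[seq_len(n_tr)])
      }
    } else {
      subjects <- sample(unique(fm$subject_ids))
      target <- ratio * W
      count <- 0
      for (sb in subjects) {
        if (count >= target) break
        idx <- which(fm$subject_ids == sb)
        train <- c(train, idx)
        count <- count + length(idx)
      }
    }
  })
  train <- sort(train)
  structure(list(train_idx = train, test_idx = setdiff(seq_len(W), train),
                 mode = mode, seed = seed, ratio = ratio),
            class = "split_plan")
}

#' Multiclass Matthews correlation coefficient
#'
#' Gorodkin generalisation on the full confusion matrix; returns a value in
#' [-1, 1] (0 when the denominator vanishes).
#'
#' @param confusion K x K count matrix, rows = truth, columns = predicted.
#' @return MCC on the [-1, 1] scale.
#' @export
mcc_multiclass <- function(confusion) {
  C <- as.matrix(confusion)
  s <- sum(C)
  c_ok <- sum(diag(C))
  t_k <- rowSums(C)
  p_k <- colSums(C)
  num <- c_ok * s - sum(t_k * p_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  if (den == 0) 0 else num / den
}

#' Compute the evaluation metrics block from a confusion matrix
#'
#' Per-class one-vs-rest sensitivity, specificity, precision and F1 (with
#' precision 0 when nothing was predicted for a class and F1 0 when both
#' precision and sensitivity are 0), their unweighted macro means, overall
#' accuracy and the multiclass MCC. All values are reported in percent
#' (MCC in [-100, 100]).
#'
#' @param confusion K x K non-negative count matrix, rows = truth.
#' @return An `eval_report` with `confusion`, `per_class` (data frame) and
#'   `macro` (named vector: acc, sens, spec, prec, f1, mcc).
#' @export
compute_metrics <- function(confusion) {
  C <- as.matrix(confusion)
  if (any(C < 0) || sum(C) <= 0) {
    abort_contract("confusion matrix must be non-negative with total > 0")
  }
  K <- nrow(C)
  total <- sum(C)
  cls <- if (!is.null(rownames(C))) rownames(C) else as.character(seq_len(K))
  tp <- diag(C)
  fn <- rowSums(C) - tp
  fp <- colSums(C) - tp
  tn <- total - tp - fn - fp
  sens <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  spec <- ifelse(tn + fp == 0, 0, tn / (tn + fp))
  prec <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  f1 <- ifelse(prec + sens == 0, 0, 2 * prec * sens / (prec + sens))
  present <- (tp + fn + fp) > 0  # classes absent from truth and prediction
  per_class <- data.frame(class = cls, n_true = rowSums(C),
                          sens = 100 * sens, spec = 100 * spec,
                          prec = 100 * prec, f1 = 100 * f1,
                          stringsAsFactors = FALSE)
  macro <- c(acc = 100 * sum(tp) / total,
             sens = 100 * mean(sens[present]),
             spec = 100 * mean(spec[present]),
             prec = 100 * mean(prec[present]),
             f1 = 100 * mean(f1[present]),
             mcc = 100 * mcc_multiclass(C))
  structure(list(confusion = C, per_class = per_class, macro = macro),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  m <- x$macro
  cat(sprintf(
    "<eval_report> ACC %.2f | Sens %.2f | Spec %.2f | Prec %.2f | F1 %.2f | MCC %.2f\n",
    m["acc"], m["sens"], m["spec"], m["prec"], m["f1"], m["mcc"]))
  if (!is.null(x$macro_sd)) {
    cat(sprintf("  across repeats: ACC %.2f +/- %.3f, MCC %.2f +/- %.3f\n",
                m["acc"], x$macro_sd["acc"], m["mcc"], x$macro_sd["mcc"]))
  }
  if (!is.null(x$test_time_s)) {
    cat(sprintf("  train %.3f s, test %.3f s (%.2e s/window)\n",
                x$train_time_s, x$test_time_s, x$test_time_per_window_s))
  }
  invisible(x)
}

confusion_from <- function(truth, pred, classes) {
  table(factor(truth, levels = classes), factor(pred, levels = classes))
}

# Stratified fold assignment: per class, shuffled indices dealt cyclically.
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in sort(unique(y))) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Run (repeated) stratified k-fold cross-validation
#'
#' Each window is tested exactly once per repeat. Metrics are computed on
#' the per-repeat pooled confusion matrix; with several repeats the report
#' carries the mean and standard deviation of each macro metric across
#' repeats, and the summed confusion matrix.
#'
#' @param fm A scaled `feature_matrix`, restricted to the training
#'   partition when used inside the hold-out protocol.
#' @param model A [model_spec()].
#' @param ranking A `ranking_result` ordering the 199 features (or `NULL`
#'   to use the native column order).
#' @param n_features Number of top-ranked features to use.
#' @param k Folds (default 5).
#' @param repeats Repetitions (1 or 10 in the standard protocol).
#' @param seed Integer seed (fold assignment, model bootstraps).
#' @return An `eval_report` (with `macro_sd` when `repeats > 1`).
#' @export
run_cv <- function(fm, model, ranking = NULL, n_features = NULL,
                   k = 5L, repeats = 1L, seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  X <- select_top(fm, ranking, n_features)
  y <- fm$labels
  classes <- sort(unique(y))
  per_repeat <- vector("list", repeats)
  conf_sum <- NULL
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      folds <- stratified_folds(y, k)
      pred <- integer(length(y))
      for (f in seq_len(k)) {
        te <- which(folds == f)
        tr <- which(folds != f)
        fit <- fit_model(model, X[tr, , drop = FALSE], y[tr],
                         seed = seed + 1000L * r + f)
        pred[te] <- predict_model(fit, X[te, , drop = FALSE])
      }
      conf <- confusion_from(y, pred, classes)
      conf_sum <- if (is.null(conf_sum)) unclass(conf) else conf_sum + conf
      per_repeat[[r]] <- compute_metrics(conf)$macro
    }
  })
  macro_mat <- do.call(rbind, per_repeat)
  rep_mean <- colMeans(macro_mat)
  out <- compute_metrics(conf_sum)
  out$macro <- rep_mean
  if (repeats > 1L) out$macro_sd <- apply(macro_mat, 2L, stats::sd)
  out$repeats <- repeats
  out
}

select_top <- function(fm, ranking, n_features) {
  X <- fm$values
  if (is.null(ranking)) {
    if (is.null(n_features)) return(X)
    return(X[, seq_len(n_features), drop = FALSE])
  }
  if (is.null(n_features)) n_features <- length(ranking$order)
  if (n_features > ncol(X)) {
    abort_contract("n_features exceeds the number of available features")
  }
  X[, ranking$order[seq_len(n_features)], drop = FALSE]
}

#' Progressive feature-count sweep
#'
#' For every (model, ranking) pair, evaluates 5-fold CV performance using
#' the top `n` ranked features for `n = stride, 2*stride, ... <= cap` and
#' records MCC and accuracy; `best_n` is the argmax-MCC count (ties go to
#' the smaller n).
#'
#' @param fm Scaled training-partition `feature_matrix`.
#' @param models Named list of [model_spec()]s.
#' @param rankings Named list of `ranking_result`s (names are the
#'   feature-selection method labels).
#' @param cap Maximum feature count (e.g. the [pca_rank()] cap).
#' @param stride Sweep stride (default 1).
#' @param k,seed Cross-validation folds and seed.
#' @return A `sweep_result`: `grid` (data frame model, fsm, n_features, mcc,
#'   acc) and `best` (one row per model x fsm), plus the `cap`.
#' @export
progressive_sweep <- function(fm, models, rankings, cap, stride = 1L,
                              k = 5L, seed = 1L) {
  if (length(models) == 0L || length(rankings) == 0L) {
    abort_contract("models and rankings must be non-empty")
  }
  if (is.null(names(models))) {
    names(models) <- vapply(models, function(m) m$model_id, "")
  }
  ns <- seq(stride, cap, by = stride)
  if (length(ns) == 0L) abort_contract("cap smaller than stride")
  rows <- list()
  for (mi in names(models)) {
    for (fi in names(rankings)) {
      for (n in ns) {
        rep <- run_cv(fm, models[[mi]], rankings[[fi]], n_features = n,
                      k = k, repeats = 1L, seed = seed)
        rows[[length(rows) + 1L]] <- data.frame(
          model = mi, fsm = fi, n_features = n,
          mcc = rep$macro[["mcc"]], acc = rep$macro[["acc"]],
          stringsAsFactors = FALSE)
      }
    }
  }
  grid <- do.call(rbind, rows)
  best <- do.call(rbind, lapply(split(grid, list(grid$model, grid$fsm),
                                      drop = TRUE), function(g) {
    g[order(-g$mcc, g$n_features)[1L], ]
  }))
  rownames(best) <- NULL
  structure(list(grid = grid, best = best, cap = cap),
            class = "sweep_result")
}

#' Grid-search hyperparameters by cross-validated MCC
#'
#' Exhaustive search over the declared grid for the model family
#' (nearest-neighbour: neighbours x distance x weighting; bagged ensemble:
#' number of learning cycles). Ties are resolved toward the simpler model
#' (fewer neighbours / cycles, then declaration order).
#'
#' @param fm Scaled training-partition `feature_matrix`.
#' @param model_id Model family to tune.
#' @param ranking,n_features Feature subset to tune on.
#' @param cv Folds (default 5).
#' @param seed Seed.
#' @return The winning [model_spec()], with the CV MCC in
#'   `attr(, "cv_mcc")` and the full grid table in `attr(, "grid")`.
#' @export
gridsearch <- function(fm, model_id, ranking = NULL, n_features = NULL,
                       cv = 5L, seed = 1L) {
  grid <- model_grid(model_id)
  mccs <- numeric(length(grid))
  for (i in seq_along(grid)) {
    mccs[i] <- run_cv(fm, grid[[i]], ranking, n_features, k = cv,
                      repeats = 1L, seed = seed)$macro[["mcc"]]
  }
  cx <- vapply(grid, grid_complexity, 0)
  best_i <- order(-mccs, cx, seq_along(grid))[1L]
  out <- grid[[best_i]]
  attr(out, "cv_mcc") <- mccs[best_i]
  attr(out, "grid") <- data.frame(
    index = seq_along(grid), complexity = cx, mcc = mccs)
  out
}

#' Final hold-out test
#'
#' Trains the given specification on the training partition only and
#' evaluates once on the untouched test partition, reporting all metrics
#' plus wall-clock training and testing time.
#'
#' @param fm Scaled `feature_matrix` covering all windows.
#' @param split A [make_holdout()] plan.
#' @param spec A [model_spec()].
#' @param ranking,n_features Feature subset.
#' @param seed Seed for model randomness.
#' @return An `eval_report` with `train_time_s`, `test_time_s` and
#'   `test_time_per_window_s`.
#' @export
final_test <- function(fm, split, spec, ranking = NULL, n_features = NULL,
                       seed = 1L) {
  stopifnot(inherits(split, "split_plan"))
  if (length(intersect(split$train_idx, split$test_idx)) > 0L) {
    abort_contract("train and test indices overlap")
  }
  X <- select_top(fm, ranking, n_features)
  y <- fm$labels
  tr <- split$train_idx; te <- split$test_idx
  t0 <- proc.time()[[3L]]
  fit <- fit_model(spec, X[tr, , drop = FALSE], y[tr], seed = seed)
  t1 <- proc.time()[[3L]]
  pred <- predict_model(fit, X[te, , drop = FALSE])
  t2 <- proc.time()[[3L]]
  classes <- sort(unique(y))
  out <- compute_metrics(confusion_from(y[te], pred, classes))
  out$train_time_s <- t1 - t0
  out$test_time_s <- t2 - t1
  out$test_time_per_window_s <- (t2 - t1) / length(te)
  out
}

# Rank features on a training-partition matrix by a named method
# ("pca" uses the resultant-component procedure).
rank_by <- function(fm_train, fsm, seed = 1L) {
  if (fsm == "pca") pca_rank(fm_train) else rank_features(fm_train, fsm,
                                                          seed = seed)
}

#' Window-size comparative study
#'
#' Re-runs segmentation, feature extraction, scaling, ranking (training
#' partition only) and the hold-out evaluation for each window size, for
#' each chosen (model, feature-selection method, feature count)
#' combination; overlap stays fixed (default 80%).
#'
#' @param streams List of `canonical_stream`s.
#' @param sizes Window sizes in seconds (default 0.5, 1, 1.5, 2).
#' @param overlap Fractional overlap (default 0.8).
#' @param best_specs Named list; each element is
#'   `list(spec = model_spec, fsm = "relieff"|"pca"|..., n_features = n)`.
#' @param scaling `"per_dataset"` or `"train_fit"` feature scaling.
#' @param ratio,seed Hold-out parameters.
#' @return Data frame with one row per (combination x size): macro metrics
#'   and timing.
#' @export
window_size_study <- function(streams, sizes = c(0.5, 1, 1.5, 2),
                              overlap = 0.8, best_specs,
                              scaling = c("per_dataset", "train_fit"),
                              ratio = 0.70, seed = 1L) {
  scaling <- match.arg(scaling)
  rows <- list()
  for (ws in sizes) {
    cfg <- segmentation_config(window_s = ws, overlap = overlap)
    fm_raw <- extract_features(segment_streams(streams, cfg))
    split <- make_holdout(fm_raw, ratio = ratio, seed = seed)
    fm <- if (scaling == "per_dataset") {
      scale_features(fm_raw, "per_dataset")
    } else {
      scale_features(fm_raw, "train_fit", fit_idx = split$train_idx)
    }
    for (nm in names(best_specs)) {
      bs <- best_specs[[nm]]
      ranking <- rank_by(subset_features(fm, split$train_idx), bs$fsm,
                         seed = seed)
      n_use <- min(bs$n_features, length(ranking$order))
      rep <- final_test(fm, split, bs$spec, ranking, n_use, seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        combo = nm, model = bs$spec$model_id, fsm = bs$fsm,
        n_features = n_use, window_s = ws, n_windows = nrow(fm$values),
        acc = rep$macro[["acc"]], sens = rep$macro[["sens"]],
        spec = rep$macro[["spec"]], prec = rep$macro[["prec"]],
        f1 = rep$macro[["f1"]], mcc = rep$macro[["mcc"]],
        train_time_s = rep$train_time_s, test_time_s = rep$test_time_s,
        test_time_per_window_s = rep$test_time_per_window_s,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
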