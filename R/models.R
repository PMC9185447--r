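# Classical classifier wrappers with a uniform fit/predict surface.
#
# Discriminant analysis and decision trees are delegated to MASS and rpart;
# the nearest-neighbour classifier is implemented here because the protocol
# requires Minkowski dissimilarities with fractional exponents and
# (squared-)inverse distance weighting; the ensemble is bagged rpart trees.

#' Declare a classifier specification
#'
#' @param model_id One of `"lda"`, `"qda"`, `"knn"`, `"ensemble_bag"`,
#'   `"dtree"`.
#' @param ... Hyperparameters. `knn`: `n_neighbors` (default 1), `distance`
#'   (`"euclidean"`, `"cityblock"`, `"minkowski"`), `exponent` (Minkowski
#'   exponent, default 2), `weighting` (`"uniform"`, `"inverse"`,
#'   `"squared_inverse"`). `ensemble_bag`: `n_cycles` (default 30 bagged
#'   trees). `lda`/`qda`/`dtree`: none.
#' @return A `model_spec`.
#' @examples
#' model_spec("knn", n_neighbors = 1, distance = "minkowski",
#'            exponent = 0.5, weighting = "squared_inverse")
#' model_spec("ensemble_bag", n_cycles = 37)
#' @export
model_spec <- function(model_id = c("lda", "qda", "knn", "ensemble_bag",
                                    "dtree"), ...) {
  model_id <- match.arg(model_id)
  hp <- list(...)
  defaults <- switch(model_id,
    knn = list(n_neighbors = 1L, distance = "euclidean", exponent = 2,
               weighting = "uniform"),
    ensemble_bag = list(n_cycles = 30L),
    list()
  )
  for (nm in names(hp)) defaults[[nm]] <- hp[[nm]]
  if (model_id == "knn") {
    stopifnot(defaults$distance %in% c("euclidean", "cityblock", "minkowski"),
              defaults$weighting %in% c("uniform", "inverse",
                                        "squared_inverse"),
              defaults$n_neighbors >= 1L)
  }
  structure(list(model_id = model_id, hyperparameters = defaults),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  hp <- x$hyperparameters
  cat(sprintf("<model_spec> %s(%s)\n", x$model_id,
              paste(names(hp), unlist(hp), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Fit a classifier
#'
#' @param spec A [model_spec()].
#' @param X Numeric training matrix (windows x features).
#' @param y Integer class labels.
#' @param seed Seed controlling any internal randomness (bootstraps).
#' @return A fitted model handle for [predict_model()].
#' @export
fit_model <- function(spec, X, y, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  X <- as.matrix(X)
  y <- as.integer(y)
  classes <- sort(unique(y))
  fit <- switch(spec$model_id,
    lda = , qda = {
      keep <- which(apply(X, 2L, stats::var) > 0)
      Xk <- X[, keep, drop = FALSE]
      colnames(Xk) <- paste0("f", keep)
      fn <- if (spec$model_id == "lda") MASS::lda else MASS::qda
      list(kind = spec$model_id, keep = keep,
           fit = fn(Xk, grouping = factor(y, levels = classes)))
    },
    knn = list(kind = "knn", X = X, y = y, hp = spec$hyperparameters),
    ensemble_bag = {
      n <- nrow(X)
      df <- as.data.frame(X)
      names(df) <- paste0("f", seq_len(ncol(X)))
      df$.y <- factor(y, levels = classes)
      trees <- with_seed(seed, lapply(seq_len(spec$hyperparameters$n_cycles),
        function(b) {
          idx <- sample.int(n, n, replace = TRUE)
          rpart::rpart(.y ~ ., data = df[idx, , drop = FALSE],
                       method = "class",
                       control = rpart::rpart.control(cp = 0, minsplit = 2L,
                                                      xval = 0L))
        }))
      list(kind = "ensemble_bag", trees = trees)
    },
    dtree = {
      df <- as.data.frame(X)
      names(df) <- paste0("f", seq_len(ncol(X)))
      df$.y <- factor(y, levels = classes)
      list(kind = "dtree",
           fit = rpart::rpart(.y ~ ., data = df, method = "class",
                              control = rpart::rpart.control(xval = 0L)))
    },
    abort_contract("unknown model_id: ", spec$model_id)
  )
  fit$classes <- classes
  fit$n_features <- ncol(X)
  class(fit) <- "falladl_fit"
  fit
}

#' Predict classes for new windows
#'
#' @param fit A [fit_model()] handle.
#' @param X Numeric matrix with the same columns as at fit time.
#' @return Integer class labels.
#' @export
predict_model <- function(fit, X) {
  stopifnot(inherits(fit, "falladl_fit"))
  X <- as.matrix(X)
  if (ncol(X) != fit$n_features) {
    abort_contract("feature count mismatch at predict time")
  }
  switch(fit$kind,
    lda = , qda = {
      Xk <- X[, fit$keep, drop = FALSE]
      colnames(Xk) <- paste0("f", fit$keep)
      as.integer(as.character(stats::predict(fit$fit, Xk)$class))
    },
    knn = knn_predict(fit, X),
    ensemble_bag = {
      df <- as.data.frame(X)
      names(df) <- paste0("f", seq_len(ncol(X)))
      votes <- vapply(fit$trees, function(tr) {
        as.integer(as.character(stats::predict(tr, df, type = "class")))
      }, integer(nrow(X)))
      if (nrow(X) == 1L) votes <- matrix(votes, nrow = 1L)
      apply(votes, 1L, function(v) {
        tb <- table(v)
        cand <- as.integer(names(tb)[tb == max(tb)])
        min(cand)  # vote ties -> smallest class id
      })
    },
    dtree = {
      df <- as.data.frame(X)
      names(df) <- paste0("f", seq_len(ncol(X)))
      as.integer(as.character(stats::predict(fit$fit, df, type = "class")))
    }
  )
}

# Distance-weighted k-nearest-neighbour prediction. Fractional Minkowski
# exponents are accepted as dissimilarities (the triangle inequality is not
# required for neighbour ranking). With inverse weights, any zero-distance
# neighbours take all the weight (uniform among themselves).
knn_predict <- function(fit, Xq) {
  hp <- fit$hp
  k <- as.integer(hp$n_neighbors)
  ntr <- nrow(fit$X)
  nq <- nrow(Xq)
  pred <- integer(nq)
  chunk <- max(1L, floor(2e7 / ntr))
  for (start in seq(1L, nq, by = chunk)) {
    idx <- start:min(start + chunk - 1L, nq)
    D <- knn_dist(Xq[idx, , drop = FALSE], fit$X, hp)
    for (r in seq_along(idx)) {
      d <- D[r, ]
      nb <- order(d)[seq_len(min(k, ntr))]
      dnb <- d[nb]
      w <- switch(hp$weighting,
        uniform = rep(1, length(nb)),
        inverse = if (any(dnb == 0)) as.numeric(dnb == 0) else 1 / dnb,
        squared_inverse = if (any(dnb == 0)) as.numeric(dnb == 0)
                          else 1 / dnb^2)
      votes <- tapply(w, fit$y[nb], sum)
      cand <- as.integer(names(votes)[votes == max(votes)])
      pred[idx[r]] <- min(cand)
    }
  }
  pred
}

knn_dist <- function(A, B, hp) {
  p <- switch(hp$distance, euclidean = 2, cityblock = 1,
              minkowski = hp$exponent)
  if (p == 2) {
    # squared Euclidean via the cross-product identity (monotone in distance)
    d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
      outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
    d2[d2 < 0] <- 0
    sqrt(d2)
  } else {
    D <- matrix(0, nrow(A), nrow(B))
    for (j in seq_len(ncol(A))) {
      D <- D + abs(outer(A[, j], B[, j], "-"))^p
    }
    D^(1 / p)
  }
}

# Declared hyperparameter grids for gridsearch().
model_grid <- function(model_id) {
  switch(model_id,
    knn = {
      dist_opts <- list(
        list(distance = "euclidean", exponent = 2),
        list(distance = "cityblock", exponent = 1),
        list(distance = "minkowski", exponent = 0.5),
        list(distance = "minkowski", exponent = 3)
      )
      grid <- list()
      for (nn in c(1L, 3L, 5L, 7L, 9L)) {
        for (d in dist_opts) {
          for (w in c("uniform", "inverse", "squared_inverse")) {
            grid[[length(grid) + 1L]] <- model_spec(
              "knn", n_neighbors = nn, distance = d$distance,
              exponent = d$exponent, weighting = w)
          }
        }
      }
      grid
    },
    ensemble_bag = lapply(sort(unique(c(seq(10L, 100L, by = 10L), 37L))),
                          function(nc) model_spec("ensemble_bag",
                                                  n_cycles = nc)),
    lda = list(model_spec("lda")),
    qda = list(model_spec("qda")),
    dtree = list(model_spec("dtree")),
    abort_contract("unknown model_id: ", model_id)
  )
}

# "Simpler" ordering used to break gridsearch ties: fewer neighbours /
# fewer cycles first, then declaration order.
grid_complexity <- function(spec) {
  hp <- spec$hyperparameters
  switch(spec$model_id,
    knn = hp$n_neighbors,
    ensemble_bag = hp$n_cycles,
    0)
}
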