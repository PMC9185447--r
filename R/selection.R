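# Feature scaling and feature-selection ranking.

#' Min-max scale a feature matrix to [0, 1]
#'
#' Two groupings are supported. `"per_dataset"` rescales each feature column
#' within each source dataset separately, mirroring the harmonised-corpus
#' protocol in which every source dataset is normalised on its own (this
#' mixes information across any later train/test split and is provided for
#' protocol fidelity). `"train_fit"` fits the column minima/maxima on
#' `fit_idx` (typically the training partition) only, applies them
#' everywhere, clips to [0, 1], and stores them in `$scaler` for reuse on
#' unseen data — the leakage-safe mode.
#'
#' Constant columns map to 0.
#'
#' @param fm A raw [feature_matrix()].
#' @param grouping `"per_dataset"` or `"train_fit"`.
#' @param fit_idx Row indices used to fit the scaler in `"train_fit"` mode
#'   (default: all rows).
#' @return The scaled `feature_matrix` (`scaling_state` updated).
#' @export
scale_features <- function(fm, grouping = c("per_dataset", "train_fit"),
                           fit_idx = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  grouping <- match.arg(grouping)
  if (fm$scaling_state != "raw") {
    abort_contract("feature matrix is already scaled (", fm$scaling_state, ")")
  }
  X <- fm$values
  if (grouping == "per_dataset") {
    for (ds in unique(fm$dataset_ids)) {
      rows <- fm$dataset_ids == ds
      X[rows, ] <- minmax_cols(X[rows, , drop = FALSE])
    }
    out <- fm
    out$values <- X
    out$scaling_state <- "minmax_per_dataset"
    out$scaler <- list(grouping = "per_dataset")
  } else {
    if (is.null(fit_idx)) fit_idx <- seq_len(nrow(X))
    mins <- apply(X[fit_idx, , drop = FALSE], 2L, min)
    maxs <- apply(X[fit_idx, , drop = FALSE], 2L, max)
    out <- fm
    out$values <- apply_minmax(X, mins, maxs)
    out$scaling_state <- "minmax_train_fit"
    out$scaler <- list(grouping = "train_fit", mins = mins, maxs = maxs)
  }
  out
}

minmax_cols <- function(X) {
  apply_minmax(X, apply(X, 2L, min), apply(X, 2L, max))
}

apply_minmax <- function(X, mins, maxs) {
  rng <- maxs - mins
  rng[rng == 0] <- 1  # constant columns -> 0 after shift
  X <- sweep(sweep(X, 2L, mins), 2L, rng, "/")
  X[X < 0] <- 0
  X[X > 1] <- 1
  X
}

#' Apply a stored train-fit scaler to new feature rows
#'
#' @param fm A raw `feature_matrix` of unseen windows.
#' @param scaler The `$scaler` of a `"train_fit"`-scaled matrix.
#' @return The scaled `feature_matrix`.
#' @export
apply_scaler <- function(fm, scaler) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(scaler$mins)) abort_contract("scaler carries no parameters")
  out <- fm
  out$values <- apply_minmax(fm$values, scaler$mins, scaler$maxs)
  out$scaling_state <- "minmax_train_fit"
  out$scaler <- scaler
  out
}

# ---- ranking --------------------------------------------------------------

# Registry of ranking backends. Niche research selectors (ILFS, UFSOL,
# FSASL, FSV) can be plugged in here by the user; the built-ins cover the
# methods the benchmarking protocol actually consumes.
ranker_env <- new.env(parent = emptyenv())

#' Register a custom feature-ranking backend
#'
#' @param name Method name.
#' @param fun `function(X, y, seed)` returning `list(order =, scores =)`.
#' @export
register_ranker <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  assign(name, fun, envir = ranker_env)
  invisible(name)
}

#' Rank features by a feature-selection method
#'
#' Built-in methods: `"relieff"` (k = 10 neighbours per class over all
#' instances), `"mutinf"` (mutual information with the class, 20 equal-width
#' bins), `"mrmr"` (greedy minimum-redundancy maximum-relevance on the same
#' discretisation), `"cfs"` (greedy forward correlation-based merit
#' `k * mean(r_cf) / sqrt(k + k (k - 1) * mean(r_ff))`, class correlation as
#' the correlation ratio), `"lasso"` (order of entry into the one-vs-rest
#' L1-regularised logistic path, earliest entry across classes wins).
#' Additional methods may be added with [register_ranker()]. All built-ins
#' are deterministic; ties are broken by ascending feature id.
#'
#' @param x A scaled [feature_matrix()] or a plain numeric matrix.
#' @param method Method name.
#' @param labels Integer class ids (taken from `x` when it is a
#'   `feature_matrix`).
#' @param seed Seed forwarded to the backend (built-ins do not use
#'   randomness).
#' @return A `ranking_result`: `method`, `order` (feature ids, most to least
#'   important) and `scores` (one per feature, method-specific scale).
#' @export
rank_features <- function(x, method, labels = NULL, seed = 1L) {
  if (inherits(x, "feature_matrix")) {
    if (x$scaling_state == "raw") {
      warning("ranking an unscaled feature matrix", call. = FALSE)
    }
    labels <- x$labels
    X <- x$values
  } else {
    X <- as.matrix(x)
  }
  if (is.null(labels)) abort_contract("labels are required")
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) {
    abort_contract("ranking requires at least 2 classes")
  }
  fun <- switch(method,
    relieff = rank_relieff,
    mutinf = rank_mutinf,
    mrmr = rank_mrmr,
    cfs = rank_cfs,
    lasso = rank_lasso,
    if (exists(method, envir = ranker_env)) get(method, envir = ranker_env)
    else abort_contract("unknown ranking method: ", method)
  )
  res <- fun(X, y, seed)
  structure(list(method = method, order = res$order, scores = res$scores),
            class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, ...) {
  cat(sprintf("<ranking_result> %s over %d features; top 5: %s\n",
              x$method, length(x$order),
              paste(utils::head(x$order, 5L), collapse = ", ")))
  invisible(x)
}

# Descending-score order with ties broken by ascending feature id.
order_desc <- function(scores) {
  order(-scores, seq_along(scores))
}

# ReliefF, k nearest hits and k nearest misses per other class, all
# instances used. Per-feature differences are normalised by the feature's
# data range; instance distance is the Manhattan sum of those differences.
rank_relieff <- function(X, y, seed = 1L, k = 10L) {
  W <- nrow(X); F <- ncol(X)
  rng <- apply(X, 2L, max) - apply(X, 2L, min)
  rng[rng == 0] <- 1
  Xn <- sweep(X, 2L, rng, "/")
  D <- as.matrix(stats::dist(Xn, method = "manhattan"))
  classes <- sort(unique(y))
  prior <- as.numeric(table(factor(y, levels = classes))) / W
  names(prior) <- classes
  scores <- numeric(F)
  cls_idx <- split(seq_len(W), y)
  for (i in seq_len(W)) {
    ci <- as.character(y[i])
    d <- D[i, ]
    # hits
    hits <- setdiff(cls_idx[[ci]], i)
    if (length(hits) > 0L) {
      hits <- hits[order(d[hits], hits)]
      hits <- hits[seq_len(min(k, length(hits)))]
      dif <- abs(sweep(Xn[hits, , drop = FALSE], 2L, Xn[i, ]))
      scores <- scores - colSums(dif) / (W * length(hits))
    }
    # misses, weighted by prior of the miss class over 1 - prior of own
    for (cj in names(cls_idx)) {
      if (cj == ci) next
      mis <- cls_idx[[cj]]
      mis <- mis[order(d[mis], mis)]
      mis <- mis[seq_len(min(k, length(mis)))]
      wgt <- prior[[cj]] / (1 - prior[[ci]])
      dif <- abs(sweep(Xn[mis, , drop = FALSE], 2L, Xn[i, ]))
      scores <- scores + wgt * colSums(dif) / (W * length(mis))
    }
  }
  list(order = order_desc(scores), scores = scores)
}

# 20 equal-width bins over a column's data range.
discretize20 <- function(x, bins = 20L) {
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(rep(1L, length(x)))
  b <- floor((x - lo) / (hi - lo) * bins) + 1L
  b[b > bins] <- bins
  b
}

mi_disc <- function(bx, by) {
  tab <- table(bx, by)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

rank_mutinf <- function(X, y, seed = 1L) {
  scores <- apply(X, 2L, function(col) mi_disc(discretize20(col), y))
  list(order = order_desc(scores), scores = scores)
}

rank_mrmr <- function(X, y, seed = 1L) {
  F <- ncol(X)
  B <- apply(X, 2L, discretize20)
  rel <- vapply(seq_len(F), function(j) mi_disc(B[, j], y), 0)
  ff <- matrix(NA_real_, F, F)  # feature-feature MI, filled lazily
  selected <- integer(0)
  remaining <- seq_len(F)
  scores <- numeric(F)
  first <- remaining[order_desc(rel)[1L]]
  selected <- first; remaining <- setdiff(remaining, first)
  scores[first] <- rel[first]
  red_sum <- numeric(F)
  while (length(remaining) > 0L) {
    last <- selected[length(selected)]
    for (j in remaining) {
      if (is.na(ff[last, j])) {
        ff[last, j] <- ff[j, last] <- mi_disc(B[, last], B[, j])
      }
      red_sum[j] <- red_sum[j] + ff[last, j]
    }
    crit <- rel[remaining] - red_sum[remaining] / length(selected)
    pick <- remaining[order(-crit, remaining)[1L]]
    scores[pick] <- crit[match(pick, remaining)]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  # scores are the mRMR criterion at entry; decreasing rank = entry order
  list(order = selected, scores = scores)
}

# Correlation ratio (eta) between a numeric feature and the class factor.
corr_ratio <- function(x, y) {
  tot <- sum((x - mean(x))^2)
  if (tot == 0) return(0)
  mk <- tapply(x, y, mean)
  nk <- tapply(x, y, length)
  sqrt(sum(nk * (mk - mean(x))^2) / tot)
}

rank_cfs <- function(X, y, seed = 1L) {
  F <- ncol(X)
  rcf <- vapply(seq_len(F), function(j) corr_ratio(X[, j], y), 0)
  rff <- abs(suppressWarnings(stats::cor(X)))
  rff[is.na(rff)] <- 0  # constant columns
  diag(rff) <- 1
  selected <- integer(0)
  remaining <- seq_len(F)
  scores <- numeric(F)
  sum_rcf <- 0
  ff_to_sel <- numeric(F)  # sum of r_ff between each feature and selected set
  while (length(remaining) > 0L) {
    k <- length(selected) + 1L
    pairsum <- sum_pair_ff(selected, rff)
    merit <- vapply(remaining, function(j) {
      num <- sum_rcf + rcf[j]  # = k * mean r_cf over the candidate set
      den <- sqrt(k + if (k == 1L) 0 else 2 * (pairsum + ff_to_sel[j]))
      num / den
    }, 0)
    pick <- remaining[order(-merit, remaining)[1L]]
    scores[pick] <- merit[match(pick, remaining)]
    sum_rcf <- sum_rcf + rcf[pick]
    for (j in remaining) ff_to_sel[j] <- ff_to_sel[j] + rff[pick, j]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  list(order = selected, scores = scores)
}

sum_pair_ff <- function(selected, rff) {
  if (length(selected) < 2L) return(0)
  s <- rff[selected, selected]
  (sum(s) - length(selected)) / 2
}

rank_lasso <- function(X, y, seed = 1L) {
  F <- ncol(X)
  classes <- sort(unique(y))
  entry <- matrix(0, F, length(classes))  # lambda at which feature enters
  for (ci in seq_along(classes)) {
    yb <- as.integer(y == classes[ci])
    fit <- glmnet::glmnet(X, yb, family = "binomial",
                          standardize = FALSE, nlambda = 100)
    beta <- as.matrix(fit$beta)
    for (j in seq_len(F)) {
      nz <- which(beta[j, ] != 0)
      if (length(nz) > 0L) entry[j, ci] <- fit$lambda[nz[1L]]
    }
  }
  scores <- apply(entry, 1L, max)
  list(order = order_desc(scores), scores = scores)
}

# ---- PCA resultant-component ranking --------------------------------------

#' PCA resultant-component feature ranking and feature-count cap
#'
#' Runs PCA on the scaled feature matrix (mean-centred, no
#' re-standardisation), keeps the smallest number of principal components
#' whose cumulative explained variance reaches `target`, and combines their
#' absolute loadings — each component weighted by its share of the retained
#' explained variance — into a single non-negative "resultant" loading
#' vector normalised to sum to 1. Features are ranked by descending
#' resultant loading; the number of features whose loading strictly exceeds
#' the uniform share 1/F, doubled, gives the feature-count cap used by the
#' progressive sweep.
#'
#' @param x A scaled [feature_matrix()] or plain numeric matrix.
#' @param target Cumulative explained-variance target (default 0.70).
#' @return A `pca_rank_outcome` (also a `ranking_result`): `n_components`,
#'   `cum_explained`, `resultant_loading`, `n_above_uniform`,
#'   `cap = 2 * n_above_uniform`, `order`, `scores`.
#' @export
pca_rank <- function(x, target = 0.70) {
  if (inherits(x, "feature_matrix")) {
    if (x$scaling_state == "raw") {
      warning("running PCA on an unscaled feature matrix", call. = FALSE)
    }
    X <- x$values
  } else {
    X <- as.matrix(x)
  }
  F <- ncol(X)
  if (nrow(X) <= F) {
    warning("fewer rows than features; PCA loadings may be unstable",
            call. = FALSE)
  }
  vars <- apply(X, 2L, stats::var)
  if (all(vars == 0)) abort_contract("zero-variance matrix: PCA undefined")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  cum <- cumsum(explained)
  m <- which(cum >= target)[1L]
  if (is.na(m)) m <- length(explained)
  w <- explained[seq_len(m)] / sum(explained[seq_len(m)])
  resultant <- as.numeric(abs(pc$rotation[, seq_len(m), drop = FALSE]) %*% w)
  resultant <- resultant / sum(resultant)
  n_above <- sum(resultant > 1 / F)
  structure(
    list(method = "pca", n_components = m, cum_explained = cum[m],
         resultant_loading = resultant, n_above_uniform = n_above,
         cap = 2L * n_above, order = order_desc(resultant),
         scores = resultant),
    class = c("pca_rank_outcome", "ranking_result")
  )
}

#' @export
print.pca_rank_outcome <- function(x, ...) {
  cat(sprintf(
    "<pca_rank_outcome> %d PCs (%.1f%% explained), %d features above 1/%d, cap %d\n",
    x$n_components, 100 * x$cum_explained, x$n_above_uniform,
    length(x$resultant_loading), x$cap))
  invisible(x)
}

#' Write a ranking as CSV (rank, feature id, name, score)
#'
#' @param ranking A `ranking_result`.
#' @param path CSV path.
#' @param registry Feature registry used for names; defaults to the 199-row
#'   bank when the ranking covers 199 features.
#' @export
write_ranking_csv <- function(ranking, path, registry = NULL) {
  n <- length(ranking$order)
  nm <- if (!is.null(registry)) registry$name
        else if (n == 199L) feature_registry()$name
        else paste0("f", seq_len(n))
  df <- data.frame(rank = seq_len(n), feature_id = ranking$order,
                   name = nm[ranking$order],
                   score = ranking$scores[ranking$order])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
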