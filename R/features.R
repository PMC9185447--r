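# 199-feature bank computed on each L x 6 window (50 Hz canonical streams).
#
# Eight "signals" are derived from the 6 channels: the 3 accelerometer axes,
# the 3 gyroscope axes, and the per-sample vector magnitude (SumVM) of each
# sensor. Features are grouped in the row-group order of the published bank;
# ids run contiguously 1..199.

CHANNELS6 <- c("acc_ap", "acc_ml", "acc_v", "gyr_ap", "gyr_ml", "gyr_v")
SIGNALS8 <- c(CHANNELS6, "acc_svm", "gyr_svm")

#' The feature registry
#'
#' Deterministic table of the 199 per-window features: window-terminal
#' values, distribution moments, order statistics, inter-axis correlations,
#' kinematic summaries (signal magnitude area, displacement, sway, angular
#' change), waveform-shape counts, spectral summaries and SumVM aggregates.
#'
#' @return A data frame with one row per feature: `feature_id` (1..199),
#'   `name`, `category` (row group), `source_channel` and `domain`
#'   (`"time"` or `"frequency"`).
#' @examples
#' reg <- feature_registry()
#' nrow(reg)          # 199
#' table(reg$domain)
#' @export
feature_registry <- function() {
  if (!is.null(registry_cache$reg)) return(registry_cache$reg)
  reg <- build_registry()
  registry_cache$reg <- reg
  reg
}

registry_cache <- new.env(parent = emptyenv())

build_registry <- function() {
  rows <- list()
  add <- function(name, category, channel, domain = "time") {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, category = category, source_channel = channel,
      domain = domain, stringsAsFactors = FALSE)
  }
  # [1-6] window-terminal value of the six raw channels
  for (ch in CHANNELS6) add(paste0("terminal_", ch), "terminal_value", ch)
  # [7-8] window-terminal SumVM of each sensor
  add("terminal_acc_svm", "terminal_sumvm", "acc_svm")
  add("terminal_gyr_svm", "terminal_sumvm", "gyr_svm")
  # [9-24] skewness and kurtosis of the eight signals
  for (ch in SIGNALS8) add(paste0("skew_", ch), "moments", ch)
  for (ch in SIGNALS8) add(paste0("kurt_", ch), "moments", ch)
  # [25-64] min / max / mean / variance / std of the eight signals
  for (st in c("min", "max", "mean", "var", "std")) {
    for (ch in SIGNALS8) add(paste0(st, "_", ch), "order_moments", ch)
  }
  # [65-70] inter-axis Pearson correlations (V-ML, V-AP, ML-AP per sensor)
  for (sn in c("acc", "gyr")) {
    add(paste0("corr_", sn, "_v_ml"), "correlation", "cross-channel")
    add(paste0("corr_", sn, "_v_ap"), "correlation", "cross-channel")
    add(paste0("corr_", sn, "_ml_ap"), "correlation", "cross-channel")
  }
  # [71-77] kinematic scalars
  for (nm in c("slope_acc_svm", "total_angular_change",
               "resultant_angular_acceleration", "asma", "sma",
               "abs_vertical_acc", "cum_horizontal_displacement")) {
    add(nm, "kinematic", "cross-channel")
  }
  # [78-101] peak-to-peak, RMS, ratio index of the eight signals
  for (st in c("p2p", "rms", "ratio_index")) {
    for (ch in SIGNALS8) add(paste0(st, "_", ch), "amplitude", ch)
  }
  # [102-114] resultant angle change, fluctuation frequency, resultants of
  # per-axis means and stds
  add("resultant_angle_change", "resultants", "cross-channel")
  for (ch in SIGNALS8) add(paste0("fluct_freq_", ch), "resultants", ch)
  add("resultant_mean_acc", "resultants", "cross-channel")
  add("resultant_std_acc", "resultants", "cross-channel")
  add("resultant_mean_gyr", "resultants", "cross-channel")
  add("resultant_std_gyr", "resultants", "cross-channel")
  # [115-122] delta changes (last - first) per axis and their resultants
  for (ch in CHANNELS6[1:3]) add(paste0("delta_", ch), "delta", ch)
  add("delta_resultant_acc", "delta", "cross-channel")
  for (ch in CHANNELS6[4:6]) add(paste0("delta_", ch), "delta", ch)
  add("delta_resultant_gyr", "delta", "cross-channel")
  # [123-133] gravity component, displacement, displacement range, sway
  for (ch in CHANNELS6[1:3]) add(paste0("gravity_", ch), "displacement", ch)
  for (ch in CHANNELS6[1:3]) add(paste0("displacement_", ch), "displacement", ch)
  for (ch in CHANNELS6[1:3]) add(paste0("disp_range_", ch), "displacement", ch)
  add("cum_sway_length", "displacement", "cross-channel")
  add("mean_sway_velocity", "displacement", "cross-channel")
  # [134-157] slope changes, zero crossings, waveform length
  for (st in c("slope_changes", "zero_crossings", "waveform_length")) {
    for (ch in SIGNALS8) add(paste0(st, "_", ch), "waveform", ch)
  }
  # [158-189] spectral energy, mean frequency, peak frequency, peak magnitude
  for (st in c("spec_energy", "mean_freq", "peak_freq", "peak_mag")) {
    for (ch in SIGNALS8) add(paste0(st, "_", ch), "spectral", ch, "frequency")
  }
  # [190-195] SumVM-of-resultant aggregates
  add("median_acc_svm", "sumvm_aggregates", "acc_svm")
  add("median_gyr_svm", "sumvm_aggregates", "gyr_svm")
  add("iqr_acc_svm", "sumvm_aggregates", "acc_svm")
  add("iqr_gyr_svm", "sumvm_aggregates", "gyr_svm")
  add("mean_horizontal_acc", "sumvm_aggregates", "cross-channel")
  add("max_horizontal_acc", "sumvm_aggregates", "cross-channel")
  # [196-199] EMA, rotational angle, Z-score, angular displacement
  add("ema_acc_svm", "closing", "acc_svm")
  add("rot_angle_acc_svm", "closing", "cross-channel")
  add("zscore_acc_svm", "closing", "acc_svm")
  add("angular_displacement_magnitude", "closing", "cross-channel")

  reg <- do.call(rbind, rows)
  reg <- cbind(feature_id = seq_len(nrow(reg)), reg)
  stopifnot(nrow(reg) == 199L, !anyDuplicated(reg$name))
  reg
}

# Population skewness; 0 when the variance is 0.
pop_skew <- function(x) {
  m2 <- pop_moment(x, 2)
  if (m2 == 0) return(0)
  pop_moment(x, 3) / m2^1.5
}

# Pearson (non-excess) population kurtosis; 0 when the variance is 0.
pop_kurt <- function(x) {
  m2 <- pop_moment(x, 2)
  if (m2 == 0) return(0)
  pop_moment(x, 4) / m2^2
}

# Pearson correlation with the 0-on-degenerate convention.
safe_cor <- function(x, y) {
  if (stats::var(x) == 0 || stats::var(y) == 0) return(0)
  stats::cor(x, y)
}

# Count of sign changes of (x - mean(x)) between consecutive samples.
mean_crossings <- function(x) {
  c0 <- x - mean(x)
  sum(c0[-length(c0)] * c0[-1L] < 0)
}

# Cumulative trapezoidal integral sampled on the window grid, dt spacing.
cum_trapz <- function(x, dt) {
  c(0, cumsum((x[-1L] + x[-length(x)]) / 2 * dt))
}

#' Extract the 199-feature vector from one window
#'
#' @param window An L x 6 numeric matrix (L >= 2), channel order
#'   acc AP/ML/V then gyro AP/ML/V (m/s^2, deg/s).
#' @param rate Sampling rate in Hz (50 for canonical streams).
#' @return Named numeric vector of length 199, in [feature_registry()]
#'   order; all values finite.
#' @export
extract_window <- function(window, rate = CANONICAL_RATE) {
  window <- as.matrix(window)
  L <- nrow(window)
  if (L < 2L || ncol(window) != 6L) {
    abort_contract("window must be an L x 6 matrix with L >= 2")
  }
  if (!all(is.finite(window))) {
    abort_contract("non-finite values in window")
  }
  dt <- 1 / rate
  dur <- L / rate
  acc <- window[, 1:3, drop = FALSE]
  gyr <- window[, 4:6, drop = FALSE]
  acc_svm <- sqrt(rowSums(acc^2))
  gyr_svm <- sqrt(rowSums(gyr^2))
  sig <- cbind(window, acc_svm, gyr_svm)  # L x 8, SIGNALS8 order
  out <- numeric(0)

  # terminal values [1-8]
  out <- c(out, sig[L, 1:6], acc_svm[L], gyr_svm[L])
  # moments [9-24]
  out <- c(out, apply(sig, 2L, pop_skew), apply(sig, 2L, pop_kurt))
  # order statistics & dispersion [25-64]
  out <- c(out, apply(sig, 2L, min), apply(sig, 2L, max),
           colMeans(sig), apply(sig, 2L, stats::var),
           apply(sig, 2L, stats::sd))
  # correlations [65-70]: V-ML, V-AP, ML-AP per sensor
  out <- c(out,
           safe_cor(acc[, 3L], acc[, 2L]), safe_cor(acc[, 3L], acc[, 1L]),
           safe_cor(acc[, 2L], acc[, 1L]),
           safe_cor(gyr[, 3L], gyr[, 2L]), safe_cor(gyr[, 3L], gyr[, 1L]),
           safe_cor(gyr[, 2L], gyr[, 1L]))
  # kinematic scalars [71-77]
  tvec <- (seq_len(L) - 1L) * dt
  slope <- stats::cov(tvec, acc_svm) / stats::var(tvec)
  total_ang <- sum(gyr_svm) * dt
  dgyr <- diff(gyr) / dt
  res_ang_acc <- max(sqrt(rowSums(dgyr^2)))
  acc_c <- sweep(acc, 2L, colMeans(acc))
  asma <- mean(rowSums(abs(acc_c)))
  sma <- mean(rowSums(abs(acc)))
  abs_vert <- mean(abs(acc[, 3L] - GRAVITY))
  disp <- vapply(1:3, function(j) {
    v <- cum_trapz(acc_c[, j], dt)
    cum_trapz(v, dt)
  }, numeric(L))
  disp_range <- apply(disp, 2L, function(d) max(d) - min(d))
  cum_horiz <- sqrt(disp_range[1L]^2 + disp_range[2L]^2)
  out <- c(out, slope, total_ang, res_ang_acc, asma, sma, abs_vert, cum_horiz)
  # amplitude [78-101]
  out <- c(out,
           apply(sig, 2L, function(x) max(x) - min(x)),
           apply(sig, 2L, function(x) sqrt(mean(x^2))),
           vapply(seq_len(8L), function(j) {
             ref <- if (j %in% c(1:3, 7L)) max(acc_svm) else max(gyr_svm)
             if (ref == 0) 0 else max(abs(sig[, j])) / ref
           }, 0))
  # resultants [102-114]
  n1 <- sqrt(sum(acc[1L, ]^2)); nL <- sqrt(sum(acc[L, ]^2))
  res_angle <- if (n1 == 0 || nL == 0) 0 else {
    acos(min(1, max(-1, sum(acc[1L, ] * acc[L, ]) / (n1 * nL))))
  }
  out <- c(out, res_angle,
           apply(sig, 2L, mean_crossings) / dur,
           sqrt(sum(colMeans(acc)^2)), sqrt(sum(apply(acc, 2L, stats::sd)^2)),
           sqrt(sum(colMeans(gyr)^2)), sqrt(sum(apply(gyr, 2L, stats::sd)^2)))
  # delta changes [115-122]
  dacc <- acc[L, ] - acc[1L, ]
  dgy <- gyr[L, ] - gyr[1L, ]
  out <- c(out, dacc, sqrt(sum(dacc^2)), dgy, sqrt(sum(dgy^2)))
  # gravity / displacement / sway [123-133]
  sway_steps <- sqrt(diff(disp[, 1L])^2 + diff(disp[, 2L])^2)
  sway <- sum(sway_steps)
  out <- c(out, colMeans(acc), disp[L, ], disp_range, sway, sway / dur)
  # waveform [134-157]
  out <- c(out,
           apply(sig, 2L, function(x) {
             d <- diff(x)
             sum(d[-length(d)] * d[-1L] < 0)
           }),
           apply(sig, 2L, mean_crossings),
           apply(sig, 2L, function(x) sum(abs(diff(x)))))
  # spectral [158-189]
  spec <- lapply(seq_len(8L), function(j) {
    x <- sig[, j]
    X <- stats::fft(x - mean(x))
    k <- seq_len(L %/% 2L)
    list(power = Mod(X[k + 1L])^2, freq = k * rate / L)
  })
  nyq_even <- L %% 2L == 0L
  energy <- vapply(spec, function(s) {
    p <- s$power
    if (nyq_even) (2 * sum(p[-length(p)]) + p[length(p)]) / L
    else 2 * sum(p) / L
  }, 0)
  mean_f <- vapply(spec, function(s) {
    tot <- sum(s$power)
    if (tot == 0) 0 else sum(s$freq * s$power) / tot
  }, 0)
  peak_i <- vapply(spec, function(s) which.max(s$power), 0L)
  peak_f <- vapply(seq_len(8L), function(j) {
    if (sum(spec[[j]]$power) == 0) 0 else spec[[j]]$freq[peak_i[j]]
  }, 0)
  peak_m <- vapply(seq_len(8L), function(j) {
    2 * sqrt(spec[[j]]$power[peak_i[j]]) / L
  }, 0)
  out <- c(out, energy, mean_f, peak_f, peak_m)
  # SumVM aggregates [190-195]
  horiz <- sqrt(acc[, 1L]^2 + acc[, 2L]^2)
  out <- c(out,
           stats::median(acc_svm), stats::median(gyr_svm),
           unname(stats::quantile(acc_svm, 0.75) - stats::quantile(acc_svm, 0.25)),
           unname(stats::quantile(gyr_svm, 0.75) - stats::quantile(gyr_svm, 0.25)),
           mean(horiz), max(horiz))
  # closing features [196-199]
  ema <- acc_svm[1L]
  for (t in seq_len(L)[-1L]) ema <- 0.1 * acc_svm[t] + 0.9 * ema
  ratio_v <- ifelse(acc_svm == 0, 1, pmin(1, pmax(-1, acc[, 3L] / acc_svm)))
  rot_angle <- mean(ifelse(acc_svm == 0, 0, acos(ratio_v)))
  s_sd <- stats::sd(acc_svm)
  zsc <- if (s_sd == 0) 0 else (acc_svm[L] - mean(acc_svm)) / s_sd
  ang_disp <- sqrt(sum(vapply(1:3, function(j) {
    d <- cum_trapz(gyr[, j], dt)
    d[L]
  }, 0)^2))
  out <- c(out, ema, rot_angle, zsc, ang_disp)

  names(out) <- feature_registry()$name
  stopifnot(length(out) == 199L)
  if (!all(is.finite(out))) {
    abort_contract("non-finite feature value(s): ",
                   paste(names(out)[!is.finite(out)], collapse = ", "))
  }
  out
}

#' Extract features for a whole window set
#'
#' @param ws A [segment_streams()] `window_set`.
#' @return An object of class `feature_matrix`: `values` (W x 199 matrix),
#'   the feature `registry`, carried-over `labels`, `subject_ids`,
#'   `dataset_ids`, and `scaling_state = "raw"`.
#' @export
extract_features <- function(ws) {
  stopifnot(inherits(ws, "window_set"))
  W <- dim(ws$windows)[1L]
  if (W < 1L) abort_contract("window set is empty")
  reg <- feature_registry()
  rate <- ws$config$rate
  vals <- matrix(0, W, 199L, dimnames = list(NULL, reg$name))
  for (i in seq_len(W)) {
    row <- tryCatch(extract_window(ws$windows[i, , ], rate),
                    error = function(e) {
                      abort_contract("window ", i, ": ", conditionMessage(e))
                    })
    vals[i, ] <- row
  }
  feature_matrix(vals, labels = ws$labels, subject_ids = ws$subject_ids,
                 dataset_ids = ws$dataset_ids)
}

#' Construct a feature matrix object
#'
#' @param values W x 199 numeric matrix (columns in registry order).
#' @param labels Integer class ids per window.
#' @param subject_ids,dataset_ids Character vectors per window.
#' @param scaling_state One of `"raw"`, `"minmax_per_dataset"`,
#'   `"minmax_train_fit"`.
#' @param scaler Optional stored scaling parameters (see
#'   [scale_features()]).
#' @return A `feature_matrix`.
#' @export
feature_matrix <- function(values, labels, subject_ids, dataset_ids,
                           scaling_state = "raw", scaler = NULL) {
  values <- as.matrix(values)
  if (ncol(values) != 199L) abort_contract("feature matrix must have 199 columns")
  colnames(values) <- feature_registry()$name
  if (nrow(values) != length(labels)) {
    abort_contract("labels length must equal the number of rows")
  }
  structure(
    list(values = values, registry = feature_registry(),
         labels = as.integer(labels),
         subject_ids = as.character(subject_ids),
         dataset_ids = as.character(dataset_ids),
         scaling_state = scaling_state, scaler = scaler),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d windows x %d features (%s), %d classes\n",
              nrow(x$values), ncol(x$values), x$scaling_state,
              length(unique(x$labels))))
  invisible(x)
}

#' Subset a feature matrix by window index
#'
#' @param fm A `feature_matrix`.
#' @param idx Integer window indices to keep.
#' @return A `feature_matrix` restricted to `idx`.
#' @export
subset_features <- function(fm, idx) {
  stopifnot(inherits(fm, "feature_matrix"))
  feature_matrix(fm$values[idx, , drop = FALSE], fm$labels[idx],
                 fm$subject_ids[idx], fm$dataset_ids[idx],
                 scaling_state = fm$scaling_state, scaler = fm$scaler)
}

#' Write a feature matrix as CSV (+ JSON-free descriptor sidecar)
#'
#' The CSV holds one row per window (header = feature names) followed by
#' `label`, `subject`, `dataset` columns; the registry can always be
#' regenerated with [feature_registry()].
#'
#' @param fm A `feature_matrix`.
#' @param path CSV path.
#' @export
write_features_csv <- function(fm, path) {
  df <- as.data.frame(fm$values)
  df$label <- fm$labels
  df$subject <- fm$subject_ids
  df$dataset <- fm$dataset_ids
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  reg <- feature_registry()
  feature_matrix(as.matrix(df[, reg$name]), df$label, df$subject, df$dataset)
}
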