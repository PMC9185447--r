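#' Sliding-window segmentation configuration
#'
#' Window length `L = round(window_s * 50)` samples and hop
#' `H = max(1, round(L * (1 - overlap)))` samples. The default 1 s window
#' with 80% overlap gives L = 50, H = 10.
#'
#' @param window_s Window size in seconds (typically 0.5, 1, 1.5 or 2).
#' @param overlap Fractional overlap between consecutive windows, in [0, 1).
#' @param rate Sampling rate (fixed at 50 Hz for canonical streams).
#' @return An object of class `segmentation_config` with fields `window_s`,
#'   `overlap`, `L`, `H`.
#' @export
segmentation_config <- function(window_s = 1.0, overlap = 0.8,
                                rate = CANONICAL_RATE) {
  if (!is_scalar_number(window_s) || window_s <= 0) {
    abort_contract("window_s must be a positive number of seconds")
  }
  if (!is_scalar_number(overlap) || overlap < 0 || overlap >= 1) {
    abort_contract("overlap must lie in [0, 1)")
  }
  L <- as.integer(round(window_s * rate))
  if (L < 2L) abort_contract("window too short: L must be >= 2 samples")
  H <- max(1L, as.integer(round(L * (1 - overlap))))
  structure(list(window_s = window_s, overlap = overlap, rate = rate,
                 L = L, H = H),
            class = "segmentation_config")
}

#' Mode label of a window
#'
#' Returns the most frequent class id among the window's per-sample labels.
#' Ties are broken in favour of the tied label whose last occurrence in the
#' window is latest, biasing toward the activity the subject is entering.
#'
#' @param sample_labels Integer vector of per-sample class ids (length >= 1).
#' @return A single class id present in the window.
#' @examples
#' mode_label(c(1, 1, 1, 2, 2))            # 1 (strict mode)
#' mode_label(c(rep(1, 25), rep(17, 25)))  # 17 (tie -> latest occurrence)
#' @export
mode_label <- function(sample_labels) {
  if (length(sample_labels) < 1L) {
    abort_contract("mode_label needs at least one sample label")
  }
  counts <- table(sample_labels)
  top <- as.integer(names(counts)[counts == max(counts)])
  if (length(top) == 1L) return(top)
  last_pos <- vapply(top, function(lb) max(which(sample_labels == lb)), 0L)
  top[which.max(last_pos)]
}

#' Segment canonical streams into an overlapping window set
#'
#' Window k of a stream covers samples `[k*H + 1, k*H + L]` (1-based);
#' windows never span stream boundaries. A stream with fewer than L samples
#' contributes zero windows (reported via a message). Each window receives
#' one label by [mode_label()] plus its stream's subject and dataset ids.
#'
#' @param streams A `canonical_stream` or list of them.
#' @param cfg A [segmentation_config()].
#' @return An object of class `window_set`: `windows` is a W x L x 6 array
#'   (channel order acc AP/ML/V then gyro AP/ML/V), with vectors `labels`,
#'   `subject_ids`, `dataset_ids` and the `config`.
#' @export
segment_streams <- function(streams, cfg = segmentation_config()) {
  stopifnot(inherits(cfg, "segmentation_config"))
  if (inherits(streams, "canonical_stream")) streams <- list(streams)
  L <- cfg$L; H <- cfg$H
  n_win <- vapply(streams, function(s) {
    n <- nrow(s$acc)
    if (n < L) 0L else as.integer(floor((n - L) / H) + 1L)
  }, 0L)
  if (any(n_win == 0L)) {
    message(sum(n_win == 0L), " stream(s) shorter than one window; skipped")
  }
  W <- sum(n_win)
  windows <- array(0, dim = c(W, L, 6L))
  labels <- integer(W); subj <- character(W); dset <- character(W)
  w <- 0L
  for (si in seq_along(streams)) {
    s <- streams[[si]]
    if (n_win[si] == 0L) next
    chans <- cbind(s$acc, s$gyro)
    for (k in seq_len(n_win[si]) - 1L) {
      idx <- (k * H + 1L):(k * H + L)
      w <- w + 1L
      windows[w, , ] <- chans[idx, ]
      labels[w] <- mode_label(s$labels[idx])
      subj[w] <- s$subject_id
      dset[w] <- s$dataset_id
    }
  }
  structure(list(windows = windows, labels = labels, subject_ids = subj,
                 dataset_ids = dset, config = cfg),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of %d samples x 6 channels (%.1f s @ %d Hz, hop %d)\n",
              dim(x$windows)[1L], x$config$L, x$config$window_s,
              x$config$rate, x$config$H))
  invisible(x)
}

#' Number of windows a stream of N samples yields
#'
#' Closed form `max(0, floor((N - L)/H) + 1)`.
#'
#' @param n_samples Stream length N.
#' @param cfg A [segmentation_config()].
#' @return Integer window count.
#' @export
n_windows <- function(n_samples, cfg) {
  if (n_samples < cfg$L) return(0L)
  as.integer(floor((n_samples - cfg$L) / cfg$H) + 1L)
}
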