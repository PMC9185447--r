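#' Sensor mapping for a source dataset
#'
#' Describes how a source dataset's native sensor frame maps onto the
#' canonical waist frame: anteroposterior (AP), mediolateral (ML) and
#' vertical/longitudinal (V) axes. Each canonical axis is assigned one signed
#' native axis (e.g. `AP = "+y"`), the implied 3x3 signed permutation must be
#' a proper rotation (determinant +1, handedness preserved).
#'
#' @param axis_map Named character vector or list with entries `AP`, `ML`,
#'   `V`, each one of `"+x" "-x" "+y" "-y" "+z" "-z"`, using every native
#'   axis exactly once.
#' @param acc_unit `"m/s^2"` or `"g"` (converted by 9.81).
#' @param gyro_unit `"deg/s"` or `"rad/s"` (converted by 180/pi).
#' @param native_rate Native sampling rate in Hz (> 0).
#' @param acc_range Optional symmetric accelerometer saturation bound, in
#'   `acc_unit`; recorded for provenance (the synthetic generator uses it to
#'   emulate sensor clipping).
#' @return An object of class `sensor_mapping`.
#' @examples
#' sensor_mapping(c(AP = "+y", ML = "-x", V = "+z"), "g", "rad/s", 100)
#' @export
sensor_mapping <- function(axis_map,
                           acc_unit = c("m/s^2", "g"),
                           gyro_unit = c("deg/s", "rad/s"),
                           native_rate,
                           acc_range = NULL) {
  acc_unit <- match.arg(acc_unit)
  gyro_unit <- match.arg(gyro_unit)
  axis_map <- unlist(axis_map)
  if (!setequal(names(axis_map), c("AP", "ML", "V"))) {
    abort_contract("axis_map must name exactly AP, ML and V")
  }
  axis_map <- axis_map[c("AP", "ML", "V")]
  ok <- grepl("^[+-][xyz]$", axis_map)
  if (!all(ok)) {
    abort_contract("axis_map entries must look like '+y' or '-z'")
  }
  native <- substr(axis_map, 2L, 2L)
  if (length(unique(native)) != 3L) {
    abort_contract("axis_map must use each native axis exactly once")
  }
  R <- mapping_matrix(axis_map)
  if (round(det(R)) != 1) {
    abort_contract("axis_map implies determinant -1 (handedness flipped); ",
                   "flip one sign to obtain a proper rotation")
  }
  if (!is_scalar_number(native_rate) || native_rate <= 0) {
    abort_contract("native_rate must be a positive number (Hz)")
  }
  if (!is.null(acc_range) &&
      (!is_scalar_number(acc_range) || acc_range <= 0)) {
    abort_contract("acc_range must be NULL or a positive number")
  }
  structure(
    list(axis_map = axis_map, acc_unit = acc_unit, gyro_unit = gyro_unit,
         native_rate = native_rate, acc_range = acc_range),
    class = "sensor_mapping"
  )
}

# 3x3 signed permutation, canonical = R %*% native.
mapping_matrix <- function(axis_map) {
  R <- matrix(0, 3L, 3L, dimnames = list(c("AP", "ML", "V"), c("x", "y", "z")))
  for (i in seq_len(3L)) {
    sgn <- if (substr(axis_map[[i]], 1L, 1L) == "-") -1 else 1
    R[i, substr(axis_map[[i]], 2L, 2L)] <- sgn
  }
  R
}

#' Construct a raw IMU recording
#'
#' @param timestamps Numeric vector of sample times in seconds, strictly
#'   increasing.
#' @param acc N x 3 acceleration matrix in the native frame.
#' @param gyro N x 3 angular-velocity matrix in the native frame.
#' @param labels Integer per-sample class ids (taxonomy) or `NA` for
#'   unlabelled samples.
#' @param subject_id,dataset_id Opaque identifier strings.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(timestamps, acc, gyro, labels,
                          subject_id, dataset_id) {
  acc <- as.matrix(acc); gyro <- as.matrix(gyro)
  n <- length(timestamps)
  if (n < 1L) abort_contract("a recording needs at least one sample")
  if (nrow(acc) != n || nrow(gyro) != n || length(labels) != n) {
    abort_contract("timestamps, acc, gyro and labels must share length N")
  }
  if (ncol(acc) != 3L || ncol(gyro) != 3L) {
    abort_contract("acc and gyro must have 3 columns")
  }
  if (n > 1L && any(diff(timestamps) <= 0)) {
    abort_contract("timestamps must be strictly increasing")
  }
  structure(
    list(timestamps = as.numeric(timestamps),
         acc = unname(acc), gyro = unname(gyro),
         labels = as.integer(labels),
         subject_id = as.character(subject_id),
         dataset_id = as.character(dataset_id)),
    class = "raw_recording"
  )
}

#' Reorient a recording into the canonical frame and units
#'
#' Applies the signed axis permutation of a [sensor_mapping()] so that the
#' channel order becomes (AP, ML, V), and converts units to the canonical
#' m/s^2 (acceleration) and deg/s (angular velocity). Per-sample vector
#' magnitudes are preserved exactly (the mapping is a rotation). Timestamps
#' and labels are untouched.
#'
#' @param rec A [raw_recording()].
#' @param mapping A [sensor_mapping()].
#' @return A `raw_recording` in canonical axes and units.
#' @export
reorient <- function(rec, mapping) {
  stopifnot(inherits(rec, "raw_recording"), inherits(mapping, "sensor_mapping"))
  R <- mapping_matrix(mapping$axis_map)
  acc <- unname(rec$acc %*% t(R))
  gyro <- unname(rec$gyro %*% t(R))
  if (mapping$acc_unit == "g") acc <- acc * GRAVITY
  if (mapping$gyro_unit == "rad/s") gyro <- gyro * 180 / pi
  out <- rec
  out$acc <- acc
  out$gyro <- gyro
  out
}

#' Resample a canonical-frame recording onto the uniform 50 Hz grid
#'
#' Output sample k (k = 0, 1, ...) sits at `t_first + k/50`; the grid is
#' half-open, giving exactly `floor((t_last - t_first) * 50)` samples.
#' Channel values are linearly interpolated between bracketing input
#' samples; the label at each grid point is copied from the nearest-in-time
#' input sample (ties broken toward the earlier sample). No anti-alias
#' filtering is applied: the raw signal is interpolated as-is.
#'
#' @param rec A `raw_recording` already in canonical axes/units (see
#'   [reorient()]).
#' @return A `canonical_stream`: uniformly sampled 50 Hz, 6 channels
#'   (acc AP/ML/V in m/s^2, gyro AP/ML/V in deg/s).
#' @export
resample_50hz <- function(rec) {
  stopifnot(inherits(rec, "raw_recording"))
  ts <- rec$timestamps
  n_out <- floor((ts[length(ts)] - ts[1L]) * CANONICAL_RATE)
  if (n_out < 1L) {
    abort_contract("recording shorter than one 50 Hz sample")
  }
  grid <- ts[1L] + (seq_len(n_out) - 1L) / CANONICAL_RATE
  interp_cols <- function(m) {
    out <- matrix(0, n_out, 3L)
    for (j in 1:3) {
      out[, j] <- stats::approx(ts, m[, j], xout = grid, rule = 2)$y
    }
    out
  }
  labels <- rec$labels[nearest_index(ts, grid)]
  canonical_stream(acc = interp_cols(rec$acc), gyro = interp_cols(rec$gyro),
                   labels = labels, subject_id = rec$subject_id,
                   dataset_id = rec$dataset_id, t0 = ts[1L])
}

# Index of the nearest element of sorted `ts` for each query; ties -> earlier.
nearest_index <- function(ts, query) {
  lo <- findInterval(query, ts)
  lo[lo < 1L] <- 1L
  hi <- pmin(lo + 1L, length(ts))
  d_lo <- query - ts[lo]
  d_hi <- ts[hi] - query
  ifelse(d_hi < d_lo, hi, lo)
}

#' Construct a canonical 50 Hz stream
#'
#' @param acc,gyro N x 3 matrices, channel order (AP, ML, V), units m/s^2
#'   and deg/s.
#' @param labels Integer per-sample class ids.
#' @param subject_id,dataset_id Identifier strings.
#' @param t0 Time of the first sample (seconds, provenance only).
#' @return An object of class `canonical_stream`.
#' @export
canonical_stream <- function(acc, gyro, labels, subject_id, dataset_id,
                             t0 = 0) {
  acc <- as.matrix(acc); gyro <- as.matrix(gyro)
  n <- nrow(acc)
  if (nrow(gyro) != n || length(labels) != n) {
    abort_contract("acc, gyro and labels must share length N")
  }
  if (!all(is.finite(acc)) || !all(is.finite(gyro))) {
    abort_contract("canonical stream values must all be finite")
  }
  structure(
    list(rate = CANONICAL_RATE, acc = unname(acc), gyro = unname(gyro),
         labels = as.integer(labels), subject_id = as.character(subject_id),
         dataset_id = as.character(dataset_id), t0 = t0),
    class = "canonical_stream"
  )
}

#' @export
print.canonical_stream <- function(x, ...) {
  cat(sprintf(
    "<canonical_stream> %d samples @ %d Hz (%.1f s) subject=%s dataset=%s\n",
    nrow(x$acc), x$rate, nrow(x$acc) / x$rate, x$subject_id, x$dataset_id))
  invisible(x)
}

#' Harmonize one raw recording
#'
#' Convenience wrapper: [reorient()] then [resample_50hz()].
#'
#' @inheritParams reorient
#' @return A `canonical_stream`.
#' @export
harmonize <- function(rec, mapping) {
  resample_50hz(reorient(rec, mapping))
}

#' Harmonize a corpus of raw recordings
#'
#' @param recordings List of `raw_recording` objects.
#' @param manifests Named list of [sensor_mapping()]s, one per `dataset_id`
#'   occurring in `recordings`.
#' @return List of `canonical_stream` objects. Recordings shorter than one
#'   output sample are dropped with a warning.
#' @export
harmonize_corpus <- function(recordings, manifests) {
  out <- list()
  for (rec in recordings) {
    mp <- manifests[[rec$dataset_id]]
    if (is.null(mp)) {
      abort_contract("no manifest for dataset ", rec$dataset_id)
    }
    res <- tryCatch(harmonize(rec, mp), error = function(e) e)
    if (inherits(res, "error")) {
      warning("dropping recording (", conditionMessage(res), ")",
              call. = FALSE)
    } else {
      out[[length(out) + 1L]] <- res
    }
  }
  out
}

# ---- plain-text I/O -------------------------------------------------------

#' Write / read a stream CSV
#'
#' Native-frame recordings use columns
#' `time_s, acc_x, acc_y, acc_z, gyr_x, gyr_y, gyr_z, label, subject,
#' dataset`; canonical streams use `acc_ap, acc_ml, acc_v, gyr_ap, gyr_ml,
#' gyr_v` instead of the x/y/z columns.
#'
#' @param rec A `raw_recording`.
#' @param path File path.
#' @return `write_stream_csv` returns `path` invisibly; `read_stream_csv`
#'   returns a `raw_recording`.
#' @export
write_stream_csv <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  df <- data.frame(
    time_s = rec$timestamps,
    acc_x = rec$acc[, 1L], acc_y = rec$acc[, 2L], acc_z = rec$acc[, 3L],
    gyr_x = rec$gyro[, 1L], gyr_y = rec$gyro[, 2L], gyr_z = rec$gyro[, 3L],
    label = rec$labels, subject = rec$subject_id, dataset = rec$dataset_id
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stream_csv
#' @export
read_stream_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "acc_x", "acc_y", "acc_z",
            "gyr_x", "gyr_y", "gyr_z", "label", "subject", "dataset")
  if (!all(need %in% names(df))) {
    abort_contract("stream CSV is missing columns: ",
                   paste(setdiff(need, names(df)), collapse = ", "))
  }
  raw_recording(df$time_s,
                as.matrix(df[, c("acc_x", "acc_y", "acc_z")]),
                as.matrix(df[, c("gyr_x", "gyr_y", "gyr_z")]),
                df$label, df$subject[1L], df$dataset[1L])
}

#' Write / read a dataset manifest (YAML)
#'
#' One YAML document per source dataset: native rate, signed axis map,
#' units, optional accelerometer range.
#'
#' @param mapping A [sensor_mapping()].
#' @param path File path.
#' @export
write_manifest <- function(mapping, path) {
  stopifnot(inherits(mapping, "sensor_mapping"))
  obj <- list(
    native_rate = mapping$native_rate,
    axis_map = as.list(mapping$axis_map),
    acc_unit = mapping$acc_unit,
    gyro_unit = mapping$gyro_unit
  )
  if (!is.null(mapping$acc_range)) obj$acc_range <- mapping$acc_range
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  obj <- yaml::read_yaml(path)
  sensor_mapping(axis_map = obj$axis_map, acc_unit = obj$acc_unit,
                 gyro_unit = obj$gyro_unit, native_rate = obj$native_rate,
                 acc_range = obj$acc_range)
}
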