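make_rec <- function(ts, acc, gyro, labels = rep(2L, length(ts))) {
  raw_recording(ts, acc, gyro, labels, "subjA", "dsA")
}

test_that("sensor mapping validates signed permutations and handedness", {
  m <- sensor_mapping(c(AP = "+y", ML = "-x", V = "+z"), "g", "rad/s", 100)
  expect_s3_class(m, "sensor_mapping")
  expect_equal(det(falladl:::mapping_matrix(m$axis_map)), 1)
  # native axis used twice
  expect_error(sensor_mapping(c(AP = "+x", ML = "-x", V = "+z"),
                              native_rate = 50), "exactly once")
  # determinant -1 (handedness flipped)
  expect_error(sensor_mapping(c(AP = "+x", ML = "+y", V = "-z"),
                              native_rate = 50), "determinant")
  expect_error(sensor_mapping(c(AP = "+x", ML = "+y", V = "+z"),
                              acc_unit = "furlongs", native_rate = 50))
})

test_that("reorient applies the signed permutation and converts units", {
  m <- sensor_mapping(c(AP = "+y", ML = "-x", V = "+z"),
                      acc_unit = "m/s^2", gyro_unit = "deg/s",
                      native_rate = 50)
  rec <- make_rec(0, matrix(c(1, 2, 3), 1), matrix(c(4, 5, 6), 1))
  out <- reorient(rec, m)
  expect_equal(as.numeric(out$acc), c(2, -1, 3))
  expect_equal(as.numeric(out$gyro), c(5, -4, 6))

  # identity mapping with canonical units is a no-op
  mi <- sensor_mapping(c(AP = "+x", ML = "+y", V = "+z"), native_rate = 50)
  expect_equal(reorient(rec, mi)$acc, rec$acc)

  # unit conversion factors
  mg <- sensor_mapping(c(AP = "+x", ML = "+y", V = "+z"),
                       acc_unit = "g", gyro_unit = "rad/s", native_rate = 50)
  og <- reorient(rec, mg)
  expect_equal(as.numeric(og$acc), c(1, 2, 3) * 9.81)
  expect_equal(as.numeric(og$gyro), c(4, 5, 6) * 180 / pi)
})

test_that("a mapping followed by its inverse returns the original samples", {
  m <- sensor_mapping(c(AP = "+z", ML = "+x", V = "+y"), native_rate = 50)
  # inverse permutation of (AP<-z, ML<-x, V<-y): x<-ML, y<-V, z<-AP
  minv <- sensor_mapping(c(AP = "+y", ML = "+z", V = "+x"), native_rate = 50)
  set.seed(5)
  rec <- make_rec(0:9 / 50, matrix(rnorm(30), 10), matrix(rnorm(30), 10))
  back <- reorient(reorient(rec, m), minv)
  expect_equal(back$acc, rec$acc, tolerance = 1e-15)
  expect_equal(back$gyro, rec$gyro, tolerance = 1e-15)
})

test_that("reorientation preserves per-sample vector magnitudes", {
  set.seed(11)
  rec <- make_rec(0:49 / 100, matrix(rnorm(150), 50), matrix(rnorm(150), 50))
  maps <- list(
    sensor_mapping(c(AP = "+y", ML = "-x", V = "+z"), native_rate = 100),
    sensor_mapping(c(AP = "-z", ML = "+y", V = "+x"), native_rate = 100),
    sensor_mapping(c(AP = "-x", ML = "-y", V = "+z"), native_rate = 100)
  )
  for (m in maps) {
    out <- reorient(rec, m)
    expect_equal(rowSums(out$acc^2), rowSums(rec$acc^2), tolerance = 1e-12)
    expect_equal(rowSums(out$gyro^2), rowSums(rec$gyro^2), tolerance = 1e-12)
  }
})

test_that("resampling a constant 200 Hz stream yields the exact grid count", {
  n <- 2001L  # 10 s at 200 Hz
  rec <- make_rec((0:(n - 1)) / 200,
                  matrix(rep(c(1, 2, 3), each = n), n),
                  matrix(0, n, 3))
  cs <- resample_50hz(rec)
  expect_s3_class(cs, "canonical_stream")
  expect_equal(nrow(cs$acc), 500L)  # floor(10 * 50)
  expect_true(all(cs$acc[, 1] == 1))
  expect_true(all(abs(cs$acc[, 3] - 3) < 1e-12))
})

test_that("linear interpolation reproduces affine signals exactly", {
  ts <- sort(c(0, runif(200, 0, 4), 4))
  rec <- make_rec(ts, cbind(2 * ts + 1, -ts, 0 * ts),
                  cbind(ts, ts, ts), labels = rep(1L, length(ts)))
  cs <- resample_50hz(rec)
  grid <- (seq_len(nrow(cs$acc)) - 1) / 50
  expect_equal(cs$acc[, 1], 2 * grid + 1, tolerance = 1e-10)
  expect_equal(cs$acc[, 2], -grid, tolerance = 1e-10)
})

test_that("20 Hz input upsamples to a uniform 50 Hz grid", {
  n <- 101L  # 5 s at 20 Hz
  rec <- make_rec((0:(n - 1)) / 20, matrix(rnorm(3 * n), n),
                  matrix(rnorm(3 * n), n))
  cs <- resample_50hz(rec)
  expect_equal(nrow(cs$acc), 250L)
  expect_equal(cs$rate, 50)
  # implied spacing is exactly 1/50 s by construction of the grid
  expect_equal(stats::median(diff((seq_len(250) - 1) / 50)), 0.02)
})

test_that("resampling an on-grid 50 Hz stream is idempotent", {
  set.seed(2)
  n <- 200L
  rec <- make_rec((0:(n - 1)) / 50, matrix(rnorm(3 * n), n),
                  matrix(rnorm(3 * n), n),
                  labels = sample(1:3, n, replace = TRUE))
  cs <- resample_50hz(rec)
  expect_equal(nrow(cs$acc), n - 1L)  # half-open grid drops the last point
  expect_equal(cs$acc, rec$acc[seq_len(n - 1L), ], tolerance = 1e-9)
  expect_equal(cs$labels, rec$labels[seq_len(n - 1L)])
})

test_that("output length follows floor((t_last - t_first) * 50) in general", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(10:400, 1)
    rate <- sample(c(20, 33.33, 50, 100, 238), 1)
    ts <- (0:(n - 1)) / rate + runif(1, 0, 5)
    rec <- make_rec(ts, matrix(rnorm(3 * n), n), matrix(rnorm(3 * n), n))
    expected <- floor((ts[n] - ts[1]) * 50)
    if (expected < 1) {
      expect_error(resample_50hz(rec), "shorter")
    } else {
      expect_equal(nrow(resample_50hz(rec)$acc), expected)
    }
  }
})

test_that("labels transfer from the nearest input sample, earlier on ties", {
  ts <- c(0, 0.03, 0.05)
  rec <- make_rec(ts, matrix(0, 3, 3), matrix(0, 3, 3),
                  labels = c(1L, 2L, 3L))
  cs <- resample_50hz(rec)
  # grid points 0.00, 0.02: nearest are sample 1 (0s) and: 0.02 is 0.02 from
  # t=0 and 0.01 from t=0.03 -> label 2
  expect_equal(cs$labels, c(1L, 2L))
  # exact tie: grid 0.015 between 0 and 0.03 -> earlier sample wins
  rec2 <- make_rec(c(0, 0.01, 0.04), matrix(0, 3, 3), matrix(0, 3, 3),
                   labels = c(9L, 9L, 4L))
  # grid 0.00 (label 9), 0.02 (0.01 from t=0.01, 0.02 from t=0.04 -> 9)
  expect_equal(resample_50hz(rec2)$labels, c(9L, 9L))
})

test_that("raw recordings reject malformed inputs", {
  expect_error(raw_recording(c(0, 0), matrix(0, 2, 3), matrix(0, 2, 3),
                             c(1, 1), "s", "d"), "increasing")
  expect_error(raw_recording(c(0, 1), matrix(0, 3, 3), matrix(0, 2, 3),
                             c(1, 1), "s", "d"), "length")
})

test_that("stream CSV and manifest round-trip through disk", {
  set.seed(4)
  rec <- make_rec(0:19 / 50, matrix(rnorm(60), 20), matrix(rnorm(60), 20),
                  labels = rep(3L, 20))
  f <- tempfile(fileext = ".csv")
  write_stream_csv(rec, f)
  back <- read_stream_csv(f)
  expect_equal(back$acc, rec$acc, tolerance = 1e-12)
  expect_equal(back$labels, rec$labels)
  expect_equal(back$dataset_id, "dsA")

  m <- sensor_mapping(c(AP = "+y", ML = "-x", V = "+z"), "g", "rad/s",
                      238, acc_range = 8)
  fy <- tempfile(fileext = ".yaml")
  write_manifest(m, fy)
  m2 <- read_manifest(fy)
  expect_equal(m2$axis_map, m$axis_map)
  expect_equal(m2$native_rate, 238)
  expect_equal(m2$acc_range, 8)
  unlink(c(f, fy))
})

test_that("harmonize recovers canonical signals from a mapped recording", {
  set.seed(6)
  n <- 400L
  acc_can <- cbind(rnorm(n, 0, 1), rnorm(n, 0, 1), rnorm(n, 9.81, 1))
  gyr_can <- matrix(rnorm(3 * n, 0, 20), n)
  m <- sensor_mapping(c(AP = "+y", ML = "-x", V = "+z"), "g", "rad/s", 100)
  R <- falladl:::mapping_matrix(m$axis_map)
  rec <- raw_recording((0:(n - 1)) / 100, (acc_can %*% R) / 9.81,
                       (gyr_can %*% R) * pi / 180, rep(1L, n), "s", "d")
  cs <- harmonize(rec, m)
  # 100 Hz on-grid input: canonical samples are every 2nd input sample
  keep <- seq(1L, by = 2L, length.out = nrow(cs$acc))
  expect_equal(cs$acc, acc_can[keep, ], tolerance = 1e-9)
  expect_equal(cs$gyro, gyr_can[keep, ], tolerance = 1e-9)
})
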