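# Synthetic waist-IMU corpus generator.
#
# Emulates the statistical structure the analysis pipeline assumes: 20
# activity/fall classes with strong imbalance (cyclical activities dominant,
# syncope falls rarest), several "virtual datasets" with heterogeneous
# native sampling rates, signed axis conventions, units and sensor ranges,
# and multiple subjects per dataset. Signals are kinematic sketches
# (gravity orientation + gait harmonics + impact transients + noise), not
# biomechanical simulations; the "easy" preset is calibrated for class
# separability, the "realistic" preset adds inter-class overlap.

# Gravity direction unit vectors (canonical AP, ML, V frame) per posture.
posture_dirs <- function() {
  nrm <- function(v) v / sqrt(sum(v^2))
  list(
    standing = c(0, 0, 1),
    sitting = nrm(c(0.5, 0, 0.87)),     # ~30 deg recline at the waist
    lying = nrm(c(0.99, 0, 0.14)),
    prone = nrm(c(-0.99, 0, 0.14)),
    side = nrm(c(0.1, 0.99, 0.1)),
    bent = nrm(c(0.77, 0, 0.64)),       # ~50 deg forward bend
    pick = nrm(c(0.98, 0, 0.2))         # ~78 deg deep bend to the ground
  )
}

# Per-class signal parameters. Cyclic classes: step-frequency range (Hz) and
# per-axis harmonic amplitudes (m/s^2 acc, deg/s gyro); transitions: start
# and end posture; falls: impact axis, end posture and peak range (g).
class_params <- function(difficulty = "easy") {
  overlap <- difficulty == "realistic"
  list(
    walking = list(kind = "cyclic", freq = c(1.5, 2.5),
                   amp = c(1.2, 0.8, 2.0), gamp = c(15, 30, 20)),
    standing = list(kind = "posture", dir = "standing"),
    sitting = list(kind = "posture", dir = "sitting"),
    lying = list(kind = "posture", dir = "lying"),
    upstairs = list(kind = "cyclic", freq = c(1.1, 1.6),
                    amp = c(1.8, 0.6, 2.6), gamp = c(25, 35, 15),
                    tilt = 0.18),
    downstairs = list(kind = "cyclic", freq = c(1.7, 2.2),
                      amp = c(1.5, 0.7, 3.2), gamp = c(20, 40, 15),
                      tilt = -0.12),
    jumping = list(kind = "jumping", freq = c(0.8, 1.2), peak_g = c(2.0, 2.6)),
    jogging = list(kind = "cyclic", freq = c(2.4, 3.0),
                   amp = c(2.5, 1.2, if (overlap) 4.5 else 6.0),
                   gamp = c(35, 60, 30)),
    lying_to_stand = list(kind = "transition", from = "lying",
                          to = "standing", vbump = 2.5),
    stand_to_sit = list(kind = "transition", from = "standing",
                        to = "sitting", vbump = -2.0),
    sit_to_stand = list(kind = "transition", from = "sitting",
                        to = "standing", vbump = 2.0),
    stand_to_pick_to_stand = list(kind = "there_back", from = "standing",
                                  to = "pick", vbump = -3.0),
    stand_to_lying = list(kind = "transition", from = "standing",
                          to = "lying", vbump = -1.5),
    change_position_lying = list(kind = "transition", from = "lying",
                                 to = "side", vbump = 0),
    turning = list(kind = "turning", peak_dps = c(80, 140)),
    bending = list(kind = "there_back", from = "standing",
                   to = if (overlap) "sitting" else "bent", vbump = 0),
    fall_forwards = list(kind = "fall", axis = 1L, sign = -1,
                         end = "prone", peak_g = c(3.5, 8)),
    fall_backwards = list(kind = "fall", axis = 1L, sign = 1,
                          end = "lying", peak_g = c(3.5, 8)),
    fall_lateral = list(kind = "fall", axis = 2L, sign = 1,
                        end = "side", peak_g = c(3.5, 8)),
    fall_syncope = list(kind = "fall", axis = 3L, sign = -1,
                        end = "lying", peak_g = c(3, 4.5), slow = TRUE)
  )
}

# Typical segment duration ranges (s) used when scripting sessions.
# Longer cyclic/static segments keep the share of windows that straddle an
# activity boundary (and are thus intrinsically mixed) low.
class_durations <- function() {
  tax <- class_taxonomy()
  dur <- matrix(0, 20L, 2L)
  dur[tax$category == "periodic_static", ] <-
    matrix(rep(c(8, 16), 8L), ncol = 2L, byrow = TRUE)
  dur[tax$category == "transition", ] <-
    matrix(rep(c(1.5, 2.5), 8L), ncol = 2L, byrow = TRUE)
  dur[tax$category == "fall", ] <-
    matrix(rep(c(2.2, 3), 4L), ncol = 2L, byrow = TRUE)
  rownames(dur) <- tax$name
  dur
}

# Central-difference time derivative (one-sided at the ends).
num_deriv <- function(s, dt) {
  n <- length(s)
  d <- numeric(n)
  if (n >= 3L) d[2L:(n - 1L)] <- (s[3L:n] - s[1L:(n - 2L)]) / (2 * dt)
  d[1L] <- (s[2L] - s[1L]) / dt
  d[n] <- (s[n] - s[n - 1L]) / dt
  d
}

# Default class mix: walking-dominant, lying second, fall-by-syncope rarest.
default_class_mix <- function() {
  mix <- c(
    walking = 0.2973, standing = 0.09, sitting = 0.07, lying = 0.1852,
    upstairs = 0.045, downstairs = 0.045, jumping = 0.02, jogging = 0.035,
    lying_to_stand = 0.02, stand_to_sit = 0.02, sit_to_stand = 0.02,
    stand_to_pick_to_stand = 0.02, stand_to_lying = 0.02,
    change_position_lying = 0.02, turning = 0.02, bending = 0.02,
    fall_forwards = 0.012, fall_backwards = 0.009, fall_lateral = 0.008,
    fall_syncope = 0.0027
  )
  mix / sum(mix)
}

# Default virtual datasets, spanning the sampling-rate / axis-convention /
# unit heterogeneity of public waist-IMU corpora.
default_virtual_datasets <- function() {
  list(
    vds_a = sensor_mapping(c(AP = "+x", ML = "+y", V = "+z"),
                           acc_unit = "m/s^2", gyro_unit = "deg/s",
                           native_rate = 200),
    vds_b = sensor_mapping(c(AP = "+y", ML = "-x", V = "+z"),
                           acc_unit = "g", gyro_unit = "rad/s",
                           native_rate = 238),
    vds_c = sensor_mapping(c(AP = "+x", ML = "+z", V = "-y"),
                           acc_unit = "g", gyro_unit = "deg/s",
                           native_rate = 20, acc_range = 8)
  )
}

#' Synthetic corpus generator configuration
#'
#' @param n_subjects Subjects per virtual dataset.
#' @param n_sessions Recording sessions per subject.
#' @param session_s Nominal session length in seconds (sessions end at the
#'   first activity boundary past this mark).
#' @param datasets Named list of [sensor_mapping()]s defining the virtual
#'   datasets (native rate, axis convention, units, optional saturation
#'   range). Defaults span 20-238 Hz with mixed conventions.
#' @param class_mix 20 non-negative weights (taxonomy order or named),
#'   normalised to sum to 1. Default: walking ~30%, lying ~18.5%, fall by
#'   syncope ~0.3%.
#' @param noise_sd Accelerometer noise SD in m/s^2 (gyroscope noise is
#'   10x this value in deg/s). Default 0.15 (easy) / 0.8 (realistic).
#' @param artifact_rate Expected number of brief motion artifacts per
#'   second inside sustained activities (default 0.12).
#' @param difficulty `"easy"` (classes well separated, used by the
#'   acceptance suite) or `"realistic"` (overlapping transitions, more
#'   noise, per-subject orientation jitter).
#' @return A `generator_config`.
#' @export
generator_config <- function(n_subjects = 4L, n_sessions = 2L,
                             session_s = 45,
                             datasets = default_virtual_datasets(),
                             class_mix = default_class_mix(),
                             noise_sd = NULL, artifact_rate = 0.12,
                             difficulty = c("easy", "realistic")) {
  difficulty <- match.arg(difficulty)
  if (is.null(noise_sd)) noise_sd <- if (difficulty == "easy") 0.15 else 0.8
  tax <- class_taxonomy()
  if (!is.null(names(class_mix))) {
    mix <- numeric(20L)
    names(mix) <- tax$name
    mix[names(class_mix)] <- class_mix
  } else {
    stopifnot(length(class_mix) == 20L)
    mix <- stats::setNames(as.numeric(class_mix), tax$name)
  }
  if (any(mix < 0) || sum(mix) <= 0) {
    abort_contract("class_mix must be non-negative with positive sum")
  }
  mix <- mix / sum(mix)
  stopifnot(length(datasets) >= 1L,
            all(vapply(datasets, inherits, TRUE, "sensor_mapping")))
  if (is.null(names(datasets))) {
    names(datasets) <- paste0("vds_", seq_along(datasets))
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_sessions = as.integer(n_sessions),
         session_s = session_s, datasets = datasets, class_mix = mix,
         noise_sd = noise_sd, artifact_rate = artifact_rate,
         difficulty = difficulty,
         params = class_params(difficulty), durations = class_durations()),
    class = "generator_config"
  )
}

# Rotate unit vector g1 toward g2 by fraction s in [0,1] of their angle;
# returns the interpolated unit vector (spherical interpolation).
slerp <- function(g1, g2, s) {
  d <- min(1, max(-1, sum(g1 * g2)))
  th <- acos(d)
  if (th < 1e-9) return(g1)
  (sin((1 - s) * th) * g1 + sin(s * th) * g2) / sin(th)
}

rotation_axis <- function(g1, g2) {
  ax <- c(g1[2L] * g2[3L] - g1[3L] * g2[2L],
          g1[3L] * g2[1L] - g1[1L] * g2[3L],
          g1[1L] * g2[2L] - g1[2L] * g2[1L])
  n <- sqrt(sum(ax^2))
  if (n < 1e-9) c(0, 1, 0) else ax / n
}

# Smoothstep ramp and its time derivative on u in [0,1].
smoothstep <- function(u) 3 * u^2 - 2 * u^3
smoothstep_d <- function(u) 6 * u - 6 * u^2

#' Generate one labelled activity segment
#'
#' Produces a canonical-frame (AP, ML, V; m/s^2, deg/s) segment of the
#' requested class at an arbitrary native rate: static postures are a
#' gravity vector plus noise, cyclic activities add gait harmonics at a
#' class-specific step frequency, transitions rotate the gravity vector
#' smoothly between postures with matching gyroscope activity, and falls
#' are a quiescent lead-in, a fast rotation with an impact spike of 3-8 g,
#' and a post-fall lying posture.
#'
#' @param class_id Taxonomy class id (1..20).
#' @param duration_s Segment duration in seconds.
#' @param cfg A [generator_config()].
#' @param rate Sampling rate in Hz.
#' @param seed Optional seed for a reproducible stand-alone segment.
#' @return List with `acc` (N x 3), `gyro` (N x 3), `labels` (N class ids).
#' @export
synth_activity <- function(class_id, duration_s, cfg = generator_config(),
                           rate = 50, seed = NULL) {
  if (!is.null(seed)) {
    return(with_seed(seed, synth_activity(class_id, duration_s, cfg, rate)))
  }
  tax <- class_taxonomy()
  if (!class_id %in% tax$class_id) abort_contract("unknown class id")
  nm <- tax$name[class_id]
  par <- cfg$params[[nm]]
  dirs <- posture_dirs()
  N <- max(2L, round(duration_s * rate))
  t <- (seq_len(N) - 1L) / rate
  acc <- matrix(0, N, 3L)
  gyr <- matrix(0, N, 3L)
  G <- GRAVITY
  add_grav <- function(dirmat) G * dirmat

  if (par$kind == "posture") {
    acc <- matrix(rep(G * dirs[[par$dir]], each = N), N, 3L)
  } else if (par$kind == "cyclic") {
    f <- stats::runif(1L, par$freq[1L], par$freq[2L])
    ph <- stats::runif(3L, 0, 2 * pi)
    base <- dirs$standing
    if (!is.null(par$tilt)) base <- slerp(dirs$standing, dirs$bent, par$tilt)
    acc <- matrix(rep(G * base, each = N), N, 3L)
    acc[, 1L] <- acc[, 1L] + par$amp[1L] * sin(2 * pi * f * t + ph[1L])
    acc[, 2L] <- acc[, 2L] + par$amp[2L] * sin(pi * f * t + ph[2L])
    acc[, 3L] <- acc[, 3L] + par$amp[3L] * sin(2 * pi * f * t + ph[3L]) +
      0.4 * par$amp[3L] * sin(4 * pi * f * t + ph[1L])
    gyr[, 1L] <- par$gamp[1L] * sin(2 * pi * f * t + ph[2L])
    gyr[, 2L] <- par$gamp[2L] * sin(2 * pi * f * t + ph[3L])
    gyr[, 3L] <- par$gamp[3L] * sin(pi * f * t + ph[1L])
  } else if (par$kind == "jumping") {
    f <- stats::runif(1L, par$freq[1L], par$freq[2L])
    peak <- stats::runif(1L, par$peak_g[1L], par$peak_g[2L]) * G
    phase <- (f * t) %% 1
    burst <- pmax(0, sin(2 * pi * phase))^6
    flight <- pmax(0, sin(2 * pi * phase + pi))^2
    acc[, 3L] <- G + (peak - G) * burst - 0.8 * G * flight
    acc[, 1L] <- 0.4 * (peak - G) * burst * 0.3
    gyr[, 2L] <- 40 * sin(2 * pi * f * t)
  } else if (par$kind == "turning") {
    peak <- stats::runif(1L, par$peak_dps[1L], par$peak_dps[2L]) *
      sample(c(-1, 1), 1L)
    acc <- matrix(rep(G * dirs$standing, each = N), N, 3L)
    gyr[, 3L] <- peak * sin(pi * pmin(1, t / duration_s))^2
  } else if (par$kind %in% c("transition", "there_back")) {
    g1 <- dirs[[par$from]]; g2 <- dirs[[par$to]]
    u <- pmin(1, t / duration_s)
    s <- if (par$kind == "transition") {
      smoothstep(u)
    } else {
      # out, hold at the target, and back
      ifelse(u < 0.4, smoothstep(u / 0.4),
             ifelse(u < 0.6, 1, smoothstep((1 - u) / 0.4)))
    }
    dirmat <- t(vapply(s, function(ss) slerp(g1, g2, ss), numeric(3L)))
    acc <- add_grav(dirmat)
    th <- acos(min(1, max(-1, sum(g1 * g2))))
    ax <- rotation_axis(g1, g2)
    gyr <- outer(th * num_deriv(s, 1 / rate) * 180 / pi, ax)
    if (!is.null(par$vbump) && par$vbump != 0) {
      # vertical centre-of-mass acceleration signature of the transfer
      acc[, 3L] <- acc[, 3L] + par$vbump * sin(pi * pmin(1, u / 0.9))^2
    }
  } else if (par$kind == "fall") {
    lead <- stats::runif(1L, 0.6, 0.9)
    t_rot <- if (isTRUE(par$slow)) 1.2 else stats::runif(1L, 0.3, 0.45)
    g1 <- dirs$standing; g2 <- dirs[[par$end]]
    u <- pmin(1, pmax(0, (t - lead) / t_rot))
    s <- smoothstep(u)
    dirmat <- t(vapply(s, function(ss) slerp(g1, g2, ss), numeric(3L)))
    # partial free-fall during the descent: measured specific force drops
    # well below 1 g, unlike any controlled postural transition
    gfac <- 1 - 0.65 * sin(pi * u)^2
    acc <- add_grav(dirmat) * gfac
    th <- acos(min(1, max(-1, sum(g1 * g2))))
    ax <- rotation_axis(g1, g2)
    gyr <- outer(th * num_deriv(s, 1 / rate) * 180 / pi, ax)
    # impact spike at the end of the rotation, then a decaying settling
    # oscillation (body coming to rest) before the post-fall stillness
    peak <- stats::runif(1L, par$peak_g[1L], par$peak_g[2L]) * G
    t_imp <- lead + t_rot
    pulse <- peak * exp(-((t - t_imp) / 0.03)^2)
    acc[, par$axis] <- acc[, par$axis] + par$sign * pulse
    settle <- exp(-pmax(0, t - t_imp) / 0.35) * (t > t_imp)
    acc[, 3L] <- acc[, 3L] +
      2.5 * settle * sin(2 * pi * 6 * (t - t_imp))
    gyr[, (par$axis %% 3L) + 1L] <- gyr[, (par$axis %% 3L) + 1L] +
      200 * exp(-((t - t_imp) / 0.05)^2) +
      60 * settle * sin(2 * pi * 5 * (t - t_imp))
  }
  # brief motion artifacts (postural adjustments, hesitations) inside
  # sustained activities: their fixed per-second rate means long analysis
  # windows are far more likely to contain one than short windows
  if (par$kind %in% c("posture", "cyclic", "turning", "jumping")) {
    n_ev <- stats::rpois(1L, cfg$artifact_rate * duration_s)
    for (ev in seq_len(n_ev)) {
      t_ev <- stats::runif(1L, 0, duration_s)
      width <- stats::runif(1L, 0.15, 0.3)
      env <- exp(-((t - t_ev) / width)^2)
      dir3 <- stats::rnorm(3L)
      dir3 <- dir3 / sqrt(sum(dir3^2))
      acc <- acc + outer(env, dir3 * stats::runif(1L, 2.5, 5))
      gax <- stats::rnorm(3L)
      gax <- gax / sqrt(sum(gax^2))
      gyr <- gyr + outer(env * sin(2 * pi * (t - t_ev) / (2 * width)),
                         gax * stats::runif(1L, 50, 110))
    }
  }
  acc <- acc + matrix(stats::rnorm(3L * N, 0, cfg$noise_sd), N, 3L)
  gyr <- gyr + matrix(stats::rnorm(3L * N, 0, 10 * cfg$noise_sd), N, 3L)
  list(acc = acc, gyro = gyr, labels = rep(class_id, N))
}

#' Generate a full synthetic corpus
#'
#' Builds per-dataset, per-subject session recordings as random activity
#' scripts: activities are scheduled by a class-mix quota ledger shared
#' across the whole corpus (so the emitted per-sample class shares converge
#' to `class_mix`), rendered in the canonical frame at each virtual
#' dataset's native rate, then pushed through the inverse of the dataset's
#' axis mapping, unit conversion and optional saturation clipping so that
#' [harmonize()] has real work to do.
#'
#' @param cfg A [generator_config()].
#' @param seed Integer seed; the corpus is a deterministic function of
#'   (cfg, seed).
#' @return List with `recordings` (list of `raw_recording`s), `manifests`
#'   (named list of [sensor_mapping()]s) and `script` (data frame of the
#'   generating timeline: dataset, subject, session, class, start/end
#'   sample at the native rate).
#' @export
synth_corpus <- function(cfg = generator_config(), seed = 1L) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(seed, synth_corpus_impl(cfg))
}

synth_corpus_impl <- function(cfg) {
  tax <- class_taxonomy()
  mix <- cfg$class_mix
  sessions <- expand.grid(
    dataset = names(cfg$datasets),
    subject = seq_len(cfg$n_subjects),
    session = seq_len(cfg$n_sessions),
    stringsAsFactors = FALSE
  )
  total_s <- nrow(sessions) * cfg$session_s
  deficit <- mix * total_s  # seconds still owed to each class
  active <- tax$name[mix > 0]
  recordings <- list()
  script <- list()
  for (i in seq_len(nrow(sessions))) {
    ds <- sessions$dataset[i]
    mp <- cfg$datasets[[ds]]
    rate <- mp$native_rate
    subj <- sprintf("%s_s%02d", ds, sessions$subject[i])
    acc <- NULL; gyr <- NULL; labels <- integer(0)
    elapsed <- 0
    while (elapsed < cfg$session_s) {
      cand <- active[order(-deficit[active])]
      nm <- cand[1L]
      cid <- tax$class_id[tax$name == nm]
      dur <- stats::runif(1L, cfg$durations[nm, 1L], cfg$durations[nm, 2L])
      seg <- synth_activity(cid, dur, cfg, rate)
      n_start <- length(labels) + 1L
      acc <- rbind(acc, seg$acc); gyr <- rbind(gyr, seg$gyro)
      labels <- c(labels, seg$labels)
      script[[length(script) + 1L]] <- data.frame(
        dataset = ds, subject = subj, session = sessions$session[i],
        class = nm, start = n_start, end = length(labels),
        stringsAsFactors = FALSE)
      deficit[nm] <- deficit[nm] - length(seg$labels) / rate
      elapsed <- elapsed + length(seg$labels) / rate
    }
    if (cfg$difficulty == "realistic") {
      # per-subject sensor gain mismatch
      gain <- stats::runif(1L, 0.92, 1.08)
      acc <- acc * gain
    }
    # canonical -> native frame (inverse of the reorientation rotation)
    R <- mapping_matrix(mp$axis_map)
    acc_n <- acc %*% R   # = t(t(R) %*% t(acc)); R orthogonal
    gyr_n <- gyr %*% R
    if (mp$acc_unit == "g") acc_n <- acc_n / GRAVITY
    if (mp$gyro_unit == "rad/s") gyr_n <- gyr_n * pi / 180
    if (!is.null(mp$acc_range)) {
      acc_n[acc_n > mp$acc_range] <- mp$acc_range
      acc_n[acc_n < -mp$acc_range] <- -mp$acc_range
    }
    ts <- (seq_along(labels) - 1L) / rate
    recordings[[length(recordings) + 1L]] <- raw_recording(
      ts, acc_n, gyr_n, labels, subject_id = subj, dataset_id = ds)
  }
  list(recordings = recordings, manifests = cfg$datasets,
       script = do.call(rbind, script))
}

#' Write a synthetic corpus to disk (stream CSVs + YAML manifests)
#'
#' @param corpus A [synth_corpus()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ds in names(corpus$manifests)) {
    write_manifest(corpus$manifests[[ds]],
                   file.path(dir, paste0(ds, ".manifest.yaml")))
  }
  for (i in seq_along(corpus$recordings)) {
    rec <- corpus$recordings[[i]]
    write_stream_csv(rec, file.path(dir, sprintf("%s_rec%03d.csv",
                                                 rec$subject_id, i)))
  }
  invisible(dir)
}
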