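# Independent brute-force oracles. These deliberately re-derive every
# quantity with plain loops and naive algorithms (including a direct DFT)
# so that agreement with the package implementations is meaningful.

G0 <- 9.81

o_mean <- function(x) sum(x) / length(x)
o_var <- function(x) sum((x - o_mean(x))^2) / (length(x) - 1)
o_sd <- function(x) sqrt(o_var(x))

o_skew <- function(x) {
  L <- length(x); mx <- o_mean(x)
  m2 <- sum((x - mx)^2) / L
  if (m2 == 0) return(0)
  (sum((x - mx)^3) / L) / m2^1.5
}

o_kurt <- function(x) {
  L <- length(x); mx <- o_mean(x)
  m2 <- sum((x - mx)^2) / L
  if (m2 == 0) return(0)
  (sum((x - mx)^4) / L) / m2^2
}

o_cor <- function(x, y) {
  if (o_var(x) == 0 || o_var(y) == 0) return(0)
  mx <- o_mean(x); my <- o_mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# type-7 quantile, coded from the interpolation definition
o_quantile7 <- function(x, p) {
  xs <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  if (lo >= length(x)) return(xs[length(x)])
  xs[lo] + (h - lo) * (xs[lo + 1] - xs[lo])
}

o_median <- function(x) o_quantile7(x, 0.5)

o_crossings <- function(x, level) {
  n <- 0L
  for (i in seq_len(length(x) - 1L)) {
    if ((x[i] - level) * (x[i + 1] - level) < 0) n <- n + 1L
  }
  n
}

o_cumtrapz <- function(x, dt) {
  out <- numeric(length(x))
  for (i in seq_along(x)[-1L]) {
    out[i] <- out[i - 1L] + (x[i] + x[i - 1L]) / 2 * dt
  }
  out
}

# naive one-sided DFT power, DC excluded; bins k = 1..floor(L/2)
o_dft_power <- function(x) {
  L <- length(x)
  xc <- x - o_mean(x)
  ks <- seq_len(L %/% 2L)
  p <- numeric(length(ks))
  for (ki in seq_along(ks)) {
    re <- 0; im <- 0
    for (t in seq_len(L)) {
      ang <- -2 * pi * ks[ki] * (t - 1) / L
      re <- re + xc[t] * cos(ang)
      im <- im + xc[t] * sin(ang)
    }
    p[ki] <- re^2 + im^2
  }
  p
}

# Full 199-feature oracle, appended in registry row-group order.
oracle_features <- function(w, rate = 50) {
  L <- nrow(w)
  dt <- 1 / rate
  dur <- L * dt
  acc <- w[, 1:3]; gyr <- w[, 4:6]
  asvm <- numeric(L); gsvm <- numeric(L)
  for (i in seq_len(L)) {
    asvm[i] <- sqrt(acc[i, 1]^2 + acc[i, 2]^2 + acc[i, 3]^2)
    gsvm[i] <- sqrt(gyr[i, 1]^2 + gyr[i, 2]^2 + gyr[i, 3]^2)
  }
  sig <- cbind(acc, gyr, asvm, gsvm)
  out <- c()
  # terminal values
  for (j in 1:6) out <- c(out, w[L, j])
  out <- c(out, asvm[L], gsvm[L])
  # moments
  for (j in 1:8) out <- c(out, o_skew(sig[, j]))
  for (j in 1:8) out <- c(out, o_kurt(sig[, j]))
  # order stats & dispersion
  for (j in 1:8) out <- c(out, min(sig[, j]))
  for (j in 1:8) out <- c(out, max(sig[, j]))
  for (j in 1:8) out <- c(out, o_mean(sig[, j]))
  for (j in 1:8) out <- c(out, o_var(sig[, j]))
  for (j in 1:8) out <- c(out, o_sd(sig[, j]))
  # correlations V-ML, V-AP, ML-AP per sensor
  out <- c(out, o_cor(acc[, 3], acc[, 2]), o_cor(acc[, 3], acc[, 1]),
           o_cor(acc[, 2], acc[, 1]),
           o_cor(gyr[, 3], gyr[, 2]), o_cor(gyr[, 3], gyr[, 1]),
           o_cor(gyr[, 2], gyr[, 1]))
  # kinematic scalars
  tv <- (seq_len(L) - 1) * dt
  mt <- o_mean(tv); my <- o_mean(asvm)
  slope <- sum((tv - mt) * (asvm - my)) / sum((tv - mt)^2)
  total_ang <- sum(gsvm) * dt
  raa <- 0
  for (i in 2:L) {
    v <- sqrt(sum(((gyr[i, ] - gyr[i - 1, ]) / dt)^2))
    if (v > raa) raa <- v
  }
  am <- c(o_mean(acc[, 1]), o_mean(acc[, 2]), o_mean(acc[, 3]))
  asma <- o_mean(abs(acc[, 1] - am[1]) + abs(acc[, 2] - am[2]) +
                   abs(acc[, 3] - am[3]))
  sma <- o_mean(abs(acc[, 1]) + abs(acc[, 2]) + abs(acc[, 3]))
  avert <- o_mean(abs(acc[, 3] - G0))
  disp <- matrix(0, L, 3)
  for (j in 1:3) {
    disp[, j] <- o_cumtrapz(o_cumtrapz(acc[, j] - am[j], dt), dt)
  }
  drange <- apply(disp, 2, function(d) max(d) - min(d))
  out <- c(out, slope, total_ang, raa, asma, sma, avert,
           sqrt(drange[1]^2 + drange[2]^2))
  # amplitude
  for (j in 1:8) out <- c(out, max(sig[, j]) - min(sig[, j]))
  for (j in 1:8) out <- c(out, sqrt(o_mean(sig[, j]^2)))
  for (j in 1:8) {
    ref <- if (j %in% c(1, 2, 3, 7)) max(asvm) else max(gsvm)
    out <- c(out, if (ref == 0) 0 else max(abs(sig[, j])) / ref)
  }
  # resultants
  n1 <- sqrt(sum(acc[1, ]^2)); nL <- sqrt(sum(acc[L, ]^2))
  rac <- if (n1 == 0 || nL == 0) 0 else {
    acos(min(1, max(-1, sum(acc[1, ] * acc[L, ]) / (n1 * nL))))
  }
  out <- c(out, rac)
  for (j in 1:8) out <- c(out, o_crossings(sig[, j], o_mean(sig[, j])) / dur)
  out <- c(out, sqrt(sum(am^2)),
           sqrt(o_sd(acc[, 1])^2 + o_sd(acc[, 2])^2 + o_sd(acc[, 3])^2),
           sqrt(o_mean(gyr[, 1])^2 + o_mean(gyr[, 2])^2 +
                  o_mean(gyr[, 3])^2),
           sqrt(o_sd(gyr[, 1])^2 + o_sd(gyr[, 2])^2 + o_sd(gyr[, 3])^2))
  # delta changes
  da <- acc[L, ] - acc[1, ]; dg <- gyr[L, ] - gyr[1, ]
  out <- c(out, da, sqrt(sum(da^2)), dg, sqrt(sum(dg^2)))
  # gravity / displacement / sway
  out <- c(out, am, disp[L, ], drange)
  sway <- 0
  for (i in 2:L) {
    sway <- sway + sqrt((disp[i, 1] - disp[i - 1, 1])^2 +
                          (disp[i, 2] - disp[i - 1, 2])^2)
  }
  out <- c(out, sway, sway / dur)
  # waveform
  for (j in 1:8) {
    d <- diff(sig[, j]); n <- 0L
    for (i in seq_len(length(d) - 1L)) if (d[i] * d[i + 1] < 0) n <- n + 1L
    out <- c(out, n)
  }
  for (j in 1:8) out <- c(out, o_crossings(sig[, j], o_mean(sig[, j])))
  for (j in 1:8) out <- c(out, sum(abs(diff(sig[, j]))))
  # spectral (naive DFT)
  pw <- lapply(1:8, function(j) o_dft_power(sig[, j]))
  ks <- seq_len(L %/% 2L)
  fr <- ks * rate / L
  even <- L %% 2L == 0L
  for (j in 1:8) {
    p <- pw[[j]]
    out <- c(out, if (even) (2 * sum(p[-length(p)]) + p[length(p)]) / L
             else 2 * sum(p) / L)
  }
  for (j in 1:8) {
    p <- pw[[j]]
    out <- c(out, if (sum(p) == 0) 0 else sum(fr * p) / sum(p))
  }
  pk <- sapply(pw, which.max)
  for (j in 1:8) out <- c(out, if (sum(pw[[j]]) == 0) 0 else fr[pk[j]])
  for (j in 1:8) out <- c(out, 2 * sqrt(pw[[j]][pk[j]]) / L)
  # SumVM aggregates
  horiz <- sqrt(acc[, 1]^2 + acc[, 2]^2)
  out <- c(out, o_median(asvm), o_median(gsvm),
           o_quantile7(asvm, 0.75) - o_quantile7(asvm, 0.25),
           o_quantile7(gsvm, 0.75) - o_quantile7(gsvm, 0.25),
           o_mean(horiz), max(horiz))
  # closing
  ema <- asvm[1]
  for (i in seq_len(L)[-1]) ema <- 0.1 * asvm[i] + 0.9 * ema
  ang <- 0
  for (i in seq_len(L)) {
    ang <- ang + if (asvm[i] == 0) 0 else {
      acos(min(1, max(-1, acc[i, 3] / asvm[i])))
    }
  }
  zs <- if (o_sd(asvm) == 0) 0 else (asvm[L] - o_mean(asvm)) / o_sd(asvm)
  ad <- sqrt(sum(sapply(1:3, function(j) {
    v <- o_cumtrapz(gyr[, j], dt); v[L]
  })^2))
  out <- c(out, ema, ang / L, zs, ad)
  stopifnot(length(out) == 199L)
  unname(out)
}

# brute-force window-count enumerator
oracle_window_count <- function(N, L, H) {
  n <- 0L
  start <- 1L
  while (start + L - 1L <= N) {
    n <- n + 1L
    start <- start + H
  }
  n
}

# O(W^2) ReliefF with k hits / k misses per class, range-normalised
# Manhattan distance, explicit loops everywhere.
oracle_relieff <- function(X, y, k = 10L) {
  W <- nrow(X); F <- ncol(X)
  rng <- numeric(F)
  for (j in seq_len(F)) rng[j] <- max(X[, j]) - min(X[, j])
  rng[rng == 0] <- 1
  Xn <- X
  for (j in seq_len(F)) Xn[, j] <- X[, j] / rng[j]
  D <- matrix(0, W, W)
  for (a in seq_len(W)) {
    for (b in seq_len(W)) {
      D[a, b] <- sum(abs(Xn[a, ] - Xn[b, ]))
    }
  }
  classes <- sort(unique(y))
  prior <- sapply(classes, function(cl) mean(y == cl))
  names(prior) <- classes
  scores <- numeric(F)
  for (i in seq_len(W)) {
    ci <- y[i]
    hits <- setdiff(which(y == ci), i)
    if (length(hits) > 0) {
      hits <- hits[order(D[i, hits], hits)]
      hits <- hits[seq_len(min(k, length(hits)))]
      for (h in hits) {
        scores <- scores - abs(Xn[h, ] - Xn[i, ]) / (W * length(hits))
      }
    }
    for (cj in classes) {
      if (cj == ci) next
      mis <- which(y == cj)
      mis <- mis[order(D[i, mis], mis)]
      mis <- mis[seq_len(min(k, length(mis)))]
      wgt <- prior[[as.character(cj)]] / (1 - prior[[as.character(ci)]])
      for (m in mis) {
        scores <- scores + wgt * abs(Xn[m, ] - Xn[i, ]) / (W * length(mis))
      }
    }
  }
  scores
}

# direct-formula multiclass MCC
oracle_mcc <- function(C) {
  K <- nrow(C)
  s <- sum(C)
  c_ok <- 0
  for (k in seq_len(K)) c_ok <- c_ok + C[k, k]
  tk <- numeric(K); pk <- numeric(K)
  for (k in seq_len(K)) {
    tk[k] <- sum(C[k, ])
    pk[k] <- sum(C[, k])
  }
  num <- c_ok * s - sum(tk * pk)
  den <- sqrt(s^2 - sum(pk^2)) * sqrt(s^2 - sum(tk^2))
  if (den == 0) 0 else num / den
}

# brute-force per-class tally from raw truth/prediction vectors
oracle_perclass <- function(truth, pred, classes) {
  res <- list()
  for (cl in classes) {
    tp <- sum(truth == cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    fp <- sum(truth != cl & pred == cl)
    tn <- sum(truth != cl & pred != cl)
    res[[as.character(cl)]] <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  }
  res
}
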