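# Small feature-window neural networks: CNN, LSTM, BiLSTM and CNN-LSTM.
#
# The networks consume an engineered feature vector treated as a length-F
# single-channel sequence (the protocol feeds selected features, not raw
# windows, to the nets). Layers, backpropagation and the Adam optimiser are
# implemented here directly on base matrices; gradients are verified
# against finite differences in the test suite.

#' Neural network specification
#'
#' The training regime is held constant across architectures: 100 epochs,
#' batch size 64, Adam at a constant 0.001 learning rate, cross-entropy
#' loss, 150 hidden units in the recurrent layer, 20-way softmax output.
#'
#' @param arch `"cnn"`, `"lstm"`, `"bilstm"` or `"cnn_lstm"`.
#' @param input_width F, the number of selected features fed to the net.
#' @param n_classes Output width (20, the taxonomy size).
#' @param hidden_units Recurrent hidden units (default 150).
#' @param epochs,batch_size,learning_rate Training regime.
#' @param seed Seed for parameter initialisation and batch shuffling.
#' @return A `net_spec`.
#' @export
net_spec <- function(arch = c("cnn", "lstm", "bilstm", "cnn_lstm"),
                     input_width, n_classes = 20L, hidden_units = 150L,
                     epochs = 100L, batch_size = 64L, learning_rate = 1e-3,
                     seed = 1L) {
  arch <- match.arg(arch)
  stopifnot(input_width >= 1L, n_classes >= 2L)
  structure(list(arch = arch, input_width = as.integer(input_width),
                 n_classes = as.integer(n_classes),
                 hidden_units = as.integer(hidden_units),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "net_spec")
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

lstm_params <- function(C, H) {
  list(Wx = glorot(C, 4L * H), Wh = glorot(H, 4L * H),
       b = rep(0, 4L * H))
}

conv_params <- function(k, Cin, Cout) {
  list(W = array(stats::runif(k * Cin * Cout,
                              -sqrt(6 / (k * Cin + Cout)),
                              sqrt(6 / (k * Cin + Cout))),
                 dim = c(k, Cin, Cout)),
       b = rep(0, Cout))
}

#' Build a trainable model handle
#'
#' Architectures: `cnn` = two 1-D convolution blocks (32 then 64 filters,
#' kernel 3, ReLU, max-pool 2) into a dense softmax; `lstm` = one recurrent
#' layer over the feature sequence, last hidden state into the softmax;
#' `bilstm` = forward and backward recurrent layers, concatenated;
#' `cnn_lstm` = one convolution block feeding the recurrent layer. All end
#' in an `n_classes`-way softmax. Initialisation is a deterministic
#' function of the spec seed.
#'
#' @param spec A [net_spec()].
#' @return A `net_model` (parameters + spec).
#' @export
net_build <- function(spec) {
  stopifnot(inherits(spec, "net_spec"))
  F <- spec$input_width; H <- spec$hidden_units; K <- spec$n_classes
  params <- with_seed(spec$seed, switch(spec$arch,
    cnn = {
      T1 <- F %/% 2L; T2 <- T1 %/% 2L
      if (T2 < 1L) abort_contract("input too short for two pooling stages")
      list(conv1 = conv_params(3L, 1L, 32L),
           conv2 = conv_params(3L, 32L, 64L),
           dense = list(W = glorot(T2 * 64L, K), b = rep(0, K)))
    },
    lstm = list(rnn = lstm_params(1L, H),
                dense = list(W = glorot(H, K), b = rep(0, K))),
    bilstm = list(fwd = lstm_params(1L, H), bwd = lstm_params(1L, H),
                  dense = list(W = glorot(2L * H, K), b = rep(0, K))),
    cnn_lstm = {
      T1 <- F %/% 2L
      if (T1 < 1L) abort_contract("input too short for the pooling stage")
      list(conv1 = conv_params(3L, 1L, 32L), rnn = lstm_params(32L, H),
           dense = list(W = glorot(H, K), b = rep(0, K)))
    }
  ))
  structure(list(spec = spec, params = params), class = "net_model")
}

#' Total number of trainable parameters
#'
#' @param model A [net_build()] handle.
#' @return Integer parameter count.
#' @export
net_n_params <- function(model) {
  sum(vapply(unlist(model$params, recursive = FALSE), length, 0L))
}

# ---- layer primitives -----------------------------------------------------

# 1-D convolution with same-padding, kernel k. X: n x T x Cin array.
conv1d_forward <- function(X, par) {
  k <- dim(par$W)[1L]; Cin <- dim(par$W)[2L]; Cout <- dim(par$W)[3L]
  n <- dim(X)[1L]; T <- dim(X)[2L]
  pad <- (k - 1L) %/% 2L
  Wmat <- matrix(par$W, k * Cin, Cout)
  # column matrix: rows = (n, t), cols = (dk, cin)
  cols <- matrix(0, n * T, k * Cin)
  for (dk in seq_len(k)) {
    src <- seq_len(T) + dk - 1L - pad
    ok <- src >= 1L & src <= T
    block <- matrix(0, n * T, Cin)
    for (ci in seq_len(Cin)) {
      v <- matrix(0, n, T)
      v[, ok] <- X[, src[ok], ci]
      block[, ci] <- as.vector(v)
    }
    cols[, ((dk - 1L) * Cin + 1L):(dk * Cin)] <- block
  }
  out_mat <- cols %*% Wmat
  out <- array(out_mat, dim = c(n, T, Cout))
  out <- sweep(out, 3L, par$b, "+")
  list(out = out, cols = cols, dims = c(n = n, T = T, k = k,
                                        Cin = Cin, Cout = Cout, pad = pad))
}

conv1d_backward <- function(dout, cache, par) {
  d <- cache$dims
  n <- d[["n"]]; T <- d[["T"]]; k <- d[["k"]]
  Cin <- d[["Cin"]]; Cout <- d[["Cout"]]; pad <- d[["pad"]]
  dmat <- matrix(dout, n * T, Cout)
  Wmat <- matrix(par$W, k * Cin, Cout)
  dW <- array(crossprod(cache$cols, dmat), dim = dim(par$W))
  db <- colSums(dmat)
  dcols <- dmat %*% t(Wmat)
  dX <- array(0, dim = c(n, T, Cin))
  for (dk in seq_len(k)) {
    src <- seq_len(T) + dk - 1L - pad
    ok <- src >= 1L & src <= T
    for (ci in seq_len(Cin)) {
      v <- matrix(dcols[, (dk - 1L) * Cin + ci], n, T)
      dX[, src[ok], ci] <- dX[, src[ok], ci] + v[, ok]
    }
  }
  list(dX = dX, grads = list(W = dW, b = db))
}

relu_forward <- function(X) list(out = pmax(X, 0), mask = X > 0)
relu_backward <- function(dout, cache) dout * cache$mask

# Max-pool size 2, stride 2 along the time axis.
pool2_forward <- function(X) {
  n <- dim(X)[1L]; T <- dim(X)[2L]; C <- dim(X)[3L]
  T2 <- T %/% 2L
  a <- X[, 2L * seq_len(T2) - 1L, , drop = FALSE]
  b <- X[, 2L * seq_len(T2), , drop = FALSE]
  take_a <- a >= b
  list(out = ifelse(take_a, a, b), take_a = take_a, T = T, T2 = T2)
}

pool2_backward <- function(dout, cache) {
  n <- dim(dout)[1L]; C <- dim(dout)[3L]
  dX <- array(0, dim = c(n, cache$T, C))
  dX[, 2L * seq_len(cache$T2) - 1L, ] <- dout * cache$take_a
  dX[, 2L * seq_len(cache$T2), ] <- dX[, 2L * seq_len(cache$T2), ] +
    dout * !cache$take_a
  dX
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# LSTM over X: n x T x C; returns the last hidden state (n x H).
lstm_forward <- function(X, par) {
  n <- dim(X)[1L]; T <- dim(X)[2L]
  H <- ncol(par$Wh) %/% 4L
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  cache <- vector("list", T)
  for (t in seq_len(T)) {
    x_t <- matrix(X[, t, ], n)
    g <- x_t %*% par$Wx + h %*% par$Wh +
      matrix(par$b, n, 4L * H, byrow = TRUE)
    i <- sigmoid(g[, 1:H, drop = FALSE])
    f <- sigmoid(g[, (H + 1L):(2L * H), drop = FALSE])
    gg <- tanh(g[, (2L * H + 1L):(3L * H), drop = FALSE])
    o <- sigmoid(g[, (3L * H + 1L):(4L * H), drop = FALSE])
    c_new <- f * cc + i * gg
    h_new <- o * tanh(c_new)
    cache[[t]] <- list(x = x_t, h_prev = h, c_prev = cc, i = i, f = f,
                       g = gg, o = o, c = c_new)
    h <- h_new; cc <- c_new
  }
  list(out = h, cache = cache, n = n, T = T, H = H, C = dim(X)[3L])
}

lstm_backward <- function(dh_last, fw, par) {
  n <- fw$n; T <- fw$T; H <- fw$H; C <- fw$C
  dWx <- matrix(0, nrow(par$Wx), ncol(par$Wx))
  dWh <- matrix(0, nrow(par$Wh), ncol(par$Wh))
  db <- rep(0, length(par$b))
  dX <- array(0, dim = c(n, T, C))
  dh <- dh_last
  dc <- matrix(0, n, H)
  for (t in rev(seq_len(T))) {
    cc <- fw$cache[[t]]
    tc <- tanh(cc$c)
    do <- dh * tc
    dc <- dc + dh * cc$o * (1 - tc^2)
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    dG <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do * cc$o * (1 - cc$o))
    dWx <- dWx + crossprod(cc$x, dG)
    dWh <- dWh + crossprod(cc$h_prev, dG)
    db <- db + colSums(dG)
    dX[, t, ] <- dG %*% t(par$Wx)
    dh <- dG %*% t(par$Wh)
    dc <- dc * cc$f
  }
  list(dX = dX, grads = list(Wx = dWx, Wh = dWh, b = db))
}

dense_forward <- function(X, par) {
  list(out = X %*% par$W + matrix(par$b, nrow(X), length(par$b),
                                  byrow = TRUE), X = X)
}

dense_backward <- function(dout, cache, par) {
  list(dX = dout %*% t(par$W),
       grads = list(W = crossprod(cache$X, dout), b = colSums(dout)))
}

softmax_probs <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- model forward / backward ---------------------------------------------

#' Forward pass: class probabilities for a batch
#'
#' @param model A `net_model`.
#' @param X n x F matrix of (scaled) feature vectors.
#' @return n x n_classes matrix of softmax probabilities (rows sum to 1).
#' @export
net_forward <- function(model, X) {
  net_pass(model, as.matrix(X))$probs
}

net_pass <- function(model, X) {
  p <- model$params
  n <- nrow(X)
  Xa <- array(X, dim = c(n, ncol(X), 1L))
  caches <- list()
  feat <- switch(model$spec$arch,
    cnn = {
      c1 <- conv1d_forward(Xa, p$conv1); r1 <- relu_forward(c1$out)
      p1 <- pool2_forward(r1$out)
      c2 <- conv1d_forward(p1$out, p$conv2); r2 <- relu_forward(c2$out)
      p2 <- pool2_forward(r2$out)
      caches <- list(c1 = c1, r1 = r1, p1 = p1, c2 = c2, r2 = r2, p2 = p2)
      matrix(p2$out, n)
    },
    lstm = {
      fw <- lstm_forward(Xa, p$rnn)
      caches <- list(fw = fw)
      fw$out
    },
    bilstm = {
      fw <- lstm_forward(Xa, p$fwd)
      Xr <- Xa[, rev(seq_len(dim(Xa)[2L])), , drop = FALSE]
      bw <- lstm_forward(Xr, p$bwd)
      caches <- list(fw = fw, bw = bw)
      cbind(fw$out, bw$out)
    },
    cnn_lstm = {
      c1 <- conv1d_forward(Xa, p$conv1); r1 <- relu_forward(c1$out)
      p1 <- pool2_forward(r1$out)
      fw <- lstm_forward(p1$out, p$rnn)
      caches <- list(c1 = c1, r1 = r1, p1 = p1, fw = fw)
      fw$out
    }
  )
  d <- dense_forward(feat, p$dense)
  list(probs = softmax_probs(d$out), logits = d$out, dense_cache = d,
       caches = caches, n = n)
}

net_backward <- function(model, pass, y_units) {
  p <- model$params
  n <- pass$n
  probs <- pass$probs
  dlogits <- probs
  dlogits[cbind(seq_len(n), y_units)] <-
    dlogits[cbind(seq_len(n), y_units)] - 1
  dlogits <- dlogits / n
  dd <- dense_backward(dlogits, pass$dense_cache, p$dense)
  grads <- list(dense = dd$grads)
  ca <- pass$caches
  switch(model$spec$arch,
    cnn = {
      dp2 <- array(dd$dX, dim = dim(ca$p2$out))
      dr2 <- pool2_backward(dp2, ca$p2)
      dc2 <- relu_backward(dr2, ca$r2)
      b2 <- conv1d_backward(dc2, ca$c2, p$conv2)
      dr1 <- pool2_backward(b2$dX, ca$p1)
      dc1 <- relu_backward(dr1, ca$r1)
      b1 <- conv1d_backward(dc1, ca$c1, p$conv1)
      grads$conv2 <- b2$grads; grads$conv1 <- b1$grads
    },
    lstm = {
      grads$rnn <- lstm_backward(dd$dX, ca$fw, p$rnn)$grads
    },
    bilstm = {
      H <- model$spec$hidden_units
      grads$fwd <- lstm_backward(dd$dX[, 1:H, drop = FALSE], ca$fw,
                                 p$fwd)$grads
      grads$bwd <- lstm_backward(dd$dX[, (H + 1L):(2L * H), drop = FALSE],
                                 ca$bw, p$bwd)$grads
    },
    cnn_lstm = {
      lb <- lstm_backward(dd$dX, ca$fw, p$rnn)
      grads$rnn <- lb$grads
      dr1 <- pool2_backward(lb$dX, ca$p1)
      dc1 <- relu_backward(dr1, ca$r1)
      b1 <- conv1d_backward(dc1, ca$c1, p$conv1)
      grads$conv1 <- b1$grads
    }
  )
  grads
}

# Adam step over a nested parameter list.
adam_init <- function(params) {
  zeros <- function(x) {
    if (is.list(x)) lapply(x, zeros) else x * 0
  }
  list(m = zeros(params), v = zeros(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  tt <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    m2 <- beta1 * m + (1 - beta1) * g
    v2 <- beta2 * v + (1 - beta2) * g^2
    mhat <- m2 / (1 - beta1^tt)
    vhat <- v2 / (1 - beta2^tt)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m2, v = v2)
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = tt))
}

cross_entropy <- function(probs, y_units) {
  -mean(log(pmax(probs[cbind(seq_len(nrow(probs)), y_units)], 1e-12)))
}

#' Train a network and evaluate it on held-out windows
#'
#' Trains for exactly `spec$epochs` epochs of shuffled mini-batches
#' (`spec$batch_size`), Adam at the constant `spec$learning_rate`,
#' cross-entropy loss, then predicts the test partition and returns the
#' same report schema as the classical models.
#'
#' @param spec A [net_spec()] whose `input_width` matches `ncol` of the
#'   feature matrices.
#' @param X_train,y_train Scaled training features (n x F) and class ids.
#' @param X_test,y_test Held-out features and class ids.
#' @return An `eval_report` with timing fields and a `loss` vector (mean
#'   training loss per epoch) in `$loss_history`.
#' @export
net_train_eval <- function(spec, X_train, y_train, X_test, y_test) {
  X_train <- as.matrix(X_train); X_test <- as.matrix(X_test)
  stopifnot(ncol(X_train) == spec$input_width,
            ncol(X_test) == spec$input_width)
  y_train <- as.integer(y_train); y_test <- as.integer(y_test)
  if (any(c(y_train, y_test) < 1L | c(y_train, y_test) > spec$n_classes)) {
    abort_contract("class ids must lie in 1..n_classes")
  }
  missing_cls <- setdiff(sort(unique(y_test)), sort(unique(y_train)))
  if (length(missing_cls) > 0L) {
    warning("class(es) absent from training set: ",
            paste(missing_cls, collapse = ", "), call. = FALSE)
  }
  model <- net_build(spec)
  state <- adam_init(model$params)
  n <- nrow(X_train)
  losses <- numeric(spec$epochs)
  t0 <- proc.time()[[3L]]
  with_seed(spec$seed + 1L, {
    for (ep in seq_len(spec$epochs)) {
      idx <- sample.int(n)
      batch_losses <- c()
      for (start in seq(1L, n, by = spec$batch_size)) {
        bi <- idx[start:min(start + spec$batch_size - 1L, n)]
        pass <- net_pass(model, X_train[bi, , drop = FALSE])
        batch_losses <- c(batch_losses, cross_entropy(pass$probs,
                                                      y_train[bi]))
        grads <- net_backward(model, pass, y_train[bi])
        st <- adam_step(model$params, grads, state, spec$learning_rate)
        model$params <- st$params
        state <- st$state
      }
      losses[ep] <- mean(batch_losses)
    }
  })
  t1 <- proc.time()[[3L]]
  pred <- max.col(net_forward(model, X_test), ties.method = "first")
  t2 <- proc.time()[[3L]]
  classes <- sort(unique(c(y_train, y_test)))
  out <- compute_metrics(confusion_from(y_test, pred, classes))
  out$train_time_s <- t1 - t0
  out$test_time_s <- t2 - t1
  out$test_time_per_window_s <- (t2 - t1) / nrow(X_test)
  out$loss_history <- losses
  out$model <- model
  out
}
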