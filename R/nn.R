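# Compact neural-network training core: minibatch Adagrad on binary
# cross-entropy, written with base matrix operations. Three architectures
# are provided: an LSTM over the time dimension, a 1-D convolution over
# time with global max pooling, and a single dense (linear) layer on the
# flattened input. All randomness (weight init, shuffling, dropout) is
# drawn from a seed kept inside the model, so training is reproducible on
# a fixed BLAS.

sigmoid <- function(z) 1 / (1 + exp(-z))

bce_loss <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Adagrad state is a list parallel to the parameter list; accumulators
# start at 0.1 (the usual framework convention) so the first step is not
# simply +-lr per coordinate
adagrad_update <- function(params, grads, cache, lr, eps = 1e-8) {
  for (nm in names(params)) {
    cache[[nm]] <- cache[[nm]] + grads[[nm]]^2
    params[[nm]] <- params[[nm]] - lr * grads[[nm]] / (sqrt(cache[[nm]]) + eps)
  }
  list(params = params, cache = cache)
}

init_uniform <- function(nr, nc, scale) {
  matrix(stats::runif(nr * nc, -scale, scale), nr, nc)
}

# generic minibatch loop with early stopping on the training-loss plateau
train_loop <- function(x, y, params, forward_backward, hp) {
  n <- length(y)
  cache <- lapply(params, function(p) p * 0 + 0.1)
  best <- Inf
  stall <- 0L
  history <- numeric(0)
  for (epoch in seq_len(hp$epochs)) {
    idx <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1L, n, by = hp$batch_size)) {
      batch <- idx[start:min(start + hp$batch_size - 1L, n)]
      fb <- forward_backward(params, batch, training = TRUE)
      losses <- c(losses, fb$loss)
      upd <- adagrad_update(params, fb$grads, cache, hp$learning_rate)
      params <- upd$params
      cache <- upd$cache
    }
    epoch_loss <- mean(losses)
    history <- c(history, epoch_loss)
    if (epoch_loss < best - 1e-4) {
      best <- epoch_loss
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= hp$patience) break
    }
  }
  list(params = params, history = history)
}

## ---- LSTM ------------------------------------------------------------

lstm_init <- function(n_input, hidden) {
  s <- 1 / sqrt(hidden)
  b <- numeric(4L * hidden)
  b[(hidden + 1L):(2L * hidden)] <- 1  # forget-gate bias starts open
  list(
    Wx = init_uniform(n_input, 4L * hidden, s),
    Wh = init_uniform(hidden, 4L * hidden, s),
    b = b,
    Wy = init_uniform(hidden, 1L, s),
    by = 0
  )
}

lstm_forward <- function(params, xb, hidden, keep_states = FALSE) {
  n <- dim(xb)[1]
  t_len <- dim(xb)[2]
  h <- matrix(0, n, hidden)
  cc <- matrix(0, n, hidden)
  states <- if (keep_states) vector("list", t_len) else NULL
  ii <- seq_len(hidden)
  for (t in seq_len(t_len)) {
    xt <- matrix(xb[, t, ], n)
    z <- xt %*% params$Wx + h %*% params$Wh +
      matrix(params$b, n, 4L * hidden, byrow = TRUE)
    i_g <- sigmoid(z[, ii, drop = FALSE])
    f_g <- sigmoid(z[, hidden + ii, drop = FALSE])
    g_g <- tanh(z[, 2L * hidden + ii, drop = FALSE])
    o_g <- sigmoid(z[, 3L * hidden + ii, drop = FALSE])
    c_prev <- cc
    h_prev <- h
    cc <- f_g * c_prev + i_g * g_g
    h <- o_g * tanh(cc)
    if (keep_states) {
      states[[t]] <- list(
        xt = xt, i = i_g, f = f_g, g = g_g, o = o_g,
        c = cc, c_prev = c_prev, h_prev = h_prev
      )
    }
  }
  list(h = h, states = states)
}

lstm_forward_backward <- function(params, x, y, batch, hp) {
  xb <- x[batch, , , drop = FALSE]
  yb <- y[batch]
  n <- length(batch)
  hidden <- hp$hidden
  fwd <- lstm_forward(params, xb, hidden, keep_states = TRUE)
  # inverted dropout on the final hidden state
  if (hp$dropout > 0) {
    mask <- matrix(
      stats::rbinom(n * hidden, 1L, 1 - hp$dropout) / (1 - hp$dropout),
      n, hidden
    )
  } else {
    mask <- matrix(1, n, hidden)
  }
  h_drop <- fwd$h * mask
  p <- sigmoid(drop(h_drop %*% params$Wy) + params$by)
  loss <- bce_loss(p, yb)

  dlogit <- matrix((p - yb) / n, n, 1L)
  grads <- list(
    Wy = crossprod(h_drop, dlogit),
    by = sum(dlogit)
  )
  dh <- (dlogit %*% t(params$Wy)) * mask
  dWx <- params$Wx * 0
  dWh <- params$Wh * 0
  db <- params$b * 0
  dc_next <- matrix(0, n, hidden)
  for (t in rev(seq_along(fwd$states))) {
    st <- fwd$states[[t]]
    tc <- tanh(st$c)
    do_g <- dh * tc
    dc <- dc_next + dh * st$o * (1 - tc^2)
    di <- dc * st$g
    dg <- dc * st$i
    df <- dc * st$c_prev
    dc_next <- dc * st$f
    dz <- cbind(
      di * st$i * (1 - st$i),
      df * st$f * (1 - st$f),
      dg * (1 - st$g^2),
      do_g * st$o * (1 - st$o)
    )
    dWx <- dWx + crossprod(st$xt, dz)
    dWh <- dWh + crossprod(st$h_prev, dz)
    db <- db + colSums(dz)
    dh <- dz %*% t(params$Wh)
  }
  grads$Wx <- dWx
  grads$Wh <- dWh
  grads$b <- db
  list(loss = loss, grads = grads)
}

fit_lstm <- function(x, y, hp) {
  n_input <- dim(x)[3]
  params <- lstm_init(n_input, hp$hidden)
  fb <- function(params, batch, training) {
    lstm_forward_backward(params, x, y, batch, hp)
  }
  train_loop(x, y, params, fb, hp)
}

predict_lstm <- function(params, x, hp) {
  fwd <- lstm_forward(params, x, hp$hidden)
  as.numeric(sigmoid(drop(fwd$h %*% params$Wy) + params$by))
}

## ---- 1-D CNN ---------------------------------------------------------

# im2col over the time axis: rows index (sample, position), columns the
# kernel-window values for every channel
conv_im2col <- function(x, kernel) {
  n <- dim(x)[1]
  t_len <- dim(x)[2]
  l_out <- t_len - kernel + 1L
  cols <- lapply(seq_len(kernel), function(j) {
    matrix(x[, j:(j + l_out - 1L), , drop = FALSE], nrow = n * l_out)
  })
  do.call(cbind, cols)
}

cnn_init <- function(n_input, kernel, filters) {
  s <- 1 / sqrt(kernel * n_input)
  list(
    W = init_uniform(kernel * n_input, filters, s),
    b = numeric(filters),
    Wy = init_uniform(filters, 1L, s),
    by = 0
  )
}

cnn_forward <- function(params, xb, hp, keep = FALSE) {
  n <- dim(xb)[1]
  l_out <- dim(xb)[2] - hp$kernel + 1L
  filters <- hp$filters
  xcol <- conv_im2col(xb, hp$kernel)
  s <- xcol %*% params$W +
    matrix(params$b, nrow(xcol), filters, byrow = TRUE)
  relu <- pmax(s, 0)
  pooled <- matrix(0, n, filters)
  amax <- matrix(0L, n, filters)
  for (f in seq_len(filters)) {
    m <- matrix(relu[, f], n, l_out)
    a <- max.col(m, ties.method = "first")
    amax[, f] <- a
    pooled[, f] <- m[cbind(seq_len(n), a)]
  }
  p <- sigmoid(drop(pooled %*% params$Wy) + params$by)
  out <- list(p = p)
  if (keep) {
    out <- c(out, list(
      xcol = xcol, s = s, pooled = pooled, amax = amax,
      n = n, l_out = l_out
    ))
  }
  out
}

cnn_forward_backward <- function(params, x, y, batch, hp) {
  xb <- x[batch, , , drop = FALSE]
  yb <- y[batch]
  fwd <- cnn_forward(params, xb, hp, keep = TRUE)
  n <- fwd$n
  loss <- bce_loss(fwd$p, yb)
  dlogit <- matrix((fwd$p - yb) / n, n, 1L)
  grads <- list(
    Wy = crossprod(fwd$pooled, dlogit),
    by = sum(dlogit)
  )
  dpooled <- dlogit %*% t(params$Wy)
  ds <- matrix(0, nrow(fwd$xcol), hp$filters)
  for (f in seq_len(hp$filters)) {
    rows <- seq_len(n) + (fwd$amax[, f] - 1L) * n
    ds[rows, f] <- dpooled[, f]
  }
  ds[fwd$s <= 0] <- 0
  grads$W <- crossprod(fwd$xcol, ds)
  grads$b <- colSums(ds)
  list(loss = loss, grads = grads)
}

fit_cnn <- function(x, y, hp) {
  params <- cnn_init(dim(x)[3], hp$kernel, hp$filters)
  fb <- function(params, batch, training) {
    cnn_forward_backward(params, x, y, batch, hp)
  }
  train_loop(x, y, params, fb, hp)
}

predict_cnn <- function(params, x, hp) {
  as.numeric(cnn_forward(params, x, hp)$p)
}

## ---- linear (single dense layer) --------------------------------------

flatten_input <- function(x) {
  matrix(x, nrow = dim(x)[1])
}

linear_init <- function(n_features) {
  list(W = init_uniform(n_features, 1L, 1 / sqrt(n_features)), b = 0)
}

linear_forward_backward <- function(params, xf, y, batch) {
  xb <- xf[batch, , drop = FALSE]
  yb <- y[batch]
  n <- length(batch)
  p <- sigmoid(drop(xb %*% params$W) + params$b)
  loss <- bce_loss(p, yb)
  dlogit <- matrix((p - yb) / n, n, 1L)
  list(
    loss = loss,
    grads = list(W = crossprod(xb, dlogit), b = sum(dlogit))
  )
}

fit_linear_nn <- function(x, y, hp) {
  xf <- flatten_input(x)
  params <- linear_init(ncol(xf))
  fb <- function(params, batch, training) {
    linear_forward_backward(params, xf, y, batch)
  }
  train_loop(xf, y, params, fb, hp)
}

predict_linear_nn <- function(params, x, hp) {
  xf <- flatten_input(x)
  as.numeric(sigmoid(drop(xf %*% params$W) + params$b))
}
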