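# Minimal neural-network primitives: 1-D valid convolution, non-overlapping
# max pooling, an LSTM cell with full backpropagation through time, dense
# layers, softmax cross-entropy and Adam. Written in plain matrix R;
# everything is deterministic given the R RNG state.

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

# X: T x Cin. W: (k*Cin) x F (columns of X stacked per offset). Valid conv.
conv1d_fwd <- function(X, W, b, k) {
  To <- nrow(X) - k + 1L
  M <- do.call(cbind, lapply(seq_len(k), function(j) X[j:(j + To - 1L), , drop = FALSE]))
  A <- M %*% W
  A <- sweep(A, 2L, b, "+")
  list(out = A, M = M, k = k, Tin = nrow(X), Cin = ncol(X))
}

conv1d_bwd <- function(cache, W, dA) {
  dW <- crossprod(cache$M, dA)
  db <- colSums(dA)
  dM <- dA %*% t(W)
  dX <- matrix(0, cache$Tin, cache$Cin)
  To <- nrow(dA)
  for (j in seq_len(cache$k)) {
    cols <- ((j - 1L) * cache$Cin + 1L):(j * cache$Cin)
    dX[j:(j + To - 1L), ] <- dX[j:(j + To - 1L), ] + dM[, cols, drop = FALSE]
  }
  list(dW = dW, db = db, dX = dX)
}

# non-overlapping max pooling along time; A: T x F
maxpool_fwd <- function(A, p) {
  Tp <- nrow(A) %/% p
  Fn <- ncol(A)
  out <- matrix(0, Tp, Fn)
  arg <- matrix(0L, Tp, Fn)
  for (f in seq_len(Fn)) {
    m <- matrix(A[seq_len(Tp * p), f], nrow = p)
    w <- max.col(t(m), ties.method = "first")
    out[, f] <- m[cbind(w, seq_len(Tp))]
    arg[, f] <- (seq_len(Tp) - 1L) * p + w
  }
  list(out = out, arg = arg, Tin = nrow(A))
}

maxpool_bwd <- function(cache, dP) {
  dA <- matrix(0, cache$Tin, ncol(dP))
  for (f in seq_len(ncol(dP))) {
    dA[cache$arg[, f], f] <- dP[, f]
  }
  dA
}

lstm_init <- function(input_dim, hidden) {
  list(
    Wx = glorot(input_dim, 4L * hidden),
    Wh = glorot(hidden, 4L * hidden),
    b = {
      b <- numeric(4L * hidden)
      b[(hidden + 1L):(2L * hidden)] <- 1 # forget-gate bias at 1
      b
    }
  )
}

# Z: Ts x D. Returns last hidden state and the per-step cache for BPTT.
lstm_fwd <- function(Z, p, hidden) {
  Ts <- nrow(Z)
  H <- hidden
  h <- numeric(H)
  cc <- numeric(H)
  cache <- vector("list", Ts)
  for (t in seq_len(Ts)) {
    a <- as.numeric(Z[t, ] %*% p$Wx + h %*% p$Wh) + p$b
    i <- sigmoid(a[1:H])
    f <- sigmoid(a[(H + 1):(2 * H)])
    g <- tanh(a[(2 * H + 1):(3 * H)])
    o <- sigmoid(a[(3 * H + 1):(4 * H)])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    cache[[t]] <- list(i = i, f = f, g = g, o = o, c = cc, tc = tc,
      c_prev = c_prev, h_prev = h, z = Z[t, ])
    h <- o * tc
  }
  list(out = h, cache = cache, Ts = Ts, H = H, D = ncol(Z))
}

lstm_bwd <- function(fwd, p, dh_last) {
  H <- fwd$H
  dWx <- matrix(0, fwd$D, 4L * H)
  dWh <- matrix(0, H, 4L * H)
  db <- numeric(4L * H)
  dZ <- matrix(0, fwd$Ts, fwd$D)
  dh <- dh_last
  dc <- numeric(H)
  for (t in rev(seq_len(fwd$Ts))) {
    s <- fwd$cache[[t]]
    do <- dh * s$tc
    dct <- dh * s$o * (1 - s$tc^2) + dc
    di <- dct * s$g
    df <- dct * s$c_prev
    dg <- dct * s$i
    da <- c(
      di * s$i * (1 - s$i),
      df * s$f * (1 - s$f),
      dg * (1 - s$g^2),
      do * s$o * (1 - s$o)
    )
    dWx <- dWx + outer(s$z, da)
    dWh <- dWh + outer(s$h_prev, da)
    db <- db + da
    dZ[t, ] <- as.numeric(p$Wx %*% da)
    dh <- as.numeric(p$Wh %*% da)
    dc <- dct * s$f
  }
  list(dWx = dWx, dWh = dWh, db = db, dZ = dZ)
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# Adam state and update over a named list of parameter arrays
adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

scale_grads <- function(g, s) lapply(g, function(x) x * s)
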