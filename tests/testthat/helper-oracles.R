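# independent brute-force oracles, deliberately written as naive loops so
# they share no code with the implementations they check

oracle_hudgins <- function(x, fs, eps) {
  n <- length(x)
  ss <- 0
  sa <- 0
  for (i in seq_len(n)) {
    ss <- ss + x[i]^2
    sa <- sa + abs(x[i])
  }
  wl <- 0
  zc <- 0
  for (i in seq_len(n - 1)) {
    wl <- wl + abs(x[i + 1] - x[i])
    if (x[i] * x[i + 1] < 0 && abs(x[i] - x[i + 1]) > eps) zc <- zc + 1
  }
  ssc <- 0
  if (n >= 3) {
    for (i in 2:(n - 1)) {
      d1 <- x[i] - x[i - 1]
      d2 <- x[i] - x[i + 1]
      if (d1 * d2 > 0 && abs(d1) > eps && abs(d2) > eps) ssc <- ssc + 1
    }
  }
  list(
    rms = sqrt(ss / n), mav = sa / n, iemg = sa / fs, wl = wl,
    zc = zc, ssc = ssc
  )
}

# single-segment Hann periodogram median frequency via a naive DFT matrix
# and an explicit cumulative-power crossing loop
oracle_mf_periodogram <- function(x, fs) {
  L <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))
  xw <- x * w
  nf <- L %/% 2 + 1
  freqs <- (seq_len(nf) - 1) * fs / L
  tgrid <- seq_len(L) - 1
  power <- numeric(nf)
  for (k in seq_len(nf)) {
    e <- exp(-2i * pi * (k - 1) * tgrid / L)
    power[k] <- Mod(sum(xw * e))^2
  }
  power[2:(nf - 1 + (L %% 2))] <- 2 * power[2:(nf - 1 + (L %% 2))]
  total <- sum(power)
  acc <- 0
  for (k in seq_len(nf)) {
    nxt <- acc + power[k]
    if (nxt >= total / 2) {
      if (k == 1) return(freqs[1])
      frac <- (total / 2 - acc) / power[k]
      return(freqs[k - 1] + frac * (freqs[k] - freqs[k - 1]))
    }
    acc <- nxt
  }
  freqs[nf]
}

# AUC by counting concordant score pairs, half credit for ties
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# exact Shapley value by full enumeration of orderings x background rows
oracle_shapley_exact <- function(model_fn, x, background) {
  p <- length(x)
  perms <- combinat_perms(p)
  phi <- numeric(p)
  for (b in seq_len(nrow(background))) {
    for (r in seq_len(nrow(perms))) {
      z <- background[b, ]
      prev <- model_fn(matrix(z, 1))
      for (j in seq_len(p)) {
        feat <- perms[r, j]
        z[feat] <- x[feat]
        cur <- model_fn(matrix(z, 1))
        phi[feat] <- phi[feat] + (cur - prev)
        prev <- cur
      }
    }
  }
  phi / (nrow(background) * nrow(perms))
}

combinat_perms <- function(p) {
  if (p == 1) return(matrix(1))
  sub <- combinat_perms(p - 1)
  out <- NULL
  for (k in seq_len(p)) {
    rest <- setdiff(seq_len(p), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}
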