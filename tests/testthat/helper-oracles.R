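# Independent brute-force oracles: plain-loop implementations sharing no code
# with the package, used to pin the estimators' values.

oracle_renyi <- function(x, q) {
  x <- x - mean(x)
  n <- length(x)
  nb <- n %/% 2
  P <- numeric(nb)
  for (k in seq_len(nb)) {
    s <- 0 + 0i
    for (t in seq_len(n))
      s <- s + x[t] * exp(-2i * pi * k * (t - 1) / n)
    P[k] <- Mod(s)^2
  }
  p <- P / sum(P)
  log2(sum(p^q)) / (1 - q)
}

oracle_fuzzy <- function(x, a = 2, rf = 0.15, p = 2) {
  N <- length(x)
  sdx <- sd(x)
  if (sdx == 0) return(0)
  r <- rf * sdx
  vec <- function(i, m) {
    v <- x[i:(i + m - 1)]
    v - sum(v) / m
  }
  phi <- function(m) {
    nv <- N - a
    tot <- 0
    for (i in seq_len(nv)) {
      s <- 0
      for (j in seq_len(nv)) {
        if (j == i) next
        d <- max(abs(vec(i, m) - vec(j, m)))
        s <- s + exp(-(d^p) / r)
      }
      tot <- tot + s / (nv - 1)
    }
    tot / nv
  }
  -log(phi(a + 1) / phi(a))
}

oracle_disen <- function(x, m = 2, cc = 6, d = 1) {
  N <- length(x)
  sdx <- sd(x)
  if (sdx == 0) return(0)
  z <- integer(N)
  for (i in seq_len(N)) {
    y <- pnorm(x[i], mean(x), sdx)
    t <- cc * y + 0.5
    z[i] <- floor(t) + as.integer(t - floor(t) >= 0.5)  # half away from zero
    if (z[i] < 1) z[i] <- 1
    if (z[i] > cc) z[i] <- cc
  }
  nw <- N - (m - 1) * d
  pats <- character(nw)
  for (j in seq_len(nw))
    pats[j] <- paste(z[j + (0:(m - 1)) * d], collapse = "-")
  tab <- table(pats) / nw
  -sum(tab * log(tab))
}

oracle_rdis <- function(x, a = 2, M = 8, q = 2) {
  N <- length(x)
  nv <- N - a
  ds <- c()
  for (i in seq_len(nv - 1)) {
    for (j in (i + 1):nv) {
      d <- max(abs(x[i:(i + a - 1)] - x[j:(j + a - 1)]))
      ds <- c(ds, d)
    }
  }
  dmax <- max(ds)
  if (dmax == 0) return(0)
  cnt <- integer(M)
  for (d in ds) {
    b <- ceiling(d / dmax * M)
    if (b < 1) b <- 1
    cnt[b] <- cnt[b] + 1
  }
  p <- cnt / length(ds)
  log2(sum(p[p > 0]^q)) / ((1 - q) * log2(M))
}

oracle_pe <- function(x, m = 3) {
  nw <- length(x) - m + 1
  pats <- character(nw)
  for (i in seq_len(nw))
    pats[i] <- paste(order(x[i:(i + m - 1)]), collapse = "-")
  tab <- table(pats) / nw
  -sum(tab * log(tab))
}

oracle_impe <- function(x, m = 3, s = 2) {
  N <- length(x)
  pes <- numeric(s)
  for (i in seq_len(s)) {
    ncg <- (N - i + 1) %/% s
    y <- numeric(ncg)
    for (j in seq_len(ncg))
      y[j] <- sum(x[(i + s * (j - 1)):(i + s * j - 1)]) / s
    pes[i] <- oracle_pe(y, m)
  }
  sum(pes) / s
}

oracle_apen <- function(x, m = 2, rf = 0.15) {
  N <- length(x)
  r <- rf * sd(x)
  phi <- function(mm) {
    nv <- N - mm + 1
    tot <- 0
    for (i in seq_len(nv)) {
      cnt <- 0
      for (j in seq_len(nv)) {
        d <- max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)]))
        if (d <= r) cnt <- cnt + 1
      }
      tot <- tot + log(cnt / nv)
    }
    tot / nv
  }
  phi(m) - phi(m + 1)
}

oracle_samen <- function(x, m = 2, rf = 0.15) {
  N <- length(x)
  r <- rf * sd(x)
  count <- function(mm) {
    nv <- N - m
    cnt <- 0
    for (i in seq_len(nv - 1)) {
      for (j in (i + 1):nv) {
        d <- max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)]))
        if (d <= r) cnt <- cnt + 1
      }
    }
    cnt
  }
  B <- count(m); A <- count(m + 1)
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

oracle_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) {
    for (q in neg) {
      if (p > q) s <- s + 1
      else if (p == q) s <- s + 0.5
    }
  }
  s / (length(pos) * length(neg))
}

# Dominant periodogram frequency (Hz) of a uniformly sampled signal.
oracle_peak_freq <- function(x, fs) {
  x <- x - mean(x)
  P <- Mod(stats::fft(x))^2
  n <- length(x)
  k <- which.max(P[2:(n %/% 2)])
  k * fs / n
}

# Power (arbitrary units) near frequency f0, summed over +-1 bin.
oracle_band_power <- function(x, fs, f0) {
  x <- x - mean(x)
  P <- Mod(stats::fft(x))^2
  n <- length(x)
  k <- round(f0 * n / fs) + 1
  sum(P[max(2, k - 1):min(n %/% 2, k + 1)])
}
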