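# Naive, loop-based reference implementations used as independent oracles.
# Deliberately written without reusing any production code path.

naive_td <- function(x, dz, ds, dw) {
  N <- length(x)
  xbar <- sum(x) / N
  sdv <- sqrt(sum((x - xbar)^2) / (N - 1))
  ske <- 0; kur <- 0
  if (sdv > 0) {
    for (i in 1:N) ske <- ske + (x[i] - xbar)^3
    for (i in 1:N) kur <- kur + (x[i] - xbar)^4
    ske <- ske / (N * sdv^3); kur <- kur / (N * sdv^4)
  }
  wl <- 0; for (i in 1:(N - 1)) wl <- wl + abs(x[i + 1] - x[i])
  zc <- 0
  for (i in 1:(N - 1))
    if (x[i] * x[i + 1] < 0 && abs(x[i] - x[i + 1]) > dz) zc <- zc + 1
  ssc <- 0
  for (i in 2:(N - 1))
    if ((x[i] - x[i - 1]) * (x[i] - x[i + 1]) > 0 &&
        abs(x[i] - x[i + 1]) > ds && abs(x[i] - x[i - 1]) > ds)
      ssc <- ssc + 1
  wamp <- 0
  for (i in 1:(N - 1)) if (abs(x[i + 1] - x[i]) > dw) wamp <- wamp + 1
  mmav <- 0
  for (i in 1:N) if (i >= 0.25 * N && i <= 0.75 * N) mmav <- mmav + abs(x[i])
  c(MV = xbar, SD = sdv, VAR = sdv^2, RMS = sqrt(sum(x^2) / N),
    SKE = ske, KUR = kur,
    IQR = unname(diff(quantile(x, c(0.25, 0.75)))),
    P2P = max(x) - min(x), MAV = sum(abs(x)) / N, WL = wl, ZC = zc,
    SSC = ssc, WAMP = wamp, LD = exp(sum(log(abs(x))) / N),
    Energy = sum(abs(x)^2) / N, MMAV = mmav / N)
}

naive_burg <- function(x, p) {
  x <- x - mean(x)
  N <- length(x)
  f <- x; b <- x; a <- numeric(0)
  for (m in 1:p) {
    idx <- (m + 1):N
    k <- 2 * sum(f[idx] * b[idx - 1]) /
      (sum(f[idx]^2) + sum(b[idx - 1]^2))
    f2 <- f; b2 <- b
    f2[idx] <- f[idx] - k * b[idx - 1]
    b2[idx] <- b[idx - 1] - k * f[idx]
    f <- f2; b <- b2
    a <- c(a - k * rev(a), k)
  }
  a
}

# direct DFT (no fft), one-sided magnitudes, DC excluded
naive_fd <- function(x, rate) {
  N <- length(x)
  ks <- 1:floor(N / 2)
  m <- vapply(ks, function(k) {
    re <- sum(x * cos(-2 * pi * k * (0:(N - 1)) / N))
    im <- sum(x * sin(-2 * pi * k * (0:(N - 1)) / N))
    sqrt(re^2 + im^2)
  }, 0)
  freq <- ks * rate / N
  pw <- m^2; tot <- sum(pw)
  cum <- cumsum(pw)
  ph <- pw / tot
  c(MPF = sum(pw * freq) / tot,
    MDF = freq[which(cum >= tot / 2)[1]],
    F25 = freq[which(cum >= tot / 4)[1]],
    F75 = freq[which(cum >= 3 * tot / 4)[1]],
    Entropy = -sum(ifelse(ph > 0, ph * log(ph), 0)),
    LVD1 = sort(m, decreasing = TRUE)[1],
    LVD2 = sort(m, decreasing = TRUE)[2],
    LVD3 = sort(m, decreasing = TRUE)[3])
}

# brute-force two-loop Fisher Index
brute_fisher <- function(x, y) {
  y <- as.factor(y)
  K <- nlevels(y); n <- length(y)
  vapply(seq_len(ncol(x)), function(j) {
    ms <- numeric(K); ps <- numeric(K)
    for (k in 1:K) {
      xi <- x[y == levels(y)[k], j]
      ms[k] <- mean(xi); ps[k] <- length(xi) / n
    }
    m_all <- sum(ps * ms)
    sb <- 0; sw <- 0
    for (k in 1:K) {
      xi <- x[y == levels(y)[k], j]
      sb <- sb + ps[k] * (ms[k] - m_all)^2
      sw <- sw + ps[k] * mean((xi - ms[k])^2)
    }
    sb / sw
  }, 0)
}
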