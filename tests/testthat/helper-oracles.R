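# Independent brute-force oracles, written as literal formula evaluations
# (explicit loops, O(n^2) DFTs) so they share no code path with the package.

oracle_stat_features <- function(x, fs) {
  n <- length(x)
  m <- 0
  for (v in x) m <- m + v
  m <- m / n
  ss <- 0
  for (v in x) ss <- ss + (v - m)^2
  s <- sqrt(ss / n)
  xs <- sort(x)
  med <- if (n %% 2 == 0) (xs[n / 2] + xs[n / 2 + 1]) / 2 else xs[(n + 1) / 2]
  mad <- 0
  for (v in x) mad <- mad + abs(v - m)
  mad <- mad / n
  rank_quartile <- function(p) {
    r <- (n + 1) * p
    lo <- floor(r)
    if (lo < 1) return(xs[1])
    if (lo >= n) return(xs[n])
    xs[lo] + (r - lo) * (xs[lo + 1] - xs[lo])
  }
  q1 <- rank_quartile(1 / 4)
  q3 <- rank_quartile(3 / 4)
  skew <- 0; kurt <- 0
  for (v in x) {
    skew <- skew + ((v - m) / s)^3
    kurt <- kurt + ((v - m) / s)^4
  }
  skew <- skew / n; kurt <- kurt / n
  tot <- sum(abs(x))
  sh <- 0
  for (v in x) {
    p <- abs(v) / tot
    if (p > 0) sh <- sh - p * log(p)
  }
  # one-sided DFT by direct summation
  n_half <- n %/% 2 + 1
  mag <- numeric(n_half)
  for (k in seq_len(n_half)) {
    acc <- 0 + 0i
    for (i in seq_len(n)) {
      acc <- acc + x[i] * exp(-2i * pi * (k - 1) * (i - 1) / n)
    }
    mag[k] <- Mod(acc)
  }
  pw <- mag^2
  sp <- 0
  for (v in pw) {
    p <- v / sum(pw)
    if (p > 0) sp <- sp - p * log(p)
  }
  kmax <- which.max(mag)
  c(mean = m, median = med, std = s, mad = mad, q1 = q1, q3 = q3,
    iqr = q3 - q1, skewness = skew, kurtosis = kurt,
    shannon_entropy = sh, spectral_entropy = sp,
    max_freq_hz = (kmax - 1) * fs / n, max_spectrum = mag[kmax],
    max_freq_energy_ratio = pw[kmax] / sum(pw))
}

oracle_mfcc <- function(x, fs, n_filters = 26, n_coeffs = 13,
                        frame_ms = 25, hop_ms = 10) {
  frame_n <- round(frame_ms * fs / 1000)
  hop_n <- round(hop_ms * fs / 1000)
  nfft <- 2^ceiling(log2(frame_n))
  w <- numeric(frame_n)
  for (i in seq_len(frame_n)) {
    w[i] <- 0.54 - 0.46 * cos(2 * pi * (i - 1) / (frame_n - 1))
  }
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(mm) 700 * (10^(mm / 2595) - 1)
  pts <- imel(seq(0, mel(fs / 2), length.out = n_filters + 2))
  n_bins <- nfft / 2 + 1
  H <- matrix(0, n_filters, n_bins)
  for (m in seq_len(n_filters)) {
    for (b in seq_len(n_bins)) {
      f <- (b - 1) * fs / nfft
      if (f >= pts[m] && f <= pts[m + 1]) {
        H[m, b] <- (f - pts[m]) / (pts[m + 1] - pts[m])
      } else if (f > pts[m + 1] && f <= pts[m + 2]) {
        H[m, b] <- (pts[m + 2] - f) / (pts[m + 2] - pts[m + 1])
      }
    }
  }
  n_frames <- (length(x) - frame_n) %/% hop_n + 1
  coefs <- matrix(0, n_coeffs, n_frames)
  for (j in seq_len(n_frames)) {
    seg <- x[((j - 1) * hop_n + 1):((j - 1) * hop_n + frame_n)] * w
    X <- stats::fft(c(seg, rep(0, nfft - frame_n)))[seq_len(n_bins)]
    P <- Mod(X)^2 / nfft
    E <- numeric(n_filters)
    for (m in seq_len(n_filters)) E[m] <- max(sum(H[m, ] * P), .Machine$double.eps)
    logE <- log(E)
    for (k in 0:(n_coeffs - 1)) {
      ck <- 0
      for (m in seq_len(n_filters)) {
        ck <- ck + logE[m] * cos(pi * k * (m - 0.5) / n_filters)
      }
      ck <- ck * sqrt(2 / n_filters)
      if (k == 0) ck <- ck / sqrt(2)
      coefs[k + 1, j] <- ck
    }
  }
  rowMeans(coefs)
}

oracle_interval_features <- function(s1, s2) {
  n <- min(length(s1), length(s2))
  sys <- numeric(n)
  for (i in seq_len(n)) sys[i] <- abs(s1[i] - s2[i])
  dia <- numeric(n - 1)
  for (i in seq_len(n - 1)) dia[i] <- abs(s2[i] - s1[i + 1])
  t12 <- sum(sys) / n
  t21 <- sum(dia) / (n - 1)
  sd12 <- sqrt(sum((sys - t12)^2) / n)
  sd21 <- sqrt(sum((dia - t21)^2) / (n - 1))
  c(t12, t21, sd12, sd21)
}

# build a peak list directly from times/amps (for rule-level tests)
mk_peaks <- function(times_ms, amps, threshold = 0.3) {
  pcglstf:::peaklist(times_ms, amps, threshold)
}

mk_env <- function(values, hop_ms = 10) {
  structure(list(values = values, times_ms = (seq_along(values) - 1) * hop_ms,
                 rate_hz = 1000 / hop_ms),
            class = "pcg_envelope")
}
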