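#' Names of the 27 short-term features
#'
#' Fixed order: 14 time/statistics/energy/frequency features followed by 13
#' mel-frequency cepstral coefficients.
#'
#' @return Character vector of length 27.
#' @export
short_term_feature_names <- function() {
  c("mean", "median", "std", "mad", "q1", "q3", "iqr", "skewness",
    "kurtosis", "shannon_entropy", "spectral_entropy", "max_freq_hz",
    "max_spectrum", "max_freq_energy_ratio",
    paste0("mfcc_", 1:13))
}

#' Statistical, energy and frequency features of a fragment
#'
#' Computes the 14 scalar descriptors of a five-second fragment. Moments use
#' population (divide-by-N) conventions; quartiles use the (n+1)/4 rank rule
#' with linear interpolation; `mad` is the mean absolute deviation from the
#' mean. Shannon entropy is the entropy (natural log) of the normalized
#' absolute-amplitude distribution \eqn{p_i = |x_i| / \sum_j |x_j|}; spectral
#' entropy applies the same formula to the normalized one-sided power
#' spectrum. The three frequency features are the argmax frequency of the
#' one-sided FFT magnitude (Hz), that maximum magnitude, and the ratio of the
#' power in that bin to the total one-sided power.
#'
#' @param frag A `pcg_fragment` (or bare numeric vector with `fs` given).
#' @param fs Sampling rate, used when `frag` is a bare vector.
#' @return Named numeric vector of length 14. For a constant fragment the
#'   standard deviation is 0 and skewness/kurtosis are returned as 0 with a
#'   warning.
#' @export
stat_features <- function(frag, fs = NULL) {
  x <- fragment_samples(frag)
  if (is.null(fs)) fs <- fragment_fs(frag)
  n <- length(x)
  stopifnot(n >= 4L)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))               # population sd
  if (s == 0) {
    warning("constant fragment: skewness and kurtosis set to 0")
    skew <- 0; kurt <- 0
  } else {
    skew <- mean(((x - m) / s)^3)
    kurt <- mean(((x - m) / s)^4)          # non-excess
  }
  q1 <- quartile_rank(x, 0.25)
  q3 <- quartile_rank(x, 0.75)

  abs_x <- abs(x)
  tot <- sum(abs_x)
  sh_ent <- if (tot > 0) {
    p <- abs_x[abs_x > 0] / tot
    -sum(p * log(p))
  } else 0

  spec <- one_sided_spectrum(x, fs)
  pw <- spec$magnitude^2
  tot_pw <- sum(pw)
  sp_ent <- if (tot_pw > 0) {
    p <- pw[pw > 0] / tot_pw
    -sum(p * log(p))
  } else 0
  k <- which.max(spec$magnitude)
  c(mean = m, median = stats::median(x), std = s, mad = mean(abs(x - m)),
    q1 = q1, q3 = q3, iqr = q3 - q1, skewness = skew, kurtosis = kurt,
    shannon_entropy = sh_ent, spectral_entropy = sp_ent,
    max_freq_hz = spec$freq_hz[k], max_spectrum = spec$magnitude[k],
    max_freq_energy_ratio = if (tot_pw > 0) pw[k] / tot_pw else 0)
}

# (n+1)p rank rule with linear interpolation between order statistics
quartile_rank <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  r <- (n + 1) * p
  lo <- floor(r)
  if (lo < 1) return(xs[1])
  if (lo >= n) return(xs[n])
  xs[lo] + (r - lo) * (xs[lo + 1] - xs[lo])
}

one_sided_spectrum <- function(x, fs) {
  n <- length(x)
  X <- stats::fft(x)
  half <- seq_len(n %/% 2 + 1L)
  list(freq_hz = (half - 1) * fs / n, magnitude = abs(X[half]))
}

#' Mel-frequency cepstral coefficients of a fragment
#'
#' Per frame: Hamming window, periodogram power spectrum, a bank of
#' `n_filters` triangular mel filters spanning 0 to fs/2, log filter
#' energies (floored to avoid log of zero), then an orthonormal DCT-II. The
#' first `n_coeffs` coefficients (including the 0th-order term as `mfcc_1`)
#' are kept; the fragment value of each coefficient is its mean over frames.
#'
#' @param frag A `pcg_fragment` or numeric vector.
#' @param fs Sampling rate when `frag` is a bare vector.
#' @param n_filters Number of mel filters.
#' @param n_coeffs Number of cepstral coefficients retained.
#' @param frame_ms,hop_ms Analysis frame length and hop in ms.
#' @return Named numeric vector `mfcc_1` .. `mfcc_<n_coeffs>`.
#' @export
mfcc_features <- function(frag, fs = NULL, n_filters = 26, n_coeffs = 13,
                          frame_ms = 25, hop_ms = 10) {
  x <- fragment_samples(frag)
  if (is.null(fs)) fs <- fragment_fs(frag)
  frame_n <- round(frame_ms * fs / 1000)
  hop_n <- max(1L, round(hop_ms * fs / 1000))
  stopifnot(length(x) >= frame_n)
  if (all(x == 0)) warning("all-zero fragment: MFCCs computed on floored log energies")
  nfft <- 2^ceiling(log2(frame_n))
  n_frames <- (length(x) - frame_n) %/% hop_n + 1L
  starts <- (seq_len(n_frames) - 1L) * hop_n
  idx <- outer(seq_len(frame_n), starts, `+`)    # frame_n x n_frames
  frames <- matrix(x[idx], nrow = frame_n)
  w <- hamming_window(frame_n)
  frames <- frames * w
  padded <- rbind(frames, matrix(0, nfft - frame_n, n_frames))
  spec <- stats::mvfft(padded)[seq_len(nfft %/% 2 + 1L), , drop = FALSE]
  power <- (Mod(spec)^2) / nfft                   # periodogram, nfft/2+1 x frames
  fb <- mel_filterbank(n_filters, nfft, fs)       # n_filters x (nfft/2+1)
  energies <- fb %*% power                        # n_filters x n_frames
  log_e <- log(pmax(energies, mfcc_log_floor))
  dct <- dct_matrix(n_coeffs, n_filters)          # orthonormal DCT-II rows 0..n_coeffs-1
  coeffs <- dct %*% log_e                         # n_coeffs x n_frames
  stats::setNames(rowMeans(coeffs), paste0("mfcc_", seq_len(n_coeffs)))
}

mfcc_log_floor <- .Machine$double.eps

hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular mel filter bank
#'
#' `n_filters` triangular filters with centers equally spaced on the mel
#' scale between 0 Hz and fs/2, evaluated at the nfft/2 + 1 one-sided FFT bin
#' frequencies.
#'
#' @param n_filters Number of filters.
#' @param nfft FFT length the filters will be applied to.
#' @param fs Sampling rate in Hz.
#' @return Matrix `n_filters` x `(nfft/2 + 1)`.
#' @export
mel_filterbank <- function(n_filters, nfft, fs) {
  mel_pts <- seq(hz_to_mel(0), hz_to_mel(fs / 2), length.out = n_filters + 2L)
  hz_pts <- mel_to_hz(mel_pts)
  bin_freq <- (seq_len(nfft %/% 2 + 1L) - 1) * fs / nfft
  fb <- matrix(0, n_filters, length(bin_freq))
  for (m in seq_len(n_filters)) {
    lo <- hz_pts[m]; mid <- hz_pts[m + 1L]; hi <- hz_pts[m + 2L]
    up <- bin_freq >= lo & bin_freq <= mid
    down <- bin_freq > mid & bin_freq <= hi
    fb[m, up] <- (bin_freq[up] - lo) / (mid - lo)
    fb[m, down] <- (hi - bin_freq[down]) / (hi - mid)
  }
  fb
}

# orthonormal DCT-II, rows k = 0 .. n_out-1 over n_in points
dct_matrix <- function(n_out, n_in) {
  k <- seq_len(n_out) - 1L
  j <- seq_len(n_in) - 1L
  mat <- sqrt(2 / n_in) * cos(outer(k, j, function(k, j) pi * k * (j + 0.5) / n_in))
  mat[1, ] <- mat[1, ] / sqrt(2)
  mat
}

#' Full 27-dimensional short-term feature vector
#'
#' Concatenates [stat_features()] and [mfcc_features()] in the fixed order
#' given by [short_term_feature_names()].
#'
#' @param frag A `pcg_fragment` (or numeric vector with `fs`).
#' @param fs Sampling rate when `frag` is a bare vector.
#' @param config A [pcg_config()]; its `$short_term` block supplies the MFCC
#'   frame/hop/filter settings.
#' @return Named numeric vector of length 27.
#' @export
short_term_vector <- function(frag, fs = NULL, config = pcg_config()) {
  st <- config$short_term
  out <- c(stat_features(frag, fs = fs),
           mfcc_features(frag, fs = fs,
                         n_filters = st$n_filters, n_coeffs = st$n_coeffs,
                         frame_ms = st$frame_ms, hop_ms = st$hop_ms))
  stats::setNames(out, short_term_feature_names())
}

fragment_samples <- function(frag) {
  if (inherits(frag, "pcg_fragment")) frag$samples else as.numeric(frag)
}

fragment_fs <- function(frag) {
  if (inherits(frag, "pcg_fragment")) frag$fs
  else stop("fs must be supplied when the fragment is a bare numeric vector")
}
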