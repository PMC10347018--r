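#' Names of the 6 long-term features
#' @return Character vector of length 6.
#' @export
long_term_feature_names <- function() {
  c("t12_mean_ms", "t21_mean_ms", "sd12_ms", "sd21_ms",
    "retained_peak_ratio", "retained_amp_ratio")
}

#' Systolic/diastolic interval statistics
#'
#' From the S1/S2 event times of a segmentation: the mean systolic interval
#' T12 (S1 to the paired S2), the mean diastolic interval T21 (S2 to the
#' next S1, one fewer term), and the population standard deviations SD12 and
#' SD21 of the two interval sets. All values in ms.
#'
#' @param seg A `pcg_segmentation` with at least 2 full cycles.
#' @return Named numeric vector `t12_mean_ms`, `t21_mean_ms`, `sd12_ms`,
#'   `sd21_ms`.
#' @export
interval_features <- function(seg) {
  s1 <- seg$s1_times_ms
  s2 <- seg$s2_times_ms
  n <- min(length(s1), length(s2))
  if (n < 2L) {
    stop("insufficient cycles: need at least 2 S1-S2 pairs, got ", n)
  }
  sys <- abs(s2[seq_len(n)] - s1[seq_len(n)])
  dia <- abs(s1[seq_len(n)][-1] - s2[seq_len(n)][-n])
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  c(t12_mean_ms = mean(sys), t21_mean_ms = mean(dia),
    sd12_ms = pop_sd(sys), sd21_ms = pop_sd(dia))
}

#' Peak-rejection bookkeeping features
#'
#' The fraction of candidate peaks that survive extra-peak rejection, and the
#' ratio of the mean envelope amplitude of retained peaks to that of all
#' candidates. Clean recordings reject few peaks (ratios near 1); noisy ones
#' reject many small spurious peaks (count ratio drops, amplitude ratio
#' rises above 1).
#'
#' @param seg A `pcg_segmentation`.
#' @return Named numeric vector `retained_peak_ratio`, `retained_amp_ratio`.
#' @export
rejection_features <- function(seg) {
  if (seg$n_candidates < 1L) stop("segmentation has zero candidate peaks")
  c(retained_peak_ratio = seg$n_retained / seg$n_candidates,
    retained_amp_ratio = seg$mean_amp_retained / seg$mean_amp_candidates)
}

#' Full 6-dimensional long-term feature vector
#'
#' Long-term features describe the whole recording; the same vector is later
#' appended to every fragment extracted from it.
#'
#' @param seg A `pcg_segmentation` (see [segment_recording()]).
#' @return Named numeric vector of length 6 in the order of
#'   [long_term_feature_names()].
#' @export
long_term_vector <- function(seg) {
  out <- c(interval_features(seg), rejection_features(seg))
  stats::setNames(out, long_term_feature_names())
}
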