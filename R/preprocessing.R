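#' Zero-phase low-pass filtering
#'
#' Fundamental heart sounds and murmurs live below a few hundred Hz; ambient
#' and organ noise is removed with a Butterworth low-pass applied
#' forward-backward ([signal::filtfilt()]) so that envelope peak times are not
#' shifted by filter delay.
#'
#' @param rec A [pcg_recording()].
#' @param cutoff Cutoff frequency in Hz; must be below Nyquist.
#' @param order Butterworth order (doubled in effect by the two passes).
#' @return The filtered recording (same length, same fs).
#' @export
lowpass_filter <- function(rec, cutoff = 400, order = 4) {
  if (cutoff <= 0 || cutoff >= rec$fs / 2) {
    stop("cutoff must lie in (0, fs/2) = (0, ", rec$fs / 2, ")")
  }
  bf <- signal::butter(order, cutoff / (rec$fs / 2), type = "low")
  y <- signal::filtfilt(bf, rec$samples)
  pcg_recording(y, rec$fs, id = rec$id, label = rec$label,
                source_path = rec$source_path)
}

#' Normalized average Shannon energy envelope
#'
#' The amplitude is first normalized by the recording's maximum absolute
#' value, then the average Shannon energy \eqn{-\frac{1}{M}\sum x^2 \log x^2}
#' is computed over sliding frames. Shannon energy emphasises medium-intensity
#' components, which makes the soft S2 comparable to the louder S1 — the
#' standard choice for fundamental-heart-sound gating.
#'
#' @param rec A [pcg_recording()] (ideally low-pass filtered first).
#' @param frame_ms Frame length in ms.
#' @param hop_ms Hop between frame starts in ms; must not exceed `frame_ms`.
#' @return An object of class `pcg_envelope`: list with `values`
#'   (non-negative), `times_ms` (frame centers) and `rate_hz` (1000/hop_ms).
#' @export
compute_envelope <- function(rec, frame_ms = 20, hop_ms = 10) {
  stopifnot(frame_ms >= hop_ms, hop_ms > 0)
  x <- rec$samples
  m <- max(abs(x))
  if (m > 0) x <- x / m
  frame_n <- max(2L, round(frame_ms * rec$fs / 1000))
  hop_n <- max(1L, round(hop_ms * rec$fs / 1000))
  n_frames <- max(0L, (length(x) - frame_n) %/% hop_n + 1L)
  if (n_frames == 0L) {
    return(structure(list(values = numeric(0), times_ms = numeric(0),
                          rate_hz = 1000 / hop_ms), class = "pcg_envelope"))
  }
  x2 <- x^2
  se <- ifelse(x2 > 0, -x2 * log(x2), 0)   # 0 log 0 := 0
  cs <- c(0, cumsum(se))
  starts <- (seq_len(n_frames) - 1L) * hop_n
  vals <- (cs[starts + frame_n + 1L] - cs[starts + 1L]) / frame_n
  structure(
    list(values = vals,
         times_ms = (starts + frame_n / 2) * 1000 / rec$fs,
         rate_hz = 1000 / hop_ms),
    class = "pcg_envelope"
  )
}

#' Detect candidate envelope peaks above a relative threshold
#'
#' All local maxima of the envelope whose value reaches `threshold_frac`
#' times the envelope maximum are returned as candidate S1/S2 locations; the
#' relative threshold makes detection invariant to recording gain.
#'
#' @param env A `pcg_envelope` (or a bare non-negative numeric vector, taken
#'   at `rate_hz` = 100).
#' @param threshold_frac Fraction of the envelope maximum (default 0.3).
#' @return A `pcg_peaklist`: `times_ms`, `amplitudes`, `threshold` (absolute).
#' @export
detect_candidate_peaks <- function(env, threshold_frac = 0.3) {
  if (is.numeric(env)) {
    env <- structure(list(values = env,
                          times_ms = (seq_along(env) - 1) * 10, rate_hz = 100),
                     class = "pcg_envelope")
  }
  v <- env$values
  if (length(v) == 0L || max(v) <= 0) stop("no peaks: envelope is empty or flat zero")
  thr <- threshold_frac * max(v)
  idx <- local_maxima(v)
  idx <- idx[v[idx] >= thr]
  if (length(idx) == 0L) stop("no peaks: no local maxima reach the threshold")
  peaklist(env$times_ms[idx], v[idx], thr)
}

# indices of local maxima; plateaus contribute their first sample
local_maxima <- function(v) {
  n <- length(v)
  if (n < 2L) return(if (n == 1L) 1L else integer(0))
  d <- diff(v)
  rising <- c(d[1] > 0, d > 0)       # v[i] > v[i-1] (plateau: carries forward)
  # carry the last non-zero slope through plateaus
  s <- sign(d)
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  up_then_down <- which(s[-1] < 0 & s[-length(s)] > 0) + 1L
  ends <- integer(0)
  if (all(s <= 0) && n >= 1L) ends <- 1L         # monotone falling: first point
  out <- sort(unique(c(up_then_down, ends)))
  if (length(out) == 0L) {
    # monotone rising or flat: max at the end
    out <- if (v[n] >= v[1]) n else 1L
  }
  out
}

peaklist <- function(times_ms, amplitudes, threshold) {
  o <- order(times_ms)
  structure(list(times_ms = as.numeric(times_ms[o]),
                 amplitudes = as.numeric(amplitudes[o]),
                 threshold = threshold),
            class = "pcg_peaklist")
}

#' @export
print.pcg_peaklist <- function(x, ...) {
  cat(sprintf("<pcg_peaklist: %d peaks, threshold %.4g>\n",
              length(x$times_ms), x$threshold))
  invisible(x)
}

#' Extra-peak rejection
#'
#' Cleans a candidate peak list so that only one S1 and one S2 survive per
#' cardiac cycle, by scanning left to right until stable:
#' \itemize{
#'   \item peaks closer than `min_gap_ms` (50 ms): the smaller-amplitude peak
#'     is rejected;
#'   \item more than two peaks inside one `min_cycle_ms` (400 ms) span — i.e.
#'     more events than a cycle's S1+S2 can account for: the smallest of the
#'     cluster is rejected;
#'   \item a gap longer than `max_cycle_ms` (1500 ms) between consecutive
#'     peaks means genuine heart sounds fell below the threshold: the
#'     threshold is lowered over that gap only (multiplied by
#'     `refine_factor` per attempt, floored at `floor_frac` of the envelope
#'     maximum) and detection plus the rules above are re-run. This step
#'     requires `env`; without it long gaps are left untouched with a
#'     warning.
#' }
#' The physiological basis is that a cardiac cycle lasts 400-1500 ms (40-140
#' beats per minute), so its two fundamental sounds can never be closer than
#' 50 ms nor farther apart than 1500 ms.
#'
#' @param peaks A `pcg_peaklist` from [detect_candidate_peaks()].
#' @param env The envelope, needed only for threshold refinement on long gaps.
#' @param min_gap_ms,min_cycle_ms,max_cycle_ms Rule windows in ms.
#' @param refine_factor Per-iteration multiplier on the local threshold.
#' @param floor_frac Lowest allowed local threshold as a fraction of the
#'   envelope maximum.
#' @return A stable `pcg_peaklist`; consecutive peaks are never closer than
#'   `min_gap_ms`. Re-applying the function to its own output is a no-op.
#' @export
reject_extra_peaks <- function(peaks, env = NULL, min_gap_ms = 50,
                               min_cycle_ms = 400, max_cycle_ms = 1500,
                               refine_factor = 0.8, floor_frac = 0.05) {
  t <- peaks$times_ms
  a <- peaks$amplitudes
  res <- apply_rejection_rules(t, a, min_gap_ms, min_cycle_ms)
  if (!is.null(env)) {
    env_max <- max(env$values)
    guard <- 0L
    repeat {
      gaps <- which(diff(res$t) > max_cycle_ms)
      if (length(gaps) == 0L || guard > 50L) break
      guard <- guard + 1L
      changed <- FALSE
      for (g in gaps) {
        lo <- res$t[g]; hi <- res$t[g + 1L]
        local_thr <- peaks$threshold
        found <- NULL
        while (local_thr * refine_factor >= floor_frac * env_max) {
          local_thr <- local_thr * refine_factor
          inside <- env$times_ms > lo & env$times_ms < hi
          idx <- local_maxima(env$values)
          idx <- idx[inside[idx] & env$values[idx] >= local_thr]
          if (length(idx)) { found <- idx; break }
        }
        if (is.null(found)) {
          stop("segmentation failure: gap of ", round(hi - lo),
               " ms between ", round(lo), " and ", round(hi),
               " ms could not be filled at the threshold floor")
        }
        res <- apply_rejection_rules(c(res$t, env$times_ms[found]),
                                     c(res$a, env$values[found]),
                                     min_gap_ms, min_cycle_ms, presorted = FALSE)
        changed <- TRUE
      }
      if (!changed) break
    }
  } else if (any(diff(res$t) > max_cycle_ms)) {
    warning("inter-peak gap exceeds ", max_cycle_ms,
            " ms but no envelope was supplied for threshold refinement")
  }
  peaklist(res$t, res$a, peaks$threshold)
}

apply_rejection_rules <- function(t, a, min_gap_ms, min_cycle_ms,
                                  presorted = TRUE) {
  if (!presorted) { o <- order(t); t <- t[o]; a <- a[o] }
  repeat {
    n <- length(t)
    if (n < 2L) break
    changed <- FALSE
    # rule (a): neighbours closer than min_gap -> drop the smaller
    gaps <- diff(t)
    i <- which(gaps < min_gap_ms)
    if (length(i)) {
      i <- i[1]
      drop <- if (a[i] < a[i + 1L]) i else i + 1L
      t <- t[-drop]; a <- a[-drop]
      changed <- TRUE
    } else if (n >= 3L) {
      # rule (b): >2 peaks inside one min_cycle span -> drop the smallest
      span <- t[seq(3L, n)] - t[seq(1L, n - 2L)]
      j <- which(span < min_cycle_ms)
      if (length(j)) {
        j <- j[1]
        trio <- j:(j + 2L)
        drop <- trio[which.min(a[trio])]
        t <- t[-drop]; a <- a[-drop]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(t = t, a = a)
}

#' Assign S1/S2 identities to retained peaks
#'
#' Retained peaks alternate S1, S2, S1, ... in one of two parities. The
#' physiological prior that systole (S1 to S2) is shorter than diastole (S2 to
#' the next S1) picks the parity: the labelling whose S1-to-S2 intervals have
#' the smaller mean is chosen. On an exact tie the first peak is taken as S1
#' with a warning.
#'
#' @param peaks Retained peaks (a `pcg_peaklist`), at least 4.
#' @param candidates The pre-rejection candidate list, used for the
#'   retained/candidate count and amplitude bookkeeping; defaults to `peaks`.
#' @return A `pcg_segmentation`: `s1_times_ms`, `s2_times_ms`,
#'   `n_candidates`, `n_retained`, `mean_amp_candidates`, `mean_amp_retained`.
#' @export
label_s1_s2 <- function(peaks, candidates = peaks) {
  t <- peaks$times_ms
  if (length(t) < 4L) {
    stop("insufficient peaks: need at least 4 retained peaks, got ", length(t))
  }
  gaps <- diff(t)
  odd <- seq(1L, length(gaps), by = 2L)    # intervals opened by peaks 1,3,5,...
  even <- seq(2L, length(gaps), by = 2L)   # intervals opened by peaks 2,4,6,...
  mean_odd <- mean(gaps[odd])
  mean_even <- mean(gaps[even])
  if (isTRUE(all.equal(mean_odd, mean_even))) {
    warning("systolic/diastolic parity tie; taking the first peak as S1")
    first_s1 <- 1L
  } else {
    first_s1 <- if (mean_odd < mean_even) 1L else 2L
  }
  s1_idx <- seq(first_s1, length(t), by = 2L)
  s2_idx <- seq(first_s1 + 1L, length(t), by = 2L)
  structure(
    list(s1_times_ms = t[s1_idx],
         s2_times_ms = t[s2_idx],
         n_candidates = length(candidates$times_ms),
         n_retained = length(t),
         mean_amp_candidates = mean(candidates$amplitudes),
         mean_amp_retained = mean(peaks$amplitudes)),
    class = "pcg_segmentation"
  )
}

#' @export
print.pcg_segmentation <- function(x, ...) {
  cat(sprintf("<pcg_segmentation: %d S1, %d S2 (%d/%d peaks retained)>\n",
              length(x$s1_times_ms), length(x$s2_times_ms),
              x$n_retained, x$n_candidates))
  invisible(x)
}

#' Segment a recording into S1/S2 events
#'
#' Convenience wrapper running the full pre-processing chain: low-pass
#' filter, Shannon-energy envelope, threshold peak detection, extra-peak
#' rejection (with threshold refinement) and S1/S2 parity labelling.
#'
#' @param rec A [pcg_recording()].
#' @param config A [pcg_config()] (or its `$preprocessing` sub-list defaults).
#' @return A `pcg_segmentation`.
#' @export
segment_recording <- function(rec, config = pcg_config()) {
  p <- config$preprocessing
  filt <- lowpass_filter(rec, cutoff = p$cutoff_hz, order = p$filter_order)
  env <- compute_envelope(filt, frame_ms = p$frame_ms, hop_ms = p$hop_ms)
  cand <- detect_candidate_peaks(env, threshold_frac = p$threshold_frac)
  kept <- reject_extra_peaks(cand, env = env, min_gap_ms = p$min_gap_ms,
                             min_cycle_ms = p$min_cycle_ms,
                             max_cycle_ms = p$max_cycle_ms,
                             refine_factor = p$refine_factor,
                             floor_frac = p$floor_frac)
  all_cand <- merge_peaklists(cand, kept)
  label_s1_s2(kept, candidates = all_cand)
}

# candidates = initial detections plus any peaks surfaced by refinement,
# so retained/candidate ratios stay within (0, 1]
merge_peaklists <- function(cand, kept) {
  extra <- !(kept$times_ms %in% cand$times_ms)
  peaklist(c(cand$times_ms, kept$times_ms[extra]),
           c(cand$amplitudes, kept$amplitudes[extra]),
           cand$threshold)
}

#' Write S1/S2 annotations as TSV
#'
#' @param seg A `pcg_segmentation`.
#' @param recording_id Id written in the first column.
#' @param path Output path. Columns: `recording_id`, `time_ms`, `label`.
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(seg, recording_id, path) {
  df <- data.frame(
    recording_id = recording_id,
    time_ms = c(seg$s1_times_ms, seg$s2_times_ms),
    label = rep(c("S1", "S2"), c(length(seg$s1_times_ms), length(seg$s2_times_ms)))
  )
  df <- df[order(df$time_ms), ]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a recording into fixed-length fragments
#'
#' Non-overlapping, contiguous five-second windows from t = 0; a trailing
#' remainder shorter than the window is discarded. Each fragment inherits the
#' recording's label — the working assumption of fragment-level
#' classification is that every window of an abnormal recording is abnormal.
#'
#' @param rec A [pcg_recording()].
#' @param window_s Window length in seconds.
#' @return List of `pcg_fragment` objects (`recording_id`, `index` 0-based,
#'   `samples`, `fs`, `label`). Empty list with a warning if the recording is
#'   shorter than one window.
#' @export
fragment_recording <- function(rec, window_s = 5) {
  win_n <- round(window_s * rec$fs)
  n_frag <- length(rec$samples) %/% win_n
  if (n_frag == 0L) {
    warning("recording '", rec$id, "' is shorter than ", window_s,
            " s; no fragments produced")
    return(list())
  }
  lapply(seq_len(n_frag) - 1L, function(k) {
    structure(
      list(recording_id = rec$id, index = k,
           samples = rec$samples[(k * win_n + 1L):((k + 1L) * win_n)],
           fs = rec$fs, label = rec$label),
      class = "pcg_fragment"
    )
  })
}
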