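test_that("low-pass filter passes the band and rejects above cutoff", {
  fs <- 2000
  t <- (0:3999) / fs
  mid <- 1000:3000   # ignore filter edge transients
  dc <- pcg_recording(rep(0.5, 4000), fs)
  expect_equal(lowpass_filter(dc, 400, 4)$samples[mid], dc$samples[mid],
               tolerance = 1e-6)
  tone50 <- pcg_recording(sin(2 * pi * 50 * t), fs)
  out50 <- lowpass_filter(tone50, 400, 4)$samples
  expect_equal(max(abs(out50[mid])), 1, tolerance = 0.01)
  tone900 <- pcg_recording(sin(2 * pi * 900 * t), fs)
  out900 <- lowpass_filter(tone900, 400, 4)$samples
  expect_lt(max(abs(out900[mid])), 0.1)
  expect_length(out50, 4000)
  expect_error(lowpass_filter(tone50, 1000, 4), "cutoff")
})

test_that("zero-phase filtering does not shift a burst's envelope peak", {
  fs <- 2000
  t_ms <- (0:3999) * 1000 / fs
  burst <- exp(-(t_ms - 1000)^2 / (2 * 20^2)) * sin(2 * pi * 60 * t_ms / 1000)
  rec <- pcg_recording(burst, fs)
  env_raw <- compute_envelope(rec)
  env_filt <- compute_envelope(lowpass_filter(rec, 400, 4))
  expect_equal(env_raw$times_ms[which.max(env_raw$values)],
               env_filt$times_ms[which.max(env_filt$values)],
               tolerance = 10)
})

test_that("Shannon envelope is non-negative, unimodal on a burst, zero on silence", {
  fs <- 2000
  silent <- pcg_recording(rep(0, 2000), fs)
  expect_true(all(compute_envelope(silent)$values == 0))
  t_ms <- (0:9999) * 1000 / fs
  center <- 2500
  burst <- exp(-(t_ms - center)^2 / (2 * 30^2)) * sin(2 * pi * 80 * t_ms / 1000)
  env <- compute_envelope(pcg_recording(burst, fs), frame_ms = 20, hop_ms = 10)
  expect_true(all(env$values >= 0))
  expect_equal(env$times_ms[which.max(env$values)], center, tolerance = 20)
  # scaling the signal leaves the max-normalized envelope unchanged
  env2 <- compute_envelope(pcg_recording(3 * burst, fs))
  expect_equal(env2$values, env$values, tolerance = 1e-10)
})

test_that("candidate peaks are local maxima above 30% of the envelope max", {
  tri <- function(height, half = 5) {
    height * pmax(0, 1 - abs(seq(-half, half)) / half)
  }
  env <- mk_env(c(tri(1.0), tri(0.4), tri(0.2)))
  pk <- detect_candidate_peaks(env, 0.3)
  expect_length(pk$times_ms, 2)
  expect_equal(sort(pk$amplitudes), c(0.4, 1.0))
  expect_equal(pk$threshold, 0.3)
  single <- detect_candidate_peaks(mk_env(tri(0.8)))
  expect_length(single$times_ms, 1)
  twins <- detect_candidate_peaks(mk_env(c(tri(1.0), tri(1.0))))
  expect_length(twins$times_ms, 2)
  expect_error(detect_candidate_peaks(mk_env(rep(0, 50))), "no peaks")
})

test_that("extra-peak rejection reproduces the worked rule examples", {
  # rule (a): 30 ms neighbour, smaller amplitude goes
  out <- reject_extra_peaks(mk_peaks(c(0, 30, 800), c(1.0, 0.5, 0.9)))
  expect_equal(out$times_ms, c(0, 800))
  expect_equal(out$amplitudes, c(1.0, 0.9))
  # rule (b): three peaks inside 400 ms, smallest of the cluster goes
  out <- reject_extra_peaks(mk_peaks(c(0, 300, 350, 800), c(1.0, 0.8, 0.3, 0.9)))
  expect_equal(out$times_ms, c(0, 300, 800))
  # no rule fires
  out <- reject_extra_peaks(mk_peaks(c(0, 700), c(1.0, 0.9)))
  expect_equal(out$times_ms, c(0, 700))
  expect_equal(out$amplitudes, c(1.0, 0.9))
})

test_that("rejection is idempotent and respects the 50 ms minimum gap", {
  set.seed(7)
  for (trial in 1:200) {
    n <- sample(2:40, 1)
    t <- sort(runif(n, 0, 10000))
    a <- runif(n, 0.05, 1)
    out <- suppressWarnings(reject_extra_peaks(mk_peaks(t, a)))
    if (length(out$times_ms) > 1) {
      expect_true(all(diff(out$times_ms) >= 50))
    }
    again <- suppressWarnings(reject_extra_peaks(out))
    expect_identical(again$times_ms, out$times_ms)
    expect_identical(again$amplitudes, out$amplitudes)
  }
})

test_that("threshold refinement recovers peaks lost in a long gap", {
  # three bursts; the middle one is below the 30% threshold, leaving a
  # >1500 ms gap that refinement must fill
  bump <- function(center_idx, height, v) {
    idx <- center_idx + seq(-3, 3)
    v[idx] <- pmax(v[idx], height * (1 - abs(seq(-3, 3)) / 4))
    v
  }
  v <- rep(0, 400)
  v <- bump(50, 1.0, v)    # t = 490 ms
  v <- bump(200, 0.2, v)   # t = 1990 ms, below 0.3 threshold
  v <- bump(350, 0.9, v)   # t = 3490 ms
  env <- mk_env(v)
  cand <- detect_candidate_peaks(env, 0.3)
  expect_length(cand$times_ms, 2)
  out <- reject_extra_peaks(cand, env = env)
  expect_length(out$times_ms, 3)
  expect_true(any(abs(out$times_ms - 1990) < 20))
  # without the envelope the gap cannot be repaired
  expect_warning(reject_extra_peaks(cand), "refinement")
})

test_that("S1/S2 parity follows the shorter-interval-is-systole prior", {
  # intervals 300, 500, 300, 500: first peak opens a systole
  seg <- label_s1_s2(mk_peaks(c(0, 300, 800, 1100, 1600), rep(1, 5)))
  expect_equal(seg$s1_times_ms, c(0, 800, 1600))
  expect_equal(seg$s2_times_ms, c(300, 1100))
  # intervals 500, 300, ...: parity flips, second peak is S1
  seg2 <- label_s1_s2(mk_peaks(c(0, 500, 800, 1300, 1600), rep(1, 5)))
  expect_equal(seg2$s1_times_ms, c(500, 1300))
  # tie: warn, first peak taken as S1
  expect_warning(
    seg3 <- label_s1_s2(mk_peaks(c(0, 400, 800, 1200), rep(1, 4))),
    "tie")
  expect_equal(seg3$s1_times_ms, c(0, 800))
  expect_error(label_s1_s2(mk_peaks(c(0, 300, 800), rep(1, 3))),
               "insufficient peaks")
})

test_that("segmentation bookkeeping counts candidates and retained peaks", {
  cand <- mk_peaks(c(0, 30, 300, 800, 1100, 1600, 1900),
                   c(1.0, 0.4, 0.8, 0.9, 0.7, 1.0, 0.8))
  kept <- reject_extra_peaks(cand)
  seg <- label_s1_s2(kept, candidates = cand)
  expect_equal(seg$n_candidates, 7)
  expect_equal(seg$n_retained, 6)
  expect_equal(seg$mean_amp_candidates, mean(cand$amplitudes))
  expect_equal(seg$mean_amp_retained, mean(kept$amplitudes))
})

test_that("fragmentation floors to whole windows and inherits the label", {
  fs <- 2000
  rec <- pcg_recording(rnorm(23 * fs), fs, id = "r", label = "abnormal")
  frags <- fragment_recording(rec, 5)
  expect_length(frags, 4)
  expect_true(all(vapply(frags, function(f) length(f$samples), 0) == 5 * fs))
  expect_equal(vapply(frags, `[[`, 0L, "index"), 0:3)
  expect_true(all(vapply(frags, `[[`, "", "label") == "abnormal"))
  # sample conservation: windows tile the prefix exactly
  expect_identical(unlist(lapply(frags, `[[`, "samples")),
                   rec$samples[1:(4 * 5 * fs)])
  exact <- fragment_recording(pcg_recording(rnorm(5 * fs), fs), 5)
  expect_length(exact, 1)
  expect_warning(short <- fragment_recording(pcg_recording(rnorm(4.9 * fs), fs), 5),
                 "shorter")
  expect_length(short, 0)
})
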