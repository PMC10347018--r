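test_that("event counts follow duration and heart rate exactly", {
  g <- generate_recording(synth_spec(duration_s = 60, heart_rate_bpm = 75,
                                     systole_ms = 300, jitter_ms = 0,
                                     snr_db = 30, seed = 1))
  expect_length(g$truth$s1_times_ms, 75)
  expect_length(g$truth$s2_times_ms, 75)
  expect_equal(g$recording$label, "normal")
})

test_that("generation is bit-identical under the same seed", {
  spec <- synth_spec(duration_s = 10, seed = 77, murmur_rel = 0.4)
  a <- generate_recording(spec)
  b <- generate_recording(spec)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$truth$s1_times_ms, b$truth$s1_times_ms)
  expect_equal(a$recording$label, "abnormal")
})

test_that("the realized SNR is within 1 dB of the requested value", {
  for (target in c(15, 25)) {
    spec <- synth_spec(duration_s = 20, snr_db = target, jitter_ms = 0,
                       seed = 5)
    noisy <- generate_recording(spec)$recording$samples
    clean <- generate_recording(synth_spec(duration_s = 20, snr_db = 200,
                                           jitter_ms = 0, seed = 5))$recording$samples
    noise <- noisy - clean
    got <- 10 * log10(mean(clean^2) / mean(noise^2))
    expect_equal(got, target, tolerance = 1 / target)
  }
})

test_that("ground-truth systole matches the spec within jitter tolerance", {
  spec <- synth_spec(duration_s = 30, heart_rate_bpm = 80, systole_ms = 320,
                     jitter_ms = 5, seed = 9)
  g <- generate_recording(spec)
  n <- length(g$truth$s2_times_ms)
  sys <- g$truth$s2_times_ms - g$truth$s1_times_ms[seq_len(n)]
  expect_equal(mean(sys), 320, tolerance = (3 * 5 * sqrt(2) / sqrt(n)) / 320)
})

test_that("normal recordings carry no murmur energy in diastole", {
  spec <- synth_spec(duration_s = 20, heart_rate_bpm = 60, systole_ms = 300,
                     jitter_ms = 0, snr_db = 40, seed = 21)
  x <- generate_recording(spec)$recording
  t_ms <- (seq_along(x$samples) - 1) * 1000 / x$fs
  truth <- generate_recording(spec)$truth
  # mid-diastole windows, away from S2 tails
  in_dia <- rep(FALSE, length(t_ms))
  for (i in seq_along(truth$s2_times_ms)) {
    lo <- truth$s2_times_ms[i] + 150
    hi <- truth$s1_times_ms[i] + 60000 / spec$heart_rate_bpm - 150
    in_dia <- in_dia | (t_ms >= lo & t_ms <= hi)
  }
  dia_pow <- mean(x$samples[in_dia]^2)
  tot_pow <- mean(x$samples^2)
  noise_pow <- tot_pow / (1 + 10^(spec$snr_db / 10))
  expect_lt(dia_pow, 3 * noise_pow)
})

test_that("abnormal recordings put band-limited murmur power inside systole", {
  spec_n <- synth_spec(duration_s = 20, systole_ms = 300, jitter_ms = 0,
                       snr_db = 40, seed = 33, murmur_rel = 0)
  spec_a <- synth_spec(duration_s = 20, systole_ms = 300, jitter_ms = 0,
                       snr_db = 40, seed = 33, murmur_rel = 0.5)
  xn <- generate_recording(spec_n)$recording$samples
  xa <- generate_recording(spec_a)$recording$samples
  truth <- generate_recording(spec_n)$truth
  t_ms <- (seq_along(xn) - 1) * 1000 / 2000
  in_sys <- rep(FALSE, length(t_ms))
  for (i in seq_along(truth$s2_times_ms)) {
    in_sys <- in_sys | (t_ms >= truth$s1_times_ms[i] + 50 &
                          t_ms <= truth$s2_times_ms[i] - 30)
  }
  expect_gt(mean(xa[in_sys]^2), 2 * mean(xn[in_sys]^2))
})

test_that("dataset generation writes WAVs, manifest and ground truth", {
  dir <- withr::local_tempdir()
  ranges <- default_synth_ranges()
  ranges$duration_s <- 6
  ds <- generate_dataset(3, 2, ranges = ranges, seed = 13, dir = dir)
  expect_length(ds, 5)
  man <- load_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 5)
  expect_equal(sum(man$label == "abnormal"), 2)
  expect_true(all(file.exists(manifest_paths <- pcglstf:::manifest_paths(man))))
  rec <- read_recording(manifest_paths[1], label = man$label[1])
  expect_equal(rec$fs, 2000)
  truth <- read.delim(file.path(dir, "nor001_truth.tsv"))
  expect_true(all(truth$label %in% c("S1", "S2")))
  # rerun reproduces identical files
  dir2 <- withr::local_tempdir()
  generate_dataset(3, 2, ranges = ranges, seed = 13, dir = dir2)
  expect_identical(readBin(file.path(dir, "nor001.wav"), "raw", 5e5),
                   readBin(file.path(dir2, "nor001.wav"), "raw", 5e5))
})
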