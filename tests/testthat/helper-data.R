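# Shared synthetic fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# greedy one-to-one matching of detected to true event times
match_events <- function(detected, truth, tol_ms = 30) {
  used <- logical(length(truth))
  tp <- 0L
  for (d in detected) {
    err <- abs(truth - d)
    err[used] <- Inf
    j <- which.min(err)
    if (length(j) && err[j] <= tol_ms) {
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  c(tp = tp, fp = length(detected) - tp, fn = length(truth) - tp)
}

detection_f1 <- function(seg, truth, tol_ms = 30) {
  m <- match_events(sort(c(seg$s1_times_ms, seg$s2_times_ms)),
                    sort(c(truth$s1_times_ms, truth$s2_times_ms)), tol_ms)
  2 * m["tp"] / (2 * m["tp"] + m["fp"] + m["fn"])
}

# parity is correct if detected S1s sit closer to true S1s than to true S2s
parity_correct <- function(seg, truth) {
  d_to <- function(times, ref) {
    mean(vapply(times, function(t) min(abs(ref - t)), 0))
  }
  d_to(seg$s1_times_ms, truth$s1_times_ms) <
    d_to(seg$s1_times_ms, truth$s2_times_ms)
}

# 50 murmur-free recordings spanning the study heart-rate/SNR ranges,
# segmented; used by the recovery and interval-accuracy checks
segmentation_recovery_batch <- function() {
  memo("seg_recovery", function() {
    ds <- generate_dataset(50, 1, seed = 424242)[1:50]
    lapply(ds, function(e) {
      seg <- segment_recording(e$recording)
      list(seg = seg, truth = e$truth, spec = e$spec)
    })
  })
}

# 200-recording labelled dataset (100 normal / 100 abnormal) featurized to
# the full 33-column table, plus its NCA selection
classification_fixture <- function() {
  memo("classification", function() {
    ds <- generate_dataset(100, 100, seed = 20230623)
    tbl <- extract_features(lapply(ds, `[[`, "recording"))
    sel <- select_top_k(nca_weights(tbl, seed = 1), 16)
    list(table = tbl, selection = sel,
         n_excluded = nrow(attr(tbl, "exclusions")))
  })
}

# small fast dataset for unit-level classification tests
small_table33 <- function() {
  memo("small33", function() {
    ds <- generate_dataset(8, 8, seed = 99)
    extract_features(lapply(ds, `[[`, "recording"))
  })
}
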