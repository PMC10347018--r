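feature_names_of <- function(tbl) {
  setdiff(names(tbl), c("recording_id", "fragment_index", "label"))
}

# synthetic table with named planted-signal features
planted_table <- function(n = 500, p = 10, informative = 1, seed = 1,
                          duplicate = FALSE) {
  pcglstf:::with_seed(seed, {
    y <- rep(c("normal", "abnormal"), length.out = n)
    X <- matrix(rnorm(n * p), n, p)
    for (j in seq_len(informative)) {
      X[, j] <- ifelse(y == "abnormal", 1, -1) + rnorm(n, 0, 0.3)
    }
    if (duplicate) X[, p] <- X[, 1]
    colnames(X) <- paste0("f", seq_len(p))
    df <- data.frame(recording_id = sprintf("r%04d", seq_len(n)),
                     fragment_index = 0L, X, label = y, check.names = FALSE)
    attr(df, "feature_set") <- "custom"
    df
  })
}

test_that("merging appends the 6 long-term features after the 27 short-term ones", {
  stf <- setNames(seq_len(27), short_term_feature_names())
  ltf <- setNames(101:106, long_term_feature_names())
  v <- merge_features(stf, ltf)
  expect_length(v, 33)
  expect_identical(unname(v[28:33]), 101:106)
  expect_identical(names(v), c(short_term_feature_names(),
                               long_term_feature_names()))
  # merge then split recovers both inputs
  expect_identical(v[1:27], stf)
  expect_identical(v[28:33], ltf)
  expect_error(merge_features(stf[1:5], ltf), "27")
})

test_that("all fragments of one recording share the trailing long-term block", {
  tbl <- small_table33()
  ltf_cols <- long_term_feature_names()
  for (id in unique(tbl$recording_id)) {
    sub <- tbl[tbl$recording_id == id, ltf_cols, drop = FALSE]
    expect_true(all(vapply(sub, function(col) all(col == col[1]), TRUE)),
                label = paste("constant LTF block for", id))
  }
})

test_that("NCA gives the planted informative feature the top weight", {
  tbl <- planted_table(n = 500, p = 10, seed = 11)
  sel <- nca_weights(tbl, seed = 11)
  expect_identical(names(which.max(sel$weights)), "f1")
  expect_true("f1" %in% sel$selected)
  # noise features stay far below the informative one
  expect_true(all(sel$weights[-1] < 0.1 * sel$weights[1]))
})

test_that("duplicated features share the weight and permuting rows changes nothing", {
  tbl <- planted_table(n = 300, p = 6, seed = 4, duplicate = TRUE)
  sel <- nca_weights(tbl, seed = 4)
  w1 <- sel$weights[["f1"]]; w6 <- sel$weights[["f6"]]
  expect_lt(abs(w1 - w6) / max(w1, w6), 0.10)
  perm <- pcglstf:::with_seed(99, tbl[sample(nrow(tbl)), ])
  sel2 <- nca_weights(perm, seed = 4)
  expect_equal(sel2$weights, sel$weights, tolerance = 1e-8)
})

test_that("NCA is deterministic given a seed and rejects one-class tables", {
  tbl <- planted_table(n = 200, p = 5, seed = 2)
  expect_identical(nca_weights(tbl, seed = 3)$weights,
                   nca_weights(tbl, seed = 3)$weights)
  tbl$label <- "normal"
  expect_error(nca_weights(tbl), "two classes")
})

test_that("the five feature sets have the documented column structure", {
  tbl <- small_table33()
  sel <- select_top_k(nca_weights(tbl, seed = 1), 10)
  stf <- build_feature_set(tbl, "STF")
  ltf <- build_feature_set(tbl, "LTF")
  lstf <- build_feature_set(tbl, "LSTF")
  expect_length(feature_names_of(stf), 27)
  expect_length(feature_names_of(ltf), 6)
  expect_length(feature_names_of(lstf), 33)
  expect_identical(feature_names_of(ltf), long_term_feature_names())
  sstf <- build_feature_set(tbl, "SSTF", sel)
  slstf <- build_feature_set(tbl, "SLSTF", sel)
  k <- length(intersect(sel$selected, short_term_feature_names()))
  expect_length(feature_names_of(sstf), k)
  expect_length(feature_names_of(slstf), k + 6)
  # long-term features always survive in SLSTF
  expect_true(all(long_term_feature_names() %in% feature_names_of(slstf)))
  expect_error(build_feature_set(tbl, "SSTF"), "selection")
})

test_that("top-k selection pins the SSTF cardinality", {
  tbl <- small_table33()
  sel <- select_top_k(nca_weights(tbl, seed = 1), 16)
  expect_length(sel$selected, 16)
  sstf <- build_feature_set(tbl, "SSTF", sel)
  slstf <- build_feature_set(tbl, "SLSTF", sel)
  expect_length(feature_names_of(sstf), 16)
  expect_length(feature_names_of(slstf), 22)
})

test_that("selections serialize to JSON and back", {
  tbl <- planted_table(n = 120, p = 4, seed = 9)
  sel <- nca_weights(tbl, seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  write_selection(sel, path)
  back <- read_selection(path)
  expect_equal(back$weights, sel$weights, tolerance = 1e-12)
  expect_identical(back$selected, sel$selected)
  expect_equal(back$threshold, sel$threshold, tolerance = 1e-12)
})
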