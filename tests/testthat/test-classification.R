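# linearly separable toy table
separable_table <- function(n = 200, p = 4, gap = 4, seed = 1) {
  pcglstf:::with_seed(seed, {
    y <- rep(c("normal", "abnormal"), length.out = n)
    X <- matrix(rnorm(n * p), n, p) +
      matrix(ifelse(y == "abnormal", gap / 2, -gap / 2), n, p)
    colnames(X) <- paste0("f", seq_len(p))
    df <- data.frame(recording_id = rep(sprintf("r%03d", 1:(n / 4)),
                                        length.out = n),
                     fragment_index = 0L, X, label = y, check.names = FALSE)
    attr(df, "feature_set") <- "custom"
    df
  })
}

test_that("the preset catalogue covers the 22 variants in five families", {
  v <- classifier_presets()
  expect_length(v, 22)
  fams <- vapply(v, function(x) classifier_preset(x)$family, "")
  expect_equal(as.integer(table(fams)[c("decision_tree", "naive_bayes", "svm",
                                        "knn", "ensemble")]),
               c(3L, 2L, 6L, 6L, 5L))
  expect_error(classifier_preset("giant_tree"), "unknown preset")
  expect_true(all(family_best_presets() %in% v))
})

test_that("fragment-mode splits are stratified, disjoint and reproducible", {
  tbl <- separable_table(n = 100)
  sp <- split_table(tbl, train_frac = 0.7, mode = "fragment", seed = 5)
  expect_equal(nrow(sp$train), 70)
  expect_equal(nrow(sp$validation), 30)
  expect_equal(sum(sp$train$label == "abnormal"), 35)
  sp2 <- split_table(tbl, train_frac = 0.7, mode = "fragment", seed = 5)
  expect_identical(rownames(sp$train), rownames(sp2$train))
  expect_false(identical(
    rownames(split_table(tbl, seed = 6)$train), rownames(sp$train)))
})

test_that("recording-mode splits keep whole recordings on one side", {
  tbl <- small_table33()
  sp <- split_table(tbl, mode = "recording", seed = 2)
  expect_length(intersect(sp$train$recording_id, sp$validation$recording_id), 0)
  expect_setequal(unique(c(sp$train$label, sp$validation$label)),
                  c("normal", "abnormal"))
})

test_that("every preset separates a well-separated two-class problem", {
  tbl <- separable_table(n = 240, gap = 5, seed = 3)
  sp <- split_table(tbl, seed = 3)
  rep <- train_eval(sp$train, sp$validation, presets = classifier_presets(),
                    seed = 3)
  expect_equal(nrow(rep), 22)
  expect_true(all(rep$accuracy >= 0.95),
              label = paste("min accuracy:", min(rep$accuracy)))
  expect_true(all(rep$accuracy <= 1 & rep$f1 <= 1))
})

test_that("training is deterministic given the seed", {
  tbl <- separable_table(n = 160, gap = 2, seed = 8)
  sp <- split_table(tbl, seed = 8)
  presets <- c("fine_tree", "weighted_knn", "subspace_knn", "rusboosted_tree",
               "boosted_tree", "bagged_tree")
  r1 <- train_eval(sp$train, sp$validation, presets = presets, seed = 4)
  r2 <- train_eval(sp$train, sp$validation, presets = presets, seed = 4)
  expect_identical(r1$accuracy, r2$accuracy)
})

test_that("scaling statistics come from the training rows only", {
  tbl <- separable_table(n = 120, gap = 3, seed = 10)
  sp <- split_table(tbl, seed = 10)
  # shifting validation features by a constant must not change the scaler,
  # so a shift large enough to cross the boundary flips predictions
  r_base <- train_eval(sp$train, sp$validation, presets = "linear_svm", seed = 1)
  shifted <- sp$validation
  shifted$f1 <- shifted$f1 + 100
  r_shift <- train_eval(sp$train, shifted, presets = "linear_svm", seed = 1)
  expect_lt(r_shift$accuracy, r_base$accuracy)
  # duplicating the validation set leaves accuracy unchanged
  dup <- rbind(sp$validation, sp$validation)
  attr(dup, "feature_set") <- "custom"
  r_dup <- train_eval(sp$train, dup, presets = "linear_svm", seed = 1)
  expect_equal(r_dup$accuracy, r_base$accuracy)
})

test_that("constant training columns are dropped with a warning", {
  tbl <- separable_table(n = 80, gap = 3, seed = 12)
  tbl$f4 <- 1
  sp <- split_table(tbl, seed = 12)
  expect_warning(r <- train_eval(sp$train, sp$validation,
                                 presets = "fine_knn", seed = 1),
                 "constant")
  expect_gt(r$accuracy, 0.9)
})

test_that("the ablation report covers every preset and feature set", {
  tbl <- small_table33()
  sel <- select_top_k(nca_weights(tbl, seed = 1), 16)
  rep <- ablation(tbl, sel, presets = c("fine_tree", "weighted_knn"),
                  seeds = c(1, 2))
  expect_setequal(unique(rep$feature_set),
                  c("STF", "LTF", "LSTF", "SSTF", "SLSTF"))
  expect_equal(nrow(rep), 10)
  expect_true(all(rep$n_seeds == 2))
  expect_true(all(rep$accuracy_mean >= 0 & rep$accuracy_mean <= 1))
  # identical seeds reproduce the report
  rep2 <- ablation(tbl, sel, presets = c("fine_tree", "weighted_knn"),
                   seeds = c(1, 2))
  expect_identical(rep$accuracy_mean, rep2$accuracy_mean)
})
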