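#' Classifier presets
#'
#' The benchmark covers five classical families — decision trees, naive
#' Bayes, support vector machines, k-nearest neighbors and ensemble methods —
#' in 22 named variants. Variant hyperparameters follow the widely used
#' "fine/medium/coarse" preset vocabulary: tree presets differ in allowed
#' depth, Gaussian-kernel SVM presets in kernel scale (\eqn{\gamma =
#' 1/s^2} with scale \eqn{s = \sqrt{P}/4, \sqrt{P}, 4\sqrt{P}} for
#' fine/medium/coarse, P = number of features), KNN presets in neighbor
#' count, distance and vote weighting, and ensembles combine 30 weak
#' learners (boosting, bagging, random subspaces, undersampled boosting).
#'
#' @param variant One of the names returned by `classifier_presets()`.
#' @return `classifier_preset()`: a `pcg_preset` (family, variant,
#'   hyperparameters). `classifier_presets()`: character vector of all 22
#'   variant names. `family_best_presets()`: the best-performing variant of
#'   each family (fine tree, Gaussian NB, fine Gaussian SVM, weighted KNN,
#'   subspace KNN).
#' @export
classifier_preset <- function(variant) {
  tbl <- preset_table()
  if (!variant %in% names(tbl)) {
    stop("unknown preset '", variant, "'; see classifier_presets()")
  }
  structure(c(list(variant = variant), tbl[[variant]]), class = "pcg_preset")
}

#' @rdname classifier_preset
#' @export
classifier_presets <- function() names(preset_table())

#' @rdname classifier_preset
#' @export
family_best_presets <- function() {
  c(decision_tree = "fine_tree", naive_bayes = "gaussian_nb",
    svm = "fine_gaussian_svm", knn = "weighted_knn", ensemble = "subspace_knn")
}

preset_table <- function() {
  list(
    # decision trees: max tree depth stands in for a max-split budget
    fine_tree   = list(family = "decision_tree", hyper = list(maxdepth = 8, cp = 1e-4)),
    medium_tree = list(family = "decision_tree", hyper = list(maxdepth = 5, cp = 1e-4)),
    coarse_tree = list(family = "decision_tree", hyper = list(maxdepth = 2, cp = 1e-4)),
    gaussian_nb = list(family = "naive_bayes", hyper = list(kernel = FALSE)),
    kernel_nb   = list(family = "naive_bayes", hyper = list(kernel = TRUE)),
    linear_svm    = list(family = "svm", hyper = list(kernel = "linear")),
    quadratic_svm = list(family = "svm", hyper = list(kernel = "polynomial", degree = 2)),
    cubic_svm     = list(family = "svm", hyper = list(kernel = "polynomial", degree = 3)),
    fine_gaussian_svm   = list(family = "svm", hyper = list(kernel = "radial", scale = "fine")),
    medium_gaussian_svm = list(family = "svm", hyper = list(kernel = "radial", scale = "medium")),
    coarse_gaussian_svm = list(family = "svm", hyper = list(kernel = "radial", scale = "coarse")),
    fine_knn   = list(family = "knn", hyper = list(k = 1, metric = "euclidean", weighted = FALSE)),
    medium_knn = list(family = "knn", hyper = list(k = 10, metric = "euclidean", weighted = FALSE)),
    coarse_knn = list(family = "knn", hyper = list(k = 100, metric = "euclidean", weighted = FALSE)),
    cosine_knn = list(family = "knn", hyper = list(k = 10, metric = "cosine", weighted = FALSE)),
    cubic_knn  = list(family = "knn", hyper = list(k = 10, metric = "minkowski3", weighted = FALSE)),
    weighted_knn = list(family = "knn", hyper = list(k = 10, metric = "euclidean", weighted = TRUE)),
    boosted_tree = list(family = "ensemble", hyper = list(method = "boost", n_learners = 30, maxdepth = 5)),
    bagged_tree  = list(family = "ensemble", hyper = list(method = "bag", n_learners = 30)),
    subspace_discriminant = list(family = "ensemble", hyper = list(method = "subspace_lda", n_learners = 30)),
    subspace_knn = list(family = "ensemble", hyper = list(method = "subspace_knn", n_learners = 30, k = 1)),
    rusboosted_tree = list(family = "ensemble", hyper = list(method = "rusboost", n_learners = 30, maxdepth = 5))
  )
}

pcg_classes <- c("normal", "abnormal")   # "abnormal" is the positive class

#' Stratified train/validation split
#'
#' Splits a feature table into training and validation parts, stratified by
#' class. `mode = "fragment"` splits rows independently (the benchmark
#' protocol); `mode = "recording"` keeps all fragments of a recording on the
#' same side, which prevents within-recording leakage.
#'
#' @param table A feature table.
#' @param train_frac Fraction of rows (or recordings) for training.
#' @param mode `"fragment"` or `"recording"`.
#' @param seed Integer seed; identical seeds give identical splits.
#' @return List with elements `train` and `validation`.
#' @export
split_table <- function(table, train_frac = 0.7,
                        mode = c("fragment", "recording"), seed = 1) {
  mode <- match.arg(mode)
  with_seed(seed, {
    if (mode == "fragment") {
      take <- logical(nrow(table))
      for (cl in unique(table$label)) {
        idx <- which(table$label == cl)
        n_tr <- round(train_frac * length(idx))
        take[sample(idx, n_tr)] <- TRUE
      }
    } else {
      recs <- unique(table[c("recording_id", "label")])
      take_rec <- character(0)
      for (cl in unique(recs$label)) {
        ids <- recs$recording_id[recs$label == cl]
        take_rec <- c(take_rec, sample(ids, round(train_frac * length(ids))))
      }
      take <- table$recording_id %in% take_rec
    }
    train <- table[take, , drop = FALSE]
    validation <- table[!take, , drop = FALSE]
    for (part in list(train, validation)) {
      missing <- setdiff(unique(table$label), unique(part$label))
      if (length(missing)) {
        stop("class '", missing[1], "' absent from one side of the split; ",
             "use more data or a larger train_frac")
      }
    }
    attr(train, "feature_set") <- attr(table, "feature_set")
    attr(validation, "feature_set") <- attr(table, "feature_set")
    list(train = train, validation = validation)
  })
}

# ---- fitting ----------------------------------------------------------------

fit_classifier <- function(preset, X, y, seed = 1) {
  y <- factor(y, levels = pcg_classes)
  h <- preset$hyper
  model <- with_seed(seed, switch(preset$family,
    decision_tree = {
      df <- data.frame(X, y = y, check.names = FALSE)
      rpart::rpart(y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(
                     maxdepth = h$maxdepth, cp = h$cp, minsplit = 5, xval = 0))
    },
    naive_bayes = {
      if (h$kernel) kernel_nb_fit(X, y) else e1071::naiveBayes(X, y)
    },
    svm = {
      gamma <- if (identical(h$kernel, "radial")) {
        s <- sqrt(ncol(X)) * switch(h$scale, fine = 0.25, medium = 1, coarse = 4)
        1 / s^2
      } else 1 / ncol(X)
      e1071::svm(X, y, kernel = h$kernel,
                 degree = if (is.null(h$degree)) 3 else h$degree,
                 coef0 = if (identical(h$kernel, "polynomial")) 1 else 0,
                 gamma = gamma, cost = 1, scale = FALSE)
    },
    knn = structure(list(X = X, y = y, h = h), class = "pcg_knn"),
    ensemble = fit_ensemble(h, X, y, seed),
    stop("unknown family: ", preset$family)
  ))
  structure(list(model = model, family = preset$family,
                 variant = preset$variant, hyper = h,
                 feature_names = colnames(X)),
            class = "pcg_classifier")
}

predict_classifier <- function(fit, X) {
  X <- X[, fit$feature_names, drop = FALSE]
  m <- fit$model
  out <- switch(fit$family,
    decision_tree = predict(m, data.frame(X, check.names = FALSE), type = "class"),
    naive_bayes = if (inherits(m, "pcg_kernel_nb")) kernel_nb_predict(m, X)
                  else predict(m, X),
    svm = predict(m, X),
    knn = knn_predict(m$X, m$y, X, k = m$h$k, metric = m$h$metric,
                      weighted = m$h$weighted),
    ensemble = predict_ensemble(m, X)
  )
  factor(as.character(out), levels = pcg_classes)
}

# ---- kernel naive Bayes -----------------------------------------------------

kernel_nb_fit <- function(X, y) {
  dens <- lapply(levels(y), function(cl) {
    Xc <- X[y == cl, , drop = FALSE]
    lapply(seq_len(ncol(Xc)), function(j) {
      v <- Xc[, j]
      if (stats::sd(v) == 0) list(constant = v[1], sd = 1e-3)
      else stats::density(v, n = 512, cut = 3)
    })
  })
  names(dens) <- levels(y)
  structure(list(dens = dens, prior = table(y) / length(y),
                 classes = levels(y)),
            class = "pcg_kernel_nb")
}

kernel_nb_predict <- function(m, X) {
  floor_d <- 1e-9
  ll <- sapply(m$classes, function(cl) {
    out <- log(as.numeric(m$prior[cl]))
    for (j in seq_len(ncol(X))) {
      d <- m$dens[[cl]][[j]]
      f <- if (!is.null(d$constant)) {
        stats::dnorm(X[, j], d$constant, d$sd)
      } else {
        stats::approx(d$x, d$y, xout = X[, j], yleft = 0, yright = 0)$y
      }
      out <- out + log(pmax(f, floor_d))
    }
    out
  })
  m$classes[max.col(ll, ties.method = "first")]
}

# ---- k-nearest neighbors ----------------------------------------------------

knn_predict <- function(Xtr, ytr, Xte, k, metric = "euclidean",
                        weighted = FALSE) {
  k <- min(k, nrow(Xtr))
  D <- switch(metric,
    euclidean = pairwise_dist(Xte, Xtr, p = 2),
    minkowski3 = pairwise_dist(Xte, Xtr, p = 3),
    cosine = {
      nt <- sqrt(rowSums(Xte^2)); nr <- sqrt(rowSums(Xtr^2))
      nt[nt == 0] <- 1; nr[nr == 0] <- 1
      1 - (Xte %*% t(Xtr)) / outer(nt, nr)
    },
    stop("unknown metric: ", metric))
  lvls <- levels(ytr)
  out <- character(nrow(Xte))
  for (i in seq_len(nrow(Xte))) {
    o <- order(D[i, ])[seq_len(k)]
    w <- if (weighted) 1 / (D[i, o]^2 + 1e-12) else rep(1, k)
    votes <- tapply(w, factor(ytr[o], levels = lvls), sum, default = 0)
    top <- which(votes == max(votes))
    out[i] <- if (length(top) == 1L) lvls[top] else as.character(ytr[o][1])
  }
  factor(out, levels = lvls)
}

pairwise_dist <- function(A, B, p = 2) {
  if (p == 2) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    sqrt(pmax(d2, 0))
  } else {
    D <- matrix(0, nrow(A), nrow(B))
    for (j in seq_len(ncol(A))) {
      D <- D + abs(outer(A[, j], B[, j], "-"))^p
    }
    D^(1 / p)
  }
}

# ---- ensembles --------------------------------------------------------------

fit_ensemble <- function(h, X, y, seed) {
  switch(h$method,
    boost = {
      dtrain <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L)
      booster <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = h$maxdepth,
                      eta = 0.3, nthread = 1, seed = seed),
        data = dtrain, nrounds = h$n_learners, verbose = 0)
      structure(list(booster = booster, classes = levels(y)),
                class = "pcg_boost")
    },
    bag = structure(
      list(rf = randomForest::randomForest(X, y, ntree = h$n_learners,
                                           mtry = ncol(X))),
      class = "pcg_bag"),
    subspace_lda = fit_subspace(X, y, h$n_learners,
                                learner = "lda"),
    subspace_knn = fit_subspace(X, y, h$n_learners,
                                learner = "knn", k = h$k),
    rusboost = rusboost_fit(X, y, n_rounds = h$n_learners,
                            maxdepth = h$maxdepth),
    stop("unknown ensemble method: ", h$method))
}

predict_ensemble <- function(m, X) {
  if (inherits(m, "pcg_boost")) {
    pr <- predict(m$booster, xgboost::xgb.DMatrix(X))
    m$classes[1L + as.integer(pr > 0.5)]
  } else if (inherits(m, "pcg_bag")) {
    predict(m$rf, X)
  } else if (inherits(m, "pcg_subspace")) {
    predict_subspace(m, X)
  } else if (inherits(m, "pcg_rusboost")) {
    rusboost_predict(m, X)
  } else stop("unknown ensemble model")
}

# random-subspace ensemble: each learner sees ceil(p/2) random features
fit_subspace <- function(X, y, n_learners, learner, k = 1) {
  p <- ncol(X)
  dim_sub <- max(1L, ceiling(p / 2))
  members <- lapply(seq_len(n_learners), function(b) {
    feats <- sample.int(p, dim_sub)
    fit <- if (learner == "lda") {
      Xs <- X[, feats, drop = FALSE]
      keep <- apply(Xs, 2, stats::sd) > 0
      if (!any(keep)) return(NULL)
      MASS::lda(Xs[, keep, drop = FALSE], grouping = y)
    } else NULL
    list(feats = feats, fit = fit)
  })
  structure(list(members = members, learner = learner, k = k, X = X, y = y),
            class = "pcg_subspace")
}

predict_subspace <- function(m, X) {
  lvls <- levels(m$y)
  votes <- matrix(0, nrow(X), length(lvls), dimnames = list(NULL, lvls))
  for (mem in m$members) {
    if (m$learner == "lda") {
      if (is.null(mem$fit)) next
      Xs <- X[, mem$feats, drop = FALSE][, colnames(mem$fit$means), drop = FALSE]
      pred <- predict(mem$fit, Xs)$class
    } else {
      pred <- knn_predict(m$X[, mem$feats, drop = FALSE], m$y,
                          X[, mem$feats, drop = FALSE], k = m$k)
    }
    votes[cbind(seq_len(nrow(X)), match(as.character(pred), lvls))] <-
      votes[cbind(seq_len(nrow(X)), match(as.character(pred), lvls))] + 1
  }
  factor(lvls[max.col(votes, ties.method = "first")], levels = lvls)
}

# AdaBoost.M1 with per-round random undersampling of the majority class
rusboost_fit <- function(X, y, n_rounds = 30, maxdepth = 5) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  lvls <- levels(y)
  n_min <- min(table(y))
  members <- list()
  alphas <- numeric(0)
  for (r in seq_len(n_rounds)) {
    idx <- unlist(lapply(lvls, function(cl) {
      pool <- which(y == cl)
      if (length(pool) <= n_min) pool
      else sample(pool, n_min, prob = w[pool] / sum(w[pool]))
    }))
    df <- data.frame(X[idx, , drop = FALSE], y = y[idx], check.names = FALSE)
    tree <- rpart::rpart(y ~ ., data = df, method = "class",
                         control = rpart::rpart.control(
                           maxdepth = maxdepth, cp = 0, minsplit = 5, xval = 0))
    pred <- predict(tree, data.frame(X, check.names = FALSE), type = "class")
    miss <- pred != y
    err <- sum(w[miss]) / sum(w)
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    members[[length(members) + 1L]] <- tree
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * ifelse(miss, 1, -1))
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  if (length(members) == 0L) {
    members <- list(rpart::rpart(y ~ ., data = data.frame(X, y = y, check.names = FALSE),
                                 method = "class",
                                 control = rpart::rpart.control(maxdepth = maxdepth, xval = 0)))
    alphas <- 1
  }
  structure(list(members = members, alphas = alphas, classes = lvls),
            class = "pcg_rusboost")
}

rusboost_predict <- function(m, X) {
  score <- numeric(nrow(X))   # positive -> second class
  df <- data.frame(X, check.names = FALSE)
  for (i in seq_along(m$members)) {
    pred <- predict(m$members[[i]], df, type = "class")
    score <- score + m$alphas[i] * ifelse(pred == m$classes[2], 1, -1)
  }
  factor(m$classes[1L + (score > 0)], levels = m$classes)
}

# ---- evaluation -------------------------------------------------------------

#' Train presets on one split and evaluate on the other
#'
#' Features are z-scored with statistics computed on the training rows only;
#' constant training columns are dropped with a warning. Classifier
#' internals are delegated to established implementations (rpart, e1071,
#' MASS, randomForest, xgboost) or to small in-package learners for variants
#' those libraries do not cover. Metrics treat `"abnormal"` as the positive
#' class.
#'
#' @param train,validation Feature tables sharing the same columns.
#' @param presets Character vector of preset names (see
#'   [classifier_presets()]).
#' @param seed Integer seed controlling all stochastic learners.
#' @return A data frame of class `pcg_eval_report`: one row per preset with
#'   `variant`, `family`, `feature_set`, `accuracy`, `sensitivity`,
#'   `specificity`, `f1`, `n_train`, `n_validation`.
#' @export
train_eval <- function(train, validation, presets = family_best_presets(),
                       seed = 1) {
  stopifnot(length(presets) > 0,
            identical(names(train), names(validation)))
  Xtr <- feature_matrix(train)
  Xva <- feature_matrix(validation)
  mu <- colMeans(Xtr)
  sdev <- apply(Xtr, 2, stats::sd)
  keep <- sdev > 0
  if (!all(keep)) {
    warning("dropping constant training column(s): ",
            paste(colnames(Xtr)[!keep], collapse = ", "))
    Xtr <- Xtr[, keep, drop = FALSE]; Xva <- Xva[, keep, drop = FALSE]
    mu <- mu[keep]; sdev <- sdev[keep]
  }
  Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdev, "/")
  Xva <- sweep(sweep(Xva, 2, mu), 2, sdev, "/")
  ytr <- factor(train$label, levels = pcg_classes)
  yva <- factor(validation$label, levels = pcg_classes)
  rows <- lapply(presets, function(v) {
    preset <- classifier_preset(v)
    fit <- fit_classifier(preset, Xtr, ytr, seed = seed)
    pred <- predict_classifier(fit, Xva)
    met <- binary_metrics(yva, pred, positive = "abnormal")
    data.frame(variant = v, family = preset$family,
               feature_set = attr_or(train, "feature_set", "custom"),
               accuracy = met["accuracy"], sensitivity = met["sensitivity"],
               specificity = met["specificity"], f1 = met["f1"],
               n_train = nrow(Xtr), n_validation = nrow(Xva),
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  class(out) <- c("pcg_eval_report", class(out))
  out
}

attr_or <- function(x, which, default) {
  v <- attr(x, which)
  if (is.null(v)) default else v
}

binary_metrics <- function(truth, pred, positive) {
  tp <- sum(truth == positive & pred == positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  acc <- (tp + tn) / length(truth)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  c(accuracy = acc, sensitivity = sens, specificity = spec, f1 = f1)
}

#' Feature-set ablation across the five representations
#'
#' Evaluates the given presets on each of the five feature sets (STF, LTF,
#' LSTF, SSTF, SLSTF) built from one full 33-column table, repeating over
#' seeds and reporting mean and standard deviation of every metric.
#'
#' @param table33 Full feature table (33 feature columns).
#' @param selection A `pcg_selection` used for the reduced sets.
#' @param presets Preset names; defaults to the best variant per family.
#' @param seeds Integer vector; one split/train run per seed.
#' @param train_frac,mode Passed to [split_table()].
#' @return Data frame with one row per (variant, feature_set):
#'   mean/sd of accuracy plus mean sensitivity/specificity/F1.
#' @export
ablation <- function(table33, selection, presets = family_best_presets(),
                     seeds = 1, train_frac = 0.7, mode = "fragment") {
  sets <- c("STF", "LTF", "LSTF", "SSTF", "SLSTF")
  runs <- list()
  for (tag in sets) {
    tbl <- build_feature_set(table33, tag, selection)
    for (s in seeds) {
      sp <- split_table(tbl, train_frac = train_frac, mode = mode, seed = s)
      rep_s <- train_eval(sp$train, sp$validation, presets = presets, seed = s)
      rep_s$seed <- s
      runs[[length(runs) + 1L]] <- rep_s
    }
  }
  all <- do.call(rbind, runs)
  agg <- do.call(rbind, lapply(split(all, list(all$variant, all$feature_set),
                                     drop = TRUE), function(g) {
    data.frame(variant = g$variant[1], family = g$family[1],
               feature_set = g$feature_set[1],
               accuracy_mean = mean(g$accuracy), accuracy_sd = stats::sd(g$accuracy),
               sensitivity_mean = mean(g$sensitivity),
               specificity_mean = mean(g$specificity),
               f1_mean = mean(g$f1), n_seeds = nrow(g), row.names = NULL)
  }))
  agg <- agg[order(agg$variant, match(agg$feature_set, sets)), ]
  rownames(agg) <- NULL
  attr(agg, "seeds") <- seeds
  class(agg) <- c("pcg_ablation", class(agg))
  agg
}

#' Serialize an evaluation report as JSON
#' @param report A report data frame.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(
    list(schema = "pcglstf-report/1",
         seeds = attr_or(report, "seeds", attr_or(report, "seed", NA)),
         rows = as.data.frame(report)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
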