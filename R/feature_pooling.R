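#' Merge short- and long-term feature vectors
#'
#' The long short-term representation of a fragment appends the 6
#' recording-level features to the fragment's 27 short-term features,
#' yielding a 33-vector. All fragments of one recording share the trailing
#' 6 components.
#'
#' @param stf Named 27-vector from [short_term_vector()].
#' @param ltf Named 6-vector from [long_term_vector()].
#' @return Named numeric vector of length 33.
#' @export
merge_features <- function(stf, ltf) {
  if (length(stf) != length(short_term_feature_names()) ||
      length(ltf) != length(long_term_feature_names())) {
    stop("expected a ", length(short_term_feature_names()),
         "-vector of short-term and a ", length(long_term_feature_names()),
         "-vector of long-term features")
  }
  c(stf, ltf)
}

#' Assemble a per-fragment feature table
#'
#' @param rows List of lists with elements `recording_id`, `fragment_index`,
#'   `features` (named numeric vector) and `label`.
#' @param feature_set Tag recorded on the table.
#' @return Data frame `recording_id`, `fragment_index`, features..., `label`
#'   with attribute `feature_set`.
#' @export
merge_feature_tables <- function(rows, feature_set = "LSTF") {
  feat <- do.call(rbind, lapply(rows, function(r) r$features))
  df <- data.frame(
    recording_id = vapply(rows, `[[`, "", "recording_id"),
    fragment_index = vapply(rows, `[[`, 0L, "fragment_index"),
    feat,
    label = vapply(rows, `[[`, "", "label"),
    check.names = FALSE
  )
  attr(df, "feature_set") <- feature_set
  df
}

feature_columns <- function(table) {
  setdiff(names(table), c("recording_id", "fragment_index", "label"))
}

feature_matrix <- function(table) {
  as.matrix(table[feature_columns(table)])
}

#' Neighborhood component analysis feature weights
#'
#' Ranks features by their usefulness for nearest-neighbor classification.
#' Per-feature weights \eqn{w_r} parameterize the distance
#' \eqn{d_{ij} = \sum_r w_r^2 |x_{ir} - x_{jr}|}; the objective is the
#' expected leave-one-out accuracy of a stochastic nearest-neighbor rule with
#' reference probabilities \eqn{p_{ij} \propto \exp(-d_{ij})}, penalized by
#' \eqn{\lambda \sum_r w_r^2}. Features are z-scored internally before
#' optimization (L-BFGS-B from an all-equal start, analytic gradient), so the
#' result is deterministic; `seed` only governs the optional row subsample
#' used to cap the pairwise computation.
#'
#' @param table A feature table (see [merge_feature_tables()]) with at least
#'   two classes.
#' @param regularization Penalty \eqn{\lambda}; default `1/n`.
#' @param seed Integer seed for row subsampling.
#' @param max_rows Cap on rows entering the pairwise objective; `Inf`
#'   disables subsampling.
#' @param threshold `"mean"` (cutoff at the mean weight) or a number.
#' @return A `pcg_selection`: `weights` (named, non-negative), `threshold`,
#'   `selected` (names with weight above the threshold, in decreasing weight
#'   order), `seed`.
#' @export
nca_weights <- function(table, regularization = NULL, seed = 1,
                        max_rows = 500, threshold = "mean") {
  X <- feature_matrix(table)
  y <- table$label
  if (length(unique(y)) < 2L) stop("NCA needs at least two classes in the table")
  if (nrow(X) > max_rows) {
    idx <- with_seed(seed, sample.int(nrow(X), max_rows))
    X <- X[idx, , drop = FALSE]
    y <- y[idx]
  }
  n <- nrow(X); p <- ncol(X)
  lambda <- if (is.null(regularization)) 1 / n else regularization
  # z-score (constant columns left at 0)
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  sdev[sdev == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  # per-feature pairwise absolute differences
  D <- lapply(seq_len(p), function(r) abs(outer(Z[, r], Z[, r], "-")))
  same <- outer(y, y, "==")
  diag(same) <- FALSE

  neg_obj_grad <- function(w) {
    w2 <- w^2
    dist <- matrix(0, n, n)
    for (r in seq_len(p)) dist <- dist + w2[r] * D[[r]]
    K <- exp(-dist)
    diag(K) <- 0
    denom <- rowSums(K)
    denom[denom == 0] <- .Machine$double.xmin
    P <- K / denom                       # p_ij
    p_i <- rowSums(P * same)             # prob. of correct stochastic 1-NN
    obj <- mean(p_i) - lambda * sum(w2)
    grad <- numeric(p)
    for (r in seq_len(p)) {
      # d obj / d w_r = (2 w_r / n) sum_i ( p_i sum_j p_ij D_ijr
      #                  - sum_{j in class i} p_ij D_ijr ) - 2 lambda w_r
      PD <- P * D[[r]]
      grad[r] <- (2 * w[r] / n) * sum(p_i * rowSums(PD) - rowSums(PD * same)) -
        2 * lambda * w[r]
    }
    list(value = -obj, gradient = -grad)
  }
  fit <- stats::optim(
    par = rep(1, p),
    fn = function(w) neg_obj_grad(w)$value,
    gr = function(w) neg_obj_grad(w)$gradient,
    method = "L-BFGS-B",
    control = list(maxit = 100)
  )
  if (fit$convergence != 0) {
    warning("NCA optimizer did not fully converge (code ", fit$convergence,
            "); using the last iterate")
  }
  w <- abs(fit$par)
  names(w) <- feature_columns(table)
  thr <- if (identical(threshold, "mean")) mean(w) else as.numeric(threshold)
  sel <- names(sort(w[w > thr], decreasing = TRUE))
  structure(list(weights = w, threshold = thr, selected = sel, seed = seed),
            class = "pcg_selection")
}

#' @export
print.pcg_selection <- function(x, ...) {
  cat(sprintf("<pcg_selection: %d/%d features above threshold %.4g>\n",
              length(x$selected), length(x$weights), x$threshold))
  invisible(x)
}

#' Keep the top-k short-term features instead of thresholding
#'
#' Rebuilds a selection so that exactly `k` short-term features (the `k`
#' largest short-term weights) are selected; long-term features are handled
#' downstream by the feature-set definitions.
#'
#' @param selection A `pcg_selection` from [nca_weights()].
#' @param k Number of short-term features to keep.
#' @return A `pcg_selection` with `selected` of length `k`.
#' @export
select_top_k <- function(selection, k) {
  stf <- intersect(names(selection$weights), short_term_feature_names())
  w <- sort(selection$weights[stf], decreasing = TRUE)
  if (k > length(w)) stop("k exceeds the number of short-term features (", length(w), ")")
  sel <- names(w)[seq_len(k)]
  thr <- if (k < length(w)) mean(w[k + c(0, 1)]) else -Inf
  structure(list(weights = selection$weights, threshold = thr,
                 selected = sel, seed = selection$seed),
            class = "pcg_selection")
}

#' Serialize / load a selection result
#' @param selection A `pcg_selection`.
#' @param path JSON path.
#' @return `write_selection` returns `path` invisibly; `read_selection` the
#'   selection.
#' @export
write_selection <- function(selection, path) {
  jsonlite::write_json(
    list(weights = as.list(selection$weights), threshold = selection$threshold,
         selected = selection$selected, seed = selection$seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_selection
#' @export
read_selection <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(weights = unlist(raw$weights), threshold = raw$threshold,
                 selected = as.character(raw$selected), seed = raw$seed),
            class = "pcg_selection")
}

#' Build one of the five benchmark feature sets
#'
#' From the full 33-column table: `STF` keeps the 27 short-term columns,
#' `LTF` the 6 long-term columns, `LSTF` all 33, `SSTF` the selected
#' short-term features, and `SLSTF` the selected short-term features plus all
#' 6 long-term features (long-term features are always kept in the reduced
#' merged set).
#'
#' @param table33 A full feature table with the 33 named columns.
#' @param tag One of `"STF"`, `"LTF"`, `"LSTF"`, `"SSTF"`, `"SLSTF"`.
#' @param selection A `pcg_selection`; required for `SSTF`/`SLSTF`.
#' @return The reduced table, tagged via attribute `feature_set`.
#' @export
build_feature_set <- function(table33, tag, selection = NULL) {
  tag <- match.arg(tag, c("STF", "LTF", "LSTF", "SSTF", "SLSTF"))
  stf <- short_term_feature_names()
  ltf <- long_term_feature_names()
  stopifnot(all(c(stf, ltf) %in% names(table33)))
  keep <- switch(tag,
    STF = stf,
    LTF = ltf,
    LSTF = c(stf, ltf),
    SSTF = {
      if (is.null(selection)) stop("SSTF requires a selection")
      intersect(stf, selection$selected)
    },
    SLSTF = {
      if (is.null(selection)) stop("SLSTF requires a selection")
      c(intersect(stf, selection$selected), ltf)
    }
  )
  if (length(keep) == 0L) stop("selection leaves no features for set ", tag)
  out <- table33[c("recording_id", "fragment_index", keep, "label")]
  attr(out, "feature_set") <- tag
  out
}

# evaluate a function with a temporary RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
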