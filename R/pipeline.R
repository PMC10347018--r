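#' Extract the full long short-term feature table from recordings
#'
#' For each recording: resample to the dataset convention, low-pass filter,
#' segment S1/S2, compute the 6 long-term features, split the filtered
#' signal into five-second fragments, compute each fragment's 27 short-term
#' features and append the recording's long-term features. Recordings whose
#' segmentation fails (or that are shorter than one window) are excluded,
#' not fatal.
#'
#' @param recordings List of [pcg_recording()] objects.
#' @param config A [pcg_config()].
#' @param verbose Print per-recording progress.
#' @return A feature table (33 feature columns, tag `"LSTF"`) with
#'   attribute `exclusions`: data frame of excluded recording ids + reasons.
#' @export
extract_features <- function(recordings, config = pcg_config(),
                             verbose = FALSE) {
  rows <- list()
  excl <- list()
  for (rec in recordings) {
    res <- tryCatch({
      rec2 <- resample_recording(rec, config$io$target_fs)
      if (config$io$normalize_amplitude) {
        rec2$samples <- rec2$samples / max(abs(rec2$samples))
      }
      p <- config$preprocessing
      filt <- lowpass_filter(rec2, cutoff = p$cutoff_hz, order = p$filter_order)
      seg <- segment_recording(rec2, config)
      ltf <- long_term_vector(seg)
      frags <- suppressWarnings(fragment_recording(filt, window_s = p$window_s))
      if (length(frags) == 0L) stop("shorter than one window")
      lapply(frags, function(fr) {
        list(recording_id = fr$recording_id, fragment_index = fr$index,
             features = merge_features(short_term_vector(fr, config = config), ltf),
             label = fr$label)
      })
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excl[[length(excl) + 1L]] <- data.frame(recording_id = rec$id,
                                              reason = conditionMessage(res))
      if (verbose) message("excluded ", rec$id, ": ", conditionMessage(res))
    } else {
      rows <- c(rows, res)
      if (verbose) message("featurized ", rec$id, " (", length(res), " fragments)")
    }
  }
  if (length(rows) == 0L) stop("pipeline error: every recording failed feature extraction")
  tbl <- merge_feature_tables(rows, feature_set = "LSTF")
  attr(tbl, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(recording_id = character(0), reason = character(0))
  tbl
}

#' Read every recording listed in a manifest
#'
#' Unreadable files are skipped with a warning and reported in the
#' `exclusions` attribute.
#'
#' @param manifest A `pcg_manifest` from [load_manifest()].
#' @return List of [pcg_recording()] objects.
#' @export
read_manifest_recordings <- function(manifest) {
  paths <- manifest_paths(manifest)
  out <- list()
  excl <- list()
  for (i in seq_len(nrow(manifest))) {
    r <- tryCatch(read_recording(paths[i], label = manifest$label[i]),
                  error = function(e) e)
    if (inherits(r, "error")) {
      warning("skipping unreadable recording ", manifest$path[i], ": ",
              conditionMessage(r))
      excl[[length(excl) + 1L]] <- data.frame(path = manifest$path[i],
                                              reason = conditionMessage(r))
    } else out[[length(out) + 1L]] <- r
  }
  attr(out, "exclusions") <- if (length(excl)) do.call(rbind, excl) else NULL
  out
}

#' Run the full pipeline on a manifest
#'
#' Orchestrates the four stages — pre-processing, feature extraction,
#' feature pooling/selection, classification — and persists intermediate
#' artifacts so a rerun with the same `out_dir` reuses the cached feature
#' table (resumability).
#'
#' @param manifest A `pcg_manifest`, or a list of in-memory
#'   [pcg_recording()] objects.
#' @param config A [pcg_config()].
#' @param out_dir Directory for artifacts (`features.csv`, `selection.json`,
#'   `report.json`); `NULL` keeps everything in memory.
#' @param presets Preset names for the ablation.
#' @param seeds Seeds for split/training repetitions (first one also seeds
#'   the NCA subsample).
#' @param verbose Print progress.
#' @return List: `features` (33-column table), `selection`, `report`
#'   (ablation data frame), `exclusions`.
#' @export
run_pipeline <- function(manifest, config = pcg_config(), out_dir = NULL,
                         presets = family_best_presets(), seeds = 1,
                         verbose = FALSE) {
  feat_path <- if (!is.null(out_dir)) file.path(out_dir, "features.csv")
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(feat_path) && file.exists(feat_path)) {
    if (verbose) message("reusing cached feature table: ", feat_path)
    table33 <- read_feature_table(feat_path)
    exclusions <- NULL
  } else {
    recordings <- if (inherits(manifest, "pcg_manifest")) {
      read_manifest_recordings(manifest)
    } else manifest
    table33 <- extract_features(recordings, config, verbose = verbose)
    exclusions <- attr(table33, "exclusions")
    if (!is.null(feat_path)) write_feature_table(table33, feat_path)
  }
  nca_cfg <- config$nca
  selection <- nca_weights(
    table33,
    regularization = nca_cfg$regularization,
    seed = seeds[1],
    max_rows = if (is.null(nca_cfg$max_rows)) Inf else nca_cfg$max_rows,
    threshold = nca_cfg$threshold)
  if (!is.null(nca_cfg$select_k)) {
    selection <- select_top_k(selection, nca_cfg$select_k)
  } else if (!any(selection$selected %in% short_term_feature_names())) {
    warning("weight threshold left no short-term feature selected; ",
            "falling back to the top 16 short-term features")
    selection <- select_top_k(selection, 16)
  }
  if (!is.null(out_dir)) write_selection(selection, file.path(out_dir, "selection.json"))
  report <- ablation(table33, selection, presets = presets, seeds = seeds,
                     train_frac = config$classification$train_frac,
                     mode = config$classification$split_mode)
  if (!is.null(out_dir)) write_report(report, file.path(out_dir, "report.json"))
  list(features = table33, selection = selection, report = report,
       exclusions = exclusions)
}
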