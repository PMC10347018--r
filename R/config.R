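#' Pipeline configuration
#'
#' All tunable parameters of the pipeline in one nested list, with the
#' defaults used throughout the package. Any subset can be overridden by
#' name; unknown names are rejected.
#'
#' @param ... Named overrides, e.g. `preprocessing = list(cutoff_hz = 300)`.
#'   Sub-lists are merged element-wise into the defaults.
#' @return A list of class `pcg_config` with blocks `io`, `preprocessing`,
#'   `short_term`, `nca`, `classification`.
#' @examples
#' cfg <- pcg_config(preprocessing = list(threshold_frac = 0.25))
#' cfg$preprocessing$threshold_frac
#' @export
pcg_config <- function(...) {
  defaults <- list(
    io = list(
      target_fs = 2000,          # dataset sampling convention, Hz
      normalize_amplitude = FALSE
    ),
    preprocessing = list(
      cutoff_hz = 400,           # low-pass cutoff; FHS + murmur band
      filter_order = 4,
      frame_ms = 20,             # Shannon-energy envelope frame
      hop_ms = 10,
      threshold_frac = 0.3,      # candidate peaks >= 30% of envelope max
      min_gap_ms = 50,
      min_cycle_ms = 400,
      max_cycle_ms = 1500,
      refine_factor = 0.8,       # threshold multiplier on >1500 ms gaps
      floor_frac = 0.05,
      window_s = 5               # fragment length
    ),
    short_term = list(
      frame_ms = 25,             # MFCC analysis frame
      hop_ms = 10,
      n_filters = 26,
      n_coeffs = 13
    ),
    nca = list(
      regularization = NULL,     # NULL -> 1/n
      max_rows = 500,            # subsample cap for the pairwise objective
      threshold = "mean",        # weight cutoff: "mean" or a number
      select_k = NULL            # alternative: keep the top-k short-term features
    ),
    classification = list(
      train_frac = 0.7,
      split_mode = "fragment"    # "fragment" (protocol-faithful) or "recording"
    )
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) stop("unknown config block(s): ", paste(bad, collapse = ", "))
  for (blk in names(overrides)) {
    ov <- overrides[[blk]]
    bad <- setdiff(names(ov), names(defaults[[blk]]))
    if (length(bad)) {
      stop("unknown option(s) in config block '", blk, "': ",
           paste(bad, collapse = ", "))
    }
    defaults[[blk]][names(ov)] <- ov
  }
  structure(defaults, class = "pcg_config")
}

#' Read / write a pipeline configuration as JSON
#'
#' @param config A [pcg_config()].
#' @param path JSON file path.
#' @return `write_config` returns `path` invisibly; `read_config` the config.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pcg_config, raw)
}
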