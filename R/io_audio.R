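#' Construct a heart-sound recording
#'
#' A `pcg_recording` holds a single-channel sampled pressure waveform together
#' with its sampling rate and a binary screening label. It is the long-term
#' unit of analysis: long-term features are computed once per recording and
#' broadcast to all of its five-second fragments.
#'
#' @param samples Numeric vector of amplitudes (arbitrary units).
#' @param fs Sampling rate in Hz (> 0).
#' @param id Recording identifier.
#' @param label One of `"normal"`, `"abnormal"`, `"unknown"`.
#' @param source_path Optional path the samples were read from.
#' @return An object of class `pcg_recording`.
#' @export
pcg_recording <- function(samples, fs, id = "rec", label = "unknown",
                          source_path = NA_character_) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    stop("degenerate input: recording '", id, "' has no samples")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a single positive number")
  }
  label <- match.arg(label, c("normal", "abnormal", "unknown"))
  structure(
    list(id = as.character(id), samples = samples, fs = as.numeric(fs),
         label = label, source_path = source_path),
    class = "pcg_recording"
  )
}

#' @export
print.pcg_recording <- function(x, ...) {
  cat(sprintf("<pcg_recording '%s': %.2f s at %g Hz, label=%s>\n",
              x$id, length(x$samples) / x$fs, x$fs, x$label))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec A `pcg_recording`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) length(rec$samples) / rec$fs

valid_labels <- c("normal", "abnormal", "unknown")

# ---- WAV (RIFF PCM) ---------------------------------------------------------

read_wav_pcm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fs <- NULL; n_channels <- NULL; bits <- NULL; audio_format <- NULL
  data <- NULL
  repeat {
    chunk_id <- readChar(con, 4, useBytes = TRUE)
    if (length(chunk_id) == 0L || nchar(chunk_id) < 4L) break
    chunk_size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(chunk_size) == 0L) break
    if (identical(chunk_id, "fmt ")) {
      audio_format <- readBin(con, "integer", 1, size = 2, endian = "little")
      n_channels <- readBin(con, "integer", 1, size = 2, endian = "little")
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little")) # byte rate
      invisible(readBin(con, "integer", 1, size = 2, endian = "little")) # block align
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      extra <- chunk_size - 16L
      if (extra > 0L) invisible(readBin(con, "raw", extra))
    } else if (identical(chunk_id, "data")) {
      if (is.null(bits)) stop("malformed WAV (data before fmt): ", path)
      n_vals <- chunk_size %/% (bits %/% 8L)
      if (bits == 16L) {
        data <- readBin(con, "integer", n_vals, size = 2, signed = TRUE,
                        endian = "little") / 32768
      } else if (bits == 8L) {
        data <- (readBin(con, "integer", n_vals, size = 1, signed = FALSE,
                         endian = "little") - 128) / 128
      } else if (bits == 32L && identical(audio_format, 3L)) {
        data <- readBin(con, "double", n_vals, size = 4, endian = "little")
      } else {
        stop("unsupported WAV sample format (", bits, "-bit, format ",
             audio_format, "): ", path)
      }
    } else {
      # skip unknown chunk (word-aligned)
      invisible(readBin(con, "raw", chunk_size + chunk_size %% 2L))
    }
    if (!is.null(data) && !is.null(fs)) break
  }
  if (is.null(fs) || is.null(data)) stop("malformed WAV file: ", path)
  if (length(data) == 0L) stop("degenerate input: empty audio in ", path)
  if (n_channels > 1L) {
    warning("multi-channel WAV; taking first channel: ", path)
    data <- data[seq(1L, length(data), by = n_channels)]
  }
  list(samples = data, fs = fs)
}

#' Write a recording as 16-bit PCM WAV
#'
#' Samples are written as-is when already within \[-1, 1\], otherwise scaled
#' by the maximum absolute amplitude first.
#'
#' @param rec A `pcg_recording`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path) {
  x <- rec$samples
  m <- max(abs(x))
  if (m > 1) x <- x / m
  pcm <- as.integer(pmax(pmin(round(x * 32768), 32767), -32768))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(rec$fs), con, size = 4, endian = "little")
  writeBin(as.integer(rec$fs * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

# ---- WFDB (format 16) -------------------------------------------------------

read_wfdb <- function(path) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("WFDB header not found: ", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  head_fields <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  record <- head_fields[1]
  n_sig <- as.integer(head_fields[2])
  fs <- if (length(head_fields) >= 3) as.numeric(head_fields[3]) else 250
  n_samp <- if (length(head_fields) >= 4) as.integer(head_fields[4]) else NA_integer_
  sig <- strsplit(trimws(lines[2]), "[ \t]+")[[1]]
  dat_file <- sig[1]
  fmt <- sub("x.*", "", sig[2])
  if (fmt != "16") stop("unsupported WFDB signal format '", sig[2], "' in ", hea)
  gain <- if (length(sig) >= 3) as.numeric(sub("[(/].*", "", sig[3])) else 200
  if (!is.finite(gain) || gain == 0) gain <- 200
  dat_path <- file.path(dirname(hea), dat_file)
  if (!file.exists(dat_path)) stop("WFDB data file not found: ", dat_path)
  con <- file(dat_path, "rb")
  on.exit(close(con))
  n_read <- if (is.na(n_samp)) file.size(dat_path) %/% 2L else n_samp * n_sig
  raw <- readBin(con, "integer", n_read, size = 2, signed = TRUE, endian = "little")
  if (length(raw) == 0L) stop("degenerate input: empty WFDB signal in ", dat_path)
  if (n_sig > 1L) {
    warning("multi-signal WFDB record; taking first signal: ", record)
    raw <- raw[seq(1L, length(raw), by = n_sig)]
  }
  list(samples = raw / gain, fs = fs, id = record)
}

#' Read a heart-sound recording from WAV or WFDB
#'
#' The format is chosen by extension: `.wav` is parsed as RIFF PCM; `.hea`
#' (or an extensionless record name whose `.hea` exists) as a WFDB
#' header/data pair (format 16).
#'
#' @param path Path to a `.wav` file, a `.hea` header, or a WFDB record name.
#' @param label Label to attach: `"normal"`, `"abnormal"` or `"unknown"`.
#' @param id Recording id; defaults to the file base name.
#' @return A [pcg_recording()] at the file's native sampling rate.
#' @export
read_recording <- function(path, label = "unknown", id = NULL) {
  label <- match.arg(label, valid_labels)
  if (grepl("\\.wav$", path, ignore.case = TRUE)) {
    if (!file.exists(path)) stop("file not found: ", path)
    w <- read_wav_pcm(path)
    if (is.null(id)) id <- sub("\\.wav$", "", basename(path), ignore.case = TRUE)
    pcg_recording(w$samples, w$fs, id = id, label = label, source_path = path)
  } else {
    w <- read_wfdb(path)
    pcg_recording(w$samples, w$fs, id = if (is.null(id)) w$id else id,
                  label = label, source_path = path)
  }
}

# ---- resampling -------------------------------------------------------------

#' Resample a recording to a target rate
#'
#' Rate conversion uses polyphase FIR filtering ([signal::resample()]), which
#' applies anti-aliasing when downsampling. The dataset convention for this
#' pipeline is 2000 Hz.
#'
#' @param rec A `pcg_recording`.
#' @param target_fs Target sampling rate in Hz.
#' @return The recording at `target_fs`; returned unchanged if already there.
#' @export
resample_recording <- function(rec, target_fs = 2000) {
  stopifnot(target_fs > 0)
  if (rec$fs == target_fs) return(rec)
  frac <- rational_approx(target_fs / rec$fs)
  y <- signal::resample(rec$samples, frac[1], frac[2])
  n_expect <- round(length(rec$samples) * target_fs / rec$fs)
  if (length(y) > n_expect) y <- y[seq_len(n_expect)]
  pcg_recording(y, target_fs, id = rec$id, label = rec$label,
                source_path = rec$source_path)
}

# p/q with q bounded; continued-fraction expansion
rational_approx <- function(x, max_den = 10000L) {
  a <- floor(x); p0 <- 1; q0 <- 0; p1 <- a; q1 <- 1; r <- x - a
  while (r > 1e-12 && q1 < max_den) {
    x <- 1 / r; a <- floor(x); r <- x - a
    p <- a * p1 + p0; q <- a * q1 + q0
    if (q > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p; q1 <- q
  }
  c(as.integer(p1), as.integer(q1))
}

# ---- manifest ---------------------------------------------------------------

#' Load a dataset manifest
#'
#' A manifest is a CSV with columns `path,label` mapping each recording file
#' to its `"normal"`/`"abnormal"` label. Relative paths are resolved against
#' the manifest's directory.
#'
#' @param path Path to the manifest CSV.
#' @return A data frame of class `pcg_manifest` with columns `path`, `label`
#'   and attribute `root`.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  if (!all(c("path", "label") %in% names(df))) {
    stop("manifest must have columns 'path' and 'label': ", path)
  }
  bad <- setdiff(unique(df$label), valid_labels)
  if (length(bad)) {
    stop("invalid label(s) ", paste(sQuote(bad), collapse = ", "),
         "; allowed: ", paste(valid_labels, collapse = ", "))
  }
  dup <- df$path[duplicated(df$path)]
  if (length(dup)) stop("duplicate manifest path(s): ", paste(unique(dup), collapse = ", "))
  attr(df, "root") <- dirname(normalizePath(path, mustWork = FALSE))
  class(df) <- c("pcg_manifest", class(df))
  df
}

manifest_paths <- function(manifest) {
  root <- attr(manifest, "root")
  ifelse(grepl("^(/|[A-Za-z]:)", manifest$path), manifest$path,
         file.path(root, manifest$path))
}

# ---- feature tables ---------------------------------------------------------

#' Write / read a feature table
#'
#' Feature tables are CSVs with header
#' `recording_id,fragment_index,<features...>,label`. Values round-trip at
#' 15 significant digits; the feature-set tag is restored from the column
#' layout on read.
#'
#' @param table A feature table data frame (see [merge_feature_tables()]).
#' @param path CSV path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns the table.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(!anyDuplicated(names(table)))
  out <- table
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) formatC(v, digits = 15, format = "g"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(recording_id = "character"))
  feat <- setdiff(names(df), c("recording_id", "fragment_index", "label"))
  df[feat] <- lapply(df[feat], as.numeric)
  attr(df, "feature_set") <- guess_feature_set(feat)
  df
}

guess_feature_set <- function(feature_names) {
  stf <- short_term_feature_names()
  ltf <- long_term_feature_names()
  if (identical(feature_names, c(stf, ltf))) "LSTF"
  else if (identical(feature_names, stf)) "STF"
  else if (identical(feature_names, ltf)) "LTF"
  else if (all(feature_names %in% stf)) "SSTF"
  else if (all(feature_names %in% c(stf, ltf))) "SLSTF"
  else "custom"
}
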