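#' Accelerometer recording container
#'
#' A calibrated single-channel accelerometer time series in microvolts.
#' The sub-xiphoid sensor used for reflux detection is sampled at 200 Hz;
#' any uniform rate is accepted but scoring assumes the default chain
#' (200 Hz in, 60 Hz after decimation).
#'
#' @param samples numeric vector of amplitudes (uV). Must be finite.
#' @param fs sampling rate in Hz (default 200).
#' @param start_time optional wall-clock start (`POSIXct` or text).
#' @param channel_label free-text channel description.
#' @param subject_id free-text subject identifier.
#' @return an object of class `accel_recording` with fields `samples`,
#'   `fs`, `start_time`, `channel_label`, `subject_id`.
#' @seealso [read_recording()], [duration_seconds()]
#' @export
recording <- function(samples, fs = 200, start_time = NULL,
                      channel_label = "accel-z", subject_id = "") {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  bad <- which(!is.finite(samples))
  if (length(bad))
    stop(sprintf("non-finite sample value at position %d", bad[1L]),
         call. = FALSE)
  structure(
    list(samples = samples, fs = fs, start_time = start_time,
         channel_label = channel_label, subject_id = subject_id),
    class = "accel_recording")
}

#' Esophageal pH recording container
#'
#' @param samples numeric vector of pH values. Values must lie in
#'   \[0, 14\]; `NA` marks invalid samples, which are excluded from
#'   episode statistics downstream.
#' @param fs sampling rate in Hz (pH loggers typically 0.25--1 Hz).
#' @param start_time optional wall-clock start.
#' @param subject_id free-text subject identifier.
#' @return an object of class `ph_recording`.
#' @export
ph_recording <- function(samples, fs = 1, start_time = NULL, subject_id = "") {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  finite <- is.finite(samples)
  out_of_range <- which(finite & (samples < 0 | samples > 14))
  if (length(out_of_range))
    stop(sprintf("pH value %.3g at position %d outside [0, 14]",
                 samples[out_of_range[1L]], out_of_range[1L]), call. = FALSE)
  samples[!finite] <- NA_real_
  structure(
    list(samples = samples, fs = fs, start_time = start_time,
         subject_id = subject_id),
    class = "ph_recording")
}

#' Recording duration in seconds
#'
#' @param x an `accel_recording` or `ph_recording`.
#' @return length(samples) / fs, in seconds.
#' @export
duration_seconds <- function(x) {
  stopifnot(inherits(x, c("accel_recording", "ph_recording")))
  length(x$samples) / x$fs
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf("<accel_recording> %s: %d samples @ %g Hz (%.1f s)\n",
              if (nzchar(x$subject_id)) x$subject_id else "(unnamed)",
              length(x$samples), x$fs, duration_seconds(x)))
  invisible(x)
}

#' @export
print.ph_recording <- function(x, ...) {
  cat(sprintf("<ph_recording> %s: %d samples @ %g Hz (%.1f s), %d invalid\n",
              if (nzchar(x$subject_id)) x$subject_id else "(unnamed)",
              length(x$samples), x$fs, duration_seconds(x),
              sum(is.na(x$samples))))
  invisible(x)
}

#' Calibration from raw file units to microvolts
#'
#' WAV files carry no physical units, so the scale factor must be supplied
#' externally. Calibration is linear: `uv = raw * volts_per_unit + dc_offset`.
#'
#' @param volts_per_unit scale factor (uV per raw unit); must be non-zero.
#' @param dc_offset additive offset in uV applied after scaling.
#' @export
calibration_spec <- function(volts_per_unit = 1, dc_offset = 0) {
  if (!is.finite(volts_per_unit) || volts_per_unit == 0)
    stop("`volts_per_unit` must be finite and non-zero", call. = FALSE)
  structure(list(volts_per_unit = volts_per_unit, dc_offset = dc_offset),
            class = "calibration_spec")
}

# Reads a two-column numeric CSV (header optional); returns list(time, value).
read_two_col_csv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(trimws(first)))
    stop(sprintf("empty input file: %s", path), call. = FALSE)
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(first, ",", fixed = TRUE)[[1L]][1L])))
  df <- utils::read.csv(path, header = has_header,
                        colClasses = c("numeric", "numeric"),
                        col.names = c("time", "value"))
  if (!nrow(df)) stop(sprintf("empty input file: %s", path), call. = FALSE)
  bad <- which(!is.finite(df$time))
  if (length(bad))
    stop(sprintf("%s: non-numeric/NaN time at data row %d", path, bad[1L]),
         call. = FALSE)
  df
}

# Infers fs from uniform timestamps; refuses to resample jittered files.
infer_fs <- function(time_s, path, tol_fraction = 0.1) {
  if (length(time_s) < 2L)
    stop(sprintf("%s: need at least 2 rows to infer sampling rate", path),
         call. = FALSE)
  dt <- diff(time_s)
  med <- stats::median(dt)
  if (med <= 0)
    stop(sprintf("%s: timestamps not strictly increasing", path), call. = FALSE)
  jitter <- max(abs(dt - med))
  if (jitter >= tol_fraction * med)
    stop(sprintf(paste0("%s: non-uniform sampling (max timestamp jitter ",
                        "%.3g s exceeds %.3g s = 0.1/fs); refusing to ",
                        "resample silently"),
                 path, jitter, tol_fraction * med), call. = FALSE)
  fs <- 1 / med
  # snap to an integer rate when the residual is pure float noise
  if (abs(fs - round(fs)) < 1e-6 * fs) fs <- round(fs)
  fs
}

# Minimal RIFF/WAVE reader: mono PCM 16/32-bit or IEEE float32.
# No R package in the runtime reads WAV, and the format is a fixed
# little-endian chunk layout, so it is parsed directly.
read_wav_mono <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readChar(con, 4L, useBytes = TRUE), "RIFF"))
    stop(sprintf("%s: not a RIFF file (offset 0)", path), call. = FALSE)
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  if (!identical(readChar(con, 4L, useBytes = TRUE), "WAVE"))
    stop(sprintf("%s: not a WAVE file (offset 8)", path), call. = FALSE)
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(size) == 0L) break
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1L, size = 2L,
                               endian = "little", signed = FALSE),
        n_channels   = readBin(con, "integer", 1L, size = 2L,
                               endian = "little", signed = FALSE),
        sample_rate  = readBin(con, "integer", 1L, size = 4L,
                               endian = "little"),
        byte_rate    = readBin(con, "integer", 1L, size = 4L,
                               endian = "little"),
        block_align  = readBin(con, "integer", 1L, size = 2L,
                               endian = "little", signed = FALSE),
        bits         = readBin(con, "integer", 1L, size = 2L,
                               endian = "little", signed = FALSE))
      if (size > 16L) invisible(readBin(con, "raw", size - 16L))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2L == 1L) invisible(readBin(con, "raw", 1L))
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop(sprintf("%s: missing fmt or data chunk", path), call. = FALSE)
  if (fmt$n_channels != 1L)
    stop(sprintf("%s: %d channels; only mono WAV is supported",
                 path, fmt$n_channels), call. = FALSE)
  n <- length(data_raw) %/% (fmt$bits %/% 8L)
  x <- if (fmt$audio_format == 1L && fmt$bits == 16L) {
    readBin(data_raw, "integer", n, size = 2L, endian = "little")
  } else if (fmt$audio_format == 1L && fmt$bits == 32L) {
    readBin(data_raw, "integer", n, size = 4L, endian = "little")
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    readBin(data_raw, "numeric", n, size = 4L, endian = "little")
  } else {
    stop(sprintf("%s: unsupported WAV encoding (format %d, %d bit)",
                 path, fmt$audio_format, fmt$bits), call. = FALSE)
  }
  list(samples = as.numeric(x), fs = fmt$sample_rate)
}

# Writes a mono float32 WAV (used in tests and by the simulator).
write_wav_mono <- function(samples, fs, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples)
  data_bytes <- 4L * n
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(3L, con, size = 2L, endian = "little")           # IEEE float
  writeBin(1L, con, size = 2L, endian = "little")           # mono
  writeBin(as.integer(fs), con, size = 4L, endian = "little")
  writeBin(as.integer(fs * 4L), con, size = 4L, endian = "little")
  writeBin(4L, con, size = 2L, endian = "little")
  writeBin(32L, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4L, endian = "little")
  writeBin(as.numeric(samples), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an accelerometer recording
#'
#' CSV is the canonical interchange format: two columns `time_s,value_uV`
#' (header optional), UTF-8, `.` decimal. Timestamps must be uniform to
#' within 0.1/fs; jittered files are refused rather than silently
#' resampled, since resampling would corrupt the scoring thresholds.
#' WAV (mono PCM16/PCM32/float32) is supported for long recordings, with
#' the physical calibration supplied via `calibration` because WAV carries
#' no units.
#'
#' @param path input file path.
#' @param format `"csv"` or `"wav"`.
#' @param calibration a [calibration_spec()]; raw values are mapped to uV
#'   as `raw * volts_per_unit + dc_offset`.
#' @param fs_override optional sampling rate (Hz) overriding the inferred
#'   (CSV) or header (WAV) rate.
#' @param subject_id optional subject identifier stored on the recording.
#' @return an [recording()] object in microvolts.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("time_s,value_uV", "0,1", "0.005,2", "0.01,3"), f)
#' rec <- read_recording(f)
#' rec$fs     # 200
#' @export
read_recording <- function(path, format = c("csv", "wav"),
                           calibration = calibration_spec(),
                           fs_override = NULL, subject_id = "") {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  stopifnot(inherits(calibration, "calibration_spec"))
  if (format == "csv") {
    df <- read_two_col_csv(path)
    bad <- which(!is.finite(df$value))
    if (length(bad))
      stop(sprintf("%s: non-finite value at data row %d", path, bad[1L]),
           call. = FALSE)
    fs <- if (is.null(fs_override)) infer_fs(df$time, path) else fs_override
    raw <- df$value
  } else {
    wav <- read_wav_mono(path)
    fs <- if (is.null(fs_override)) wav$fs else fs_override
    raw <- wav$samples
  }
  if (!length(raw)) stop(sprintf("empty input file: %s", path), call. = FALSE)
  recording(raw * calibration$volts_per_unit + calibration$dc_offset,
            fs = fs, subject_id = subject_id)
}

#' Read an esophageal pH recording
#'
#' CSV with columns `time_s,ph` (header optional). Values are validated
#' to the pH scale \[0, 14\].
#'
#' @inheritParams read_recording
#' @return a [ph_recording()].
#' @export
read_ph <- function(path, fs_override = NULL, subject_id = "") {
  if (!file.exists(path))
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  df <- read_two_col_csv(path)
  bad <- which(!is.finite(df$value))
  if (length(bad))
    stop(sprintf("%s: non-finite pH at data row %d", path, bad[1L]),
         call. = FALSE)
  out <- which(df$value < 0 | df$value > 14)
  if (length(out))
    stop(sprintf("%s: pH value %.3g at data row %d outside [0, 14]",
                 path, df$value[out[1L]], out[1L]), call. = FALSE)
  fs <- if (is.null(fs_override)) infer_fs(df$time, path) else fs_override
  ph_recording(df$value, fs = fs, subject_id = subject_id)
}

#' Write a recording to CSV (or WAV)
#'
#' The CSV round-trip is lossless to well below 1e-9 uV (values written
#' with 15 significant digits).
#'
#' @param rec an `accel_recording` or `ph_recording`.
#' @param path output path.
#' @param format `"csv"` or `"wav"` (WAV only for accelerometer data).
#' @export
write_recording <- function(rec, path, format = c("csv", "wav")) {
  format <- match.arg(format)
  if (format == "wav") {
    stopifnot(inherits(rec, "accel_recording"))
    return(invisible(write_wav_mono(rec$samples, rec$fs, path)))
  }
  value_name <- if (inherits(rec, "ph_recording")) "ph" else "value_uV"
  t <- seq_along(rec$samples) - 1
  lines <- c(paste0("time_s,", value_name),
             paste0(format(t / rec$fs, digits = 15, scientific = FALSE,
                           trim = TRUE),
                    ",",
                    format(rec$samples, digits = 15, trim = TRUE)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a report object to JSON or CSV
#'
#' JSON round-trips all scalar fields exactly (full double precision).
#' Contingency tables are written as a 2x2 CSV layout when `format="csv"`.
#'
#' @param report an `accel_report`, `boix_ochoa_result` or
#'   `contingency_table`.
#' @param path output path.
#' @param format `"json"` or `"csv"`.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  if (!is.character(format) ||
      !all(format %in% c("json", "csv")) || !length(format))
    stop(sprintf("unknown report format: %s",
                 paste(format, collapse = ", ")), call. = FALSE)
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  } else if (inherits(report, "contingency_table")) {
    df <- data.frame(
      row.names = c("accel_positive", "accel_negative"),
      ph_positive = c(report$both_pos, report$accel_neg_ph_pos),
      ph_negative = c(report$accel_pos_ph_neg, report$both_neg))
    utils::write.csv(df, path)
  } else {
    flat <- unclass(report)
    flat <- flat[vapply(flat, function(v)
      is.atomic(v) && length(v) == 1L, logical(1L))]
    utils::write.csv(as.data.frame(flat), path, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a JSON report written by [write_report()]
#'
#' @param path JSON file path.
#' @param class optional class to restore on the result.
#' @export
read_report <- function(path, class = NULL) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(class)) class(x) <- class
  x
}

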