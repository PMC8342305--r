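#' Stage-2 scoring configuration
#'
#' Parameters of the accelerometric score computed on the cleaned 60 Hz
#' signal: spectrogram segmentation, the 0--30 Hz focused band, the 1 uV
#' positivity cut-off, and the episode/pattern feature settings.
#'
#' @param spec_segment spectrogram segment length in samples (default
#'   512, i.e. 8.53 s columns at 60 Hz).
#' @param focus_low,focus_high focused frequency band in Hz (default
#'   0--30); the score is the mean bin amplitude within this band.
#' @param positive_cutoff positivity threshold in uV (default 1.0); a
#'   recording is called positive when the mean amplitude is greater
#'   than or equal to the cut-off (inclusive).
#' @param rhythmic_rate_per_min expected burst rate of the rhythmic
#'   pattern, events/min (default 4; matched with +/-50% tolerance).
#' @param continuous_min_duration minimum uninterrupted episode length
#'   for the "continuous" pattern, seconds (default 1200 s = 20 min).
#' @export
score_config <- function(spec_segment = 512, focus_low = 0, focus_high = 30,
                         positive_cutoff = 1.0, rhythmic_rate_per_min = 4,
                         continuous_min_duration = 1200) {
  if (focus_low >= focus_high)
    stop("`focus_low` must be below `focus_high`", call. = FALSE)
  if (positive_cutoff <= 0)
    stop("`positive_cutoff` must be > 0", call. = FALSE)
  structure(list(spec_segment = as.integer(spec_segment),
                 focus_low = focus_low, focus_high = focus_high,
                 positive_cutoff = positive_cutoff,
                 rhythmic_rate_per_min = rhythmic_rate_per_min,
                 continuous_min_duration = continuous_min_duration),
            class = "score_config")
}

#' Amplitude spectrogram of the cleaned 60 Hz signal
#'
#' Non-overlapping `spec_segment`-sample windows with per-window mean
#' removal and a rectangular window; amplitudes use the same single-sided
#' uV normalisation as [segment_fft()]. At the default 60 Hz rate the
#' frequency axis spans 0--30 Hz.
#'
#' @param clean a 60 Hz [recording()] (output of [clean_recording()] or
#'   [reconstruct_and_decimate()]).
#' @param cfg a [score_config()].
#' @return a `reflux_spectrogram`: list with `times` (column centers, s),
#'   `freqs` (Hz), `amplitudes` (freq x time matrix, uV), `col_dur` (s)
#'   and `gap_times_s` carried over from the cleaning stage.
#' @export
spectrogram <- function(clean, cfg = score_config()) {
  stopifnot(inherits(clean, "accel_recording"))
  n <- cfg$spec_segment
  n_col <- length(clean$samples) %/% n
  if (n_col < 1L)
    stop(sprintf("recording too short for a spectrogram column: need %d samples (%.2f s at %g Hz)",
                 n, n / clean$fs, clean$fs), call. = FALSE)
  cols <- lapply(seq_len(n_col), function(i) {
    s <- segment_spectrum_of(clean$samples[((i - 1L) * n + 1L):(i * n)],
                             clean$fs, index = i, detrend = TRUE,
                             window = "rectangular")
    s$amplitudes
  })
  col_dur <- n / clean$fs
  structure(list(
    times = (seq_len(n_col) - 0.5) * col_dur,
    freqs = (0:(n %/% 2)) * clean$fs / n,
    amplitudes = do.call(cbind, cols),
    col_dur = col_dur,
    gap_times_s = attr(clean, "gap_times_s") %||% numeric(0),
    excised_fraction = attr(clean, "excised_fraction") %||% 0),
    class = "reflux_spectrogram")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

band_rows <- function(spec, cfg) {
  spec$freqs >= cfg$focus_low & spec$freqs <= cfg$focus_high
}

#' Mean focused-band amplitude (the accelerometric score)
#'
#' Arithmetic mean, in uV, of every spectrogram cell whose frequency lies
#' in the focused band, across all columns. Columns lost to artifact
#' excision are absent from the spectrogram, not zero, so they do not
#' dilute the score.
#'
#' @param spec a [spectrogram()].
#' @param cfg a [score_config()].
#' @return the mean amplitude in uV.
#' @export
mean_amplitude <- function(spec, cfg = score_config()) {
  stopifnot(inherits(spec, "reflux_spectrogram"))
  mean(spec$amplitudes[band_rows(spec, cfg), , drop = FALSE])
}

#' Positivity call
#'
#' A recording is abnormal ("positive", i.e. indicative of pronounced
#' reflux) when its mean focused-band amplitude is at least the cut-off
#' (inclusive: a score of exactly 1.0 uV is positive).
#'
#' @param score mean amplitude in uV (must be >= 0).
#' @param cfg a [score_config()].
#' @export
classify <- function(score, cfg = score_config()) {
  if (!is.finite(score) || score < 0)
    stop("score must be a finite non-negative amplitude in uV", call. = FALSE)
  score >= cfg$positive_cutoff
}

# Active-column runs, broken at excision gaps. Returns run lengths and
# the per-column activity vector.
column_runs <- function(spec, cfg) {
  means <- colMeans(spec$amplitudes[band_rows(spec, cfg), , drop = FALSE])
  active <- means >= cfg$positive_cutoff
  n_col <- length(active)
  # a gap at time g (compressed timeline) breaks any run spanning the
  # column that contains it
  break_after <- rep(FALSE, n_col)
  for (g in spec$gap_times_s) {
    j <- min(max(ceiling(g / spec$col_dur), 1L), n_col)
    break_after[j] <- TRUE
  }
  run_id <- cumsum(c(TRUE, diff(active) != 0) |
                     c(FALSE, break_after[-n_col]))
  runs <- data.frame(
    active = tapply(active, run_id, `[`, 1L),
    len = as.integer(table(run_id)))
  list(col_means = means, active = active,
       episode_lengths = runs$len[runs$active])
}

#' Episode features of a scored recording
#'
#' A spectrogram column is "active" when its focused-band mean is at or
#' above the positivity cut-off; episodes are maximal runs of active
#' columns (runs are broken at artifact-excision gaps, so artifacts never
#' extend an episode).
#'
#' @param spec a [spectrogram()].
#' @param cfg a [score_config()].
#' @return list with `pct_time_positive` (%), `max_column_amplitude`
#'   (uV), `longest_episode` (s), `n_episodes`, and the per-column means.
#' @export
episode_features <- function(spec, cfg = score_config()) {
  r <- column_runs(spec, cfg)
  list(pct_time_positive = 100 * mean(r$active),
       max_column_amplitude = max(r$col_means),
       longest_episode = if (length(r$episode_lengths))
         max(r$episode_lengths) * spec$col_dur else 0,
       n_episodes = length(r$episode_lengths),
       col_means = r$col_means)
}

# 1 s RMS envelope of the cleaned signal (finer than the 8.53 s columns,
# needed to resolve a 4/min burst rate).
rms_envelope <- function(clean, block_s = 1) {
  n <- floor(clean$fs * block_s)
  n_blk <- length(clean$samples) %/% n
  vapply(seq_len(n_blk), function(i)
    sqrt(mean(clean$samples[((i - 1L) * n + 1L):(i * n)]^2)), numeric(1L))
}

#' Temporal pattern label
#'
#' Labels the recording's activity pattern: `negative` (no episodes),
#' `continuous` (an uninterrupted episode of at least
#' `continuous_min_duration`, by default >20 min), `rhythmic` (the 1 s
#' RMS envelope of the cleaned signal has a dominant autocorrelation
#' period within +/-50% of the configured ~4/min burst rate, the
#' up-and-down waveform attributed to gastric contractions pushing
#' refluxate through an open sphincter), else `intermittent`.
#'
#' @param features output of [episode_features()].
#' @param clean the cleaned 60 Hz recording (for the envelope).
#' @param cfg a [score_config()].
#' @return one of `"negative"`, `"intermittent"`, `"rhythmic"`,
#'   `"continuous"`.
#' @export
pattern_label <- function(features, clean, cfg = score_config()) {
  if (features$n_episodes == 0L) return("negative")
  if (features$longest_episode >= cfg$continuous_min_duration)
    return("continuous")
  env <- rms_envelope(clean)
  if (length(env) >= 30L) {
    e <- env - mean(env)
    if (stats::sd(e) > 0) {
      max_lag <- min(60L, length(e) %/% 3L)
      ac <- stats::acf(e, lag.max = max_lag, plot = FALSE)$acf[-1L]
      lags <- seq_along(ac)
      cand <- lags >= 5L
      if (any(cand)) {
        best <- lags[cand][which.max(ac[cand])]
        period <- 60 / cfg$rhythmic_rate_per_min
        if (ac[best] >= 0.25 &&
            best >= period / 1.5 && best <= period * 1.5)
          return("rhythmic")
      }
    }
  }
  "intermittent"
}

#' End-to-end accelerometric reflux score
#'
#' Runs the full chain on a raw recording: mains notch, segment FFT,
#' de-jitter, artifact excision, reconstruction/decimation, spectrogram,
#' mean-amplitude score, positivity call, episode features and pattern
#' label.
#'
#' @param rec a raw [recording()] (typically 200 Hz).
#' @param qc a [qc_config()].
#' @param cfg a [score_config()].
#' @return an `accel_report` with fields `subject_id`, `score_uV`,
#'   `positive`, `pct_time_positive`, `max_uV`, `longest_episode_s`,
#'   `n_episodes`, `pattern`, `excised_fraction`, `retained_minutes`,
#'   `short_recording` (TRUE when less than 30 min of signal survives
#'   quality control, flagging a score of reduced reliability) and
#'   `config_echo`.
#' @export
accel_score <- function(rec, qc = qc_config(), cfg = score_config()) {
  clean <- clean_recording(rec, qc)
  spec <- spectrogram(clean, cfg)
  score <- mean_amplitude(spec, cfg)
  feats <- episode_features(spec, cfg)
  retained_min <- duration_seconds(clean) / 60
  structure(list(
    subject_id = rec$subject_id,
    score_uV = score,
    positive = classify(score, cfg),
    pct_time_positive = feats$pct_time_positive,
    max_uV = feats$max_column_amplitude,
    longest_episode_s = feats$longest_episode,
    n_episodes = feats$n_episodes,
    pattern = pattern_label(feats, clean, cfg),
    excised_fraction = spec$excised_fraction,
    retained_minutes = retained_min,
    short_recording = retained_min < 30,
    config_echo = list(qc = unclass(qc), score = unclass(cfg))),
    class = "accel_report")
}

#' @export
print.accel_report <- function(x, ...) {
  cat(sprintf("<accel_report> %s\n", if (nzchar(x$subject_id))
    x$subject_id else "(unnamed)"))
  cat(sprintf("  score        %.4g uV (%s, cut-off %g uV)\n", x$score_uV,
              if (x$positive) "POSITIVE" else "negative",
              x$config_echo$score$positive_cutoff))
  cat(sprintf("  %% time +     %.1f%%   episodes %d   longest %.1f s\n",
              x$pct_time_positive, x$n_episodes, x$longest_episode_s))
  cat(sprintf("  pattern      %s   excised %.1f%%%s\n", x$pattern,
              x$excised_fraction,
              if (x$short_recording) "   [<30 min retained]" else ""))
  invisible(x)
}

#' Direct spectral score (validation path)
#'
#' Estimates the accelerometric score directly from the retained,
#' de-jittered stage-1 spectra, skipping reconstruction: the focused-band
#' amplitude sum of each retained segment is divided by the number of
#' stage-2 band bins (`spec_segment/2 + 1` for the full 0--30 Hz band)
#' and averaged over segments. For band-limited inputs at bin-centered
#' frequencies this estimates the canonical reconstruction-path score;
#' the reconstruction path remains canonical.
#'
#' @param specs stage-1 spectra after [dejitter()]/[excise_artifacts()].
#' @param qc the [qc_config()] used upstream.
#' @param cfg a [score_config()].
#' @return score estimate in uV.
#' @export
direct_score <- function(specs, qc = qc_config(), cfg = score_config()) {
  kept <- Filter(function(s) !s$excised, specs)
  if (!length(kept)) stop("all segments excised", call. = FALSE)
  freqs2 <- (0:(cfg$spec_segment %/% 2)) * qc$resample_fs / cfg$spec_segment
  n_band2 <- sum(freqs2 >= cfg$focus_low & freqs2 <= cfg$focus_high)
  per_seg <- vapply(kept, function(s) {
    in_band <- s$freqs >= cfg$focus_low & s$freqs <= cfg$focus_high
    sum(s$amplitudes[in_band]) / n_band2
  }, numeric(1L))
  mean(per_seg)
}
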