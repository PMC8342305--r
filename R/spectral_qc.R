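#' Stage-1 quality-control configuration
#'
#' Parameters of the spectral cleaning chain applied to the raw 200 Hz
#' accelerometer signal: mains notch, fixed-size FFT segmentation,
#' spectral de-jittering (noise flooring), broadband artifact excision,
#' and reconstruction/decimation to a clean 60 Hz signal.
#'
#' @param notch_freq mains frequency to reject, Hz (default 60).
#' @param notch_quality dimensionless Q of the IIR notch (default 30,
#'   i.e. 2 Hz -3 dB bandwidth at 60 Hz).
#' @param fft_segment FFT segment length in samples; must be a power of
#'   two (default 1024, i.e. 5.12 s at 200 Hz).
#' @param dejitter_floor spectral noise floor subtracted from every bin
#'   amplitude, uV (default 200); results below zero clamp to zero.
#' @param artifact_band_low lower edge (exclusive) of the artifact watch
#'   band, Hz (default 60): a segment is discarded when any de-jittered
#'   bin strictly above this frequency exceeds `artifact_threshold`.
#' @param artifact_threshold excision threshold, uV (default 200, strict
#'   `>` comparison).
#' @param resample_fs output rate of the cleaned signal, Hz (default 60).
#' @param detrend_segments remove the mean of each segment before the
#'   FFT (default TRUE).
#' @param window `"rectangular"` (default; keeps the uV amplitude
#'   interpretation exact at bin-centered frequencies) or `"hann"`.
#' @return a `qc_config` list.
#' @export
qc_config <- function(notch_freq = 60, notch_quality = 30,
                      fft_segment = 1024, dejitter_floor = 200,
                      artifact_band_low = 60, artifact_threshold = 200,
                      resample_fs = 60, detrend_segments = TRUE,
                      window = c("rectangular", "hann")) {
  window <- match.arg(window)
  if (fft_segment < 2 || bitwAnd(fft_segment, fft_segment - 1L) != 0)
    stop("`fft_segment` must be a power of two", call. = FALSE)
  if (dejitter_floor < 0) stop("`dejitter_floor` must be >= 0", call. = FALSE)
  if (resample_fs <= 0) stop("`resample_fs` must be > 0", call. = FALSE)
  structure(list(notch_freq = notch_freq, notch_quality = notch_quality,
                 fft_segment = as.integer(fft_segment),
                 dejitter_floor = dejitter_floor,
                 artifact_band_low = artifact_band_low,
                 artifact_threshold = artifact_threshold,
                 resample_fs = resample_fs,
                 detrend_segments = isTRUE(detrend_segments),
                 window = window),
            class = "qc_config")
}

# Phase-continuous signal extension by autoregressive (Burg)
# extrapolation. Reflection padding leaves a carrier-phase jump at the
# junction that rings a high-Q notch at its own centre frequency; linear
# prediction extends narrowband content (the 60 Hz mains tone in
# particular) smoothly, so the edge transient is negligible.
ar_extend <- function(x, pad, side = c("pre", "post")) {
  side <- match.arg(side)
  n <- length(x)
  m <- min(n, 2048L)
  seg <- if (side == "pre") rev(x[seq_len(m)]) else x[(n - m + 1L):n]
  ext <- rep(seg[m], pad)
  if (stats::sd(seg) > 0) {
    fit <- tryCatch(
      stats::ar(seg, aic = FALSE, order.max = min(24L, m - 1L),
                method = "burg"),
      error = function(e) NULL)
    if (!is.null(fit) && fit$order > 0)
      ext <- as.numeric(stats::predict(fit, n.ahead = pad,
                                       se.fit = FALSE))
  }
  if (side == "pre") rev(ext) else ext
}

# Zero-phase filtering with AR-extrapolated edge padding, which keeps
# forward-backward transients out of the analysed span.
filtfilt_padded <- function(b, a, x, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- min(n - 1L, 1024L)
  xp <- c(ar_extend(x, pad, "pre"), x, ar_extend(x, pad, "post"))
  y1 <- as.numeric(signal::filter(b, a, xp))
  y2 <- rev(as.numeric(signal::filter(b, a, rev(y1))))
  y2[(pad + 1L):(pad + n)]
}

# RBJ biquad notch coefficients (b, a) for centre f0 and quality Q.
notch_coefficients <- function(f0, fs, Q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  list(b = b, a = a)
}

#' Zero-phase 60 Hz band-stop filter
#'
#' Removes mains interference (NICU electronic equipment) with a
#' second-order IIR notch applied forward and backward
#' ([signal::filtfilt()]), so the passband (0--30 Hz reflux band) is left
#' intact in both amplitude (<1% change) and phase.
#'
#' @param rec an [recording()].
#' @param cfg a [qc_config()].
#' @return a recording of the same length and rate.
#' @export
notch_filter <- function(rec, cfg = qc_config()) {
  stopifnot(inherits(rec, "accel_recording"))
  if (rec$fs <= 2 * cfg$notch_freq)
    stop(sprintf("sampling rate %g Hz too low for a %g Hz notch",
                 rec$fs, cfg$notch_freq), call. = FALSE)
  co <- notch_coefficients(cfg$notch_freq, rec$fs, cfg$notch_quality)
  y <- filtfilt_padded(co$b, co$a, rec$samples)
  recording(y, fs = rec$fs, start_time = rec$start_time,
            channel_label = rec$channel_label, subject_id = rec$subject_id)
}

# Single-sided amplitude spectrum of one segment. Normalised so a
# bin-centered sinusoid of amplitude A uV reads A uV at its bin
# (DC and Nyquist carry 1x normalisation).
segment_spectrum_of <- function(x, fs, index, detrend, window) {
  n <- length(x)
  w <- if (window == "hann") 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)
       else rep(1, n)
  if (detrend) x <- x - mean(x)
  X <- stats::fft(x * w)[1:(n %/% 2 + 1)]
  scale <- sum(w)
  amp <- Mod(X) / scale
  amp[2:(n %/% 2)] <- 2 * amp[2:(n %/% 2)]
  structure(list(index = index,
                 freqs = (0:(n %/% 2)) * fs / n,
                 amplitudes = amp,
                 phases = Arg(X),
                 excised = FALSE,
                 reason = NA_character_,
                 n = n, fs = fs),
            class = "segment_spectrum")
}

#' Fixed-size FFT segmentation
#'
#' Cuts the recording into consecutive non-overlapping segments of
#' `fft_segment` samples (a trailing remainder shorter than one segment
#' is dropped) and computes the single-sided amplitude spectrum of each,
#' with per-segment mean removal and a rectangular window by default.
#' Phases are retained so segments can be inverse-transformed after
#' de-jittering.
#'
#' @inheritParams notch_filter
#' @return a list of `segment_spectrum` objects.
#' @export
segment_fft <- function(rec, cfg = qc_config()) {
  stopifnot(inherits(rec, "accel_recording"))
  n <- cfg$fft_segment
  n_seg <- length(rec$samples) %/% n
  if (n_seg < 1L)
    stop(sprintf("recording too short: %d samples < one %d-sample segment",
                 length(rec$samples), n), call. = FALSE)
  lapply(seq_len(n_seg), function(i) {
    segment_spectrum_of(rec$samples[((i - 1L) * n + 1L):(i * n)], rec$fs,
                        index = i, detrend = cfg$detrend_segments,
                        window = cfg$window)
  })
}

#' Spectral de-jitter (noise flooring)
#'
#' Subtracts `dejitter_floor` uV from every bin amplitude, clamping
#' negative results to zero. Phases are unchanged. Accepts a single
#' segment spectrum or a list of them.
#'
#' @param spec a `segment_spectrum` or list of them.
#' @param cfg a [qc_config()].
#' @export
dejitter <- function(spec, cfg = qc_config()) {
  if (inherits(spec, "segment_spectrum")) {
    spec$amplitudes <- pmax(spec$amplitudes - cfg$dejitter_floor, 0)
    spec
  } else {
    lapply(spec, dejitter, cfg = cfg)
  }
}

#' Broadband artifact excision
#'
#' Marks a segment as excised when any de-jittered bin at a frequency
#' strictly above `artifact_band_low` exceeds `artifact_threshold`
#' (strict `>`): such broadband high-frequency content indicates motion
#' or handling noise, and the entire segment (its full 0--100 Hz
#' spectrum) is excluded from all downstream scoring.
#'
#' @param specs list of de-jittered `segment_spectrum` objects.
#' @param cfg a [qc_config()].
#' @return the list with `excised`/`reason` flags set; the number of
#'   excised segments is attached as attribute `n_excised`.
#' @export
excise_artifacts <- function(specs, cfg = qc_config()) {
  out <- lapply(specs, function(s) {
    hot <- s$freqs > cfg$artifact_band_low &
           s$amplitudes > cfg$artifact_threshold
    if (any(hot)) {
      k <- which(hot)[which.max(s$amplitudes[which(hot)])]
      s$excised <- TRUE
      s$reason <- sprintf("%.4g uV at %.4g Hz exceeds %g uV above %g Hz",
                          s$amplitudes[k], s$freqs[k],
                          cfg$artifact_threshold, cfg$artifact_band_low)
    }
    s
  })
  structure(out, n_excised = sum(vapply(out, `[[`, logical(1L), "excised")))
}

# Inverse of segment_spectrum_of for a rectangular window: rebuilds the
# time-domain segment from single-sided amplitudes and original phases.
inverse_segment <- function(s) {
  n <- s$n
  half <- n %/% 2
  amp <- s$amplitudes
  amp[2:half] <- amp[2:half] / 2          # undo single-sided doubling
  X <- complex(modulus = amp * n, argument = s$phases)
  full <- c(X, Conj(X[half:2]))
  Re(stats::fft(full, inverse = TRUE)) / n
}

# Polyphase rational resampler: zero-stuff by p, zero-phase FIR low-pass
# (Hamming fir1, double-pass via filtfilt), keep every q-th sample.
resample_poly <- function(x, p, q, n_taps = 511, cutoff_frac = 0.98) {
  up <- numeric(length(x) * p)
  up[seq(1L, length(up), by = p)] <- x * p
  wc <- min(1 / p, 1 / q) * cutoff_frac   # fraction of upsampled Nyquist
  h <- as.numeric(signal::fir1(n_taps, wc))
  y <- filtfilt_padded(h, 1, up, pad = min(length(up) - 1L, 2L * n_taps))
  y[seq(1L, length(y), by = q)]
}

#' Reconstruct the cleaned signal and decimate to 60 Hz
#'
#' Each retained (non-excised) segment is inverse-transformed from its
#' de-jittered single-sided spectrum using the original phases (floored
#' bins contribute nothing); retained segments are concatenated in order,
#' excised segments are removed outright (not zero-filled) with the gap
#' positions logged; the result is low-pass filtered below the new
#' Nyquist (zero-phase FIR, >40 dB stopband) and resampled at
#' `resample_fs` by polyphase rational resampling (200 to 60 Hz = x3/10).
#'
#' @param specs list of `segment_spectrum` objects after [dejitter()] and
#'   [excise_artifacts()].
#' @param cfg a [qc_config()].
#' @return an [recording()] at `resample_fs` Hz with attributes
#'   `gap_times_s` (positions, in the output's compressed timeline, where
#'   excised segments were removed), `excised_fraction` (percent of
#'   segments excised) and `n_excised`.
#' @export
reconstruct_and_decimate <- function(specs, cfg = qc_config()) {
  stopifnot(length(specs) > 0L, inherits(specs[[1L]], "segment_spectrum"))
  excised <- vapply(specs, `[[`, logical(1L), "excised")
  if (all(excised)) {
    reasons <- vapply(specs, `[[`, character(1L), "reason")
    stop(sprintf("all %d segments excised; first reason: %s",
                 length(specs), reasons[1L]), call. = FALSE)
  }
  kept <- specs[!excised]
  fs_in <- kept[[1L]]$fs
  seg_dur <- kept[[1L]]$n / fs_in
  x <- unlist(lapply(kept, inverse_segment), use.names = FALSE)

  # gap positions in the compressed (post-removal) timeline
  gaps <- numeric(0)
  retained_before <- cumsum(!excised)
  if (any(excised))
    gaps <- unique(retained_before[excised]) * seg_dur

  # rationalise the rate ratio (rates are specified to <= mHz precision)
  p <- round(cfg$resample_fs * 1000)
  q <- round(fs_in * 1000)
  g <- gcd_int(p, q)
  y <- resample_poly(x, p %/% g, q %/% g)
  out <- recording(y, fs = cfg$resample_fs)
  attr(out, "gap_times_s") <- gaps
  attr(out, "n_excised") <- sum(excised)
  attr(out, "excised_fraction") <- 100 * mean(excised)
  out
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Run the full stage-1 chain
#'
#' Convenience wrapper: notch, segment FFT, de-jitter, artifact excision,
#' reconstruction and decimation.
#'
#' @inheritParams notch_filter
#' @return the cleaned 60 Hz recording (see [reconstruct_and_decimate()]),
#'   with the de-jittered stage-1 spectra attached as attribute `specs`.
#' @export
clean_recording <- function(rec, cfg = qc_config()) {
  specs <- segment_fft(notch_filter(rec, cfg), cfg)
  specs <- excise_artifacts(dejitter(specs, cfg), cfg)
  out <- reconstruct_and_decimate(specs, cfg)
  attr(out, "specs") <- specs
  out
}
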