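# Independent oracles and small fixture builders used across the suite.

# Single-sided amplitude at frequency f by direct DFT projection
# (independent of the package's FFT path).
dft_amp <- function(z, f, fs) {
  n <- length(z)
  2 * Mod(sum(z * exp(-2i * pi * f * (0:(n - 1)) / fs))) / n
}

# Brute-force acid-episode scan: walks the trace sample by sample.
brute_force_episodes <- function(x, fs, threshold = 4, min_s = 15) {
  eps <- list()
  i <- 1L; n <- length(x)
  while (i <= n) {
    if (!is.na(x[i]) && x[i] < threshold) {
      j <- i
      while (j < n && !is.na(x[j + 1L]) && x[j + 1L] < threshold) j <- j + 1L
      if ((j - i + 1L) / fs >= min_s)
        eps[[length(eps) + 1L]] <- c(start_s = (i - 1L) / fs, end_s = j / fs)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(eps)) return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  as.data.frame(do.call(rbind, eps))
}

# Spectrogram object with prescribed per-column focused-band means:
# every cell of column j equals col_value[j].
flat_spectrogram <- function(col_values, n_freq = 257L, col_dur = 512 / 60,
                             gaps = numeric(0)) {
  structure(list(
    times = (seq_along(col_values) - 0.5) * col_dur,
    freqs = seq(0, 30, length.out = n_freq),
    amplitudes = matrix(rep(col_values, each = n_freq), nrow = n_freq),
    col_dur = col_dur, gap_times_s = gaps, excised_fraction = 0),
    class = "reflux_spectrogram")
}

# Segment spectrum with amplitudes set at chosen frequencies (others 0);
# frequency grid of a 1024-sample / 200 Hz segment.
synthetic_spectrum <- function(amp_at = numeric(0), index = 1L,
                               n = 1024L, fs = 200) {
  freqs <- (0:(n %/% 2)) * fs / n
  amps <- numeric(length(freqs))
  for (f in names(amp_at)) {
    k <- which.min(abs(freqs - as.numeric(f)))
    amps[k] <- amp_at[[f]]
  }
  structure(list(index = index, freqs = freqs, amplitudes = amps,
                 phases = numeric(length(freqs)), excised = FALSE,
                 reason = NA_character_, n = n, fs = fs),
            class = "segment_spectrum")
}

# Frequencies bin-centered in both analysis stages (1024@200 and
# 512@60 Hz): multiples of 0.5859375 Hz.
common_grid_hz <- function(k) 0.5859375 * k

tone <- function(f, amp, dur_s, fs = 200) {
  amp * sin(2 * pi * f * (0:(dur_s * fs - 1)) / fs)
}
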