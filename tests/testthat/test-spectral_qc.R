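test_that("the 60 Hz notch removes mains by >=40 dB and spares the reflux band", {
  fs <- 200
  rec <- recording(tone(60, 100, 10), fs)
  resid <- dft_amp(notch_filter(rec)$samples, 60, fs)
  expect_lte(resid, 1)                       # 100 uV tone -> <=1 uV
  expect_gte(20 * log10(100 / resid), 40)

  passband <- dft_amp(notch_filter(recording(tone(5, 100, 10), fs))$samples,
                      5, fs)
  expect_gte(passband, 99)
  expect_lte(passband, 101)

  zero <- notch_filter(recording(rep(0, 2000), fs))
  expect_equal(zero$samples, rep(0, 2000))

  expect_error(notch_filter(recording(1:100, fs = 100)), "too low")
})

test_that("segment FFT recovers bin-centered amplitudes against a direct DFT oracle", {
  fs <- 200
  f <- 26 * fs / 1024                        # exactly bin-centered
  x <- 350 * sin(2 * pi * f * (0:1023) / fs)
  s <- segment_fft(recording(x, fs))[[1]]
  k <- which.min(abs(s$freqs - f))
  expect_equal(s$amplitudes[k], 350, tolerance = 1e-6)
  expect_equal(s$amplitudes[k], dft_amp(x, f, fs), tolerance = 1e-6)
  expect_lt(max(s$amplitudes[-k]), 1e-6)     # no leakage off the bin

  # constant signal vanishes under detrending
  sc <- segment_fft(recording(rep(7, 1024), fs))[[1]]
  expect_lt(max(sc$amplitudes), 1e-9)

  # trailing remainder shorter than a segment is dropped
  expect_length(segment_fft(recording(rnorm(2049), fs)), 2L)
  expect_error(segment_fft(recording(rnorm(1000), fs)), "too short")
})

test_that("de-jittering floors bin amplitudes by exactly 200 uV with clamping", {
  s <- synthetic_spectrum(c(`5.078125` = 350, `10.15625` = 150))
  d <- dejitter(s)
  k350 <- which(s$amplitudes == 350)
  k150 <- which(s$amplitudes == 150)
  expect_equal(d$amplitudes[k350], 150)
  expect_equal(d$amplitudes[k150], 0)
  expect_identical(d$phases, s$phases)

  z <- synthetic_spectrum()
  expect_equal(dejitter(z)$amplitudes, z$amplitudes)
})

test_that("spectral energy never increases through de-jittering", {
  set.seed(101)
  for (i in 1:20) {
    s <- segment_fft(recording(rnorm(1024, 0, 300), 200))[[1]]
    expect_lte(sum(dejitter(s)$amplitudes^2), sum(s$amplitudes^2))
  }
})

test_that("artifact excision applies the strict >200 uV / >60 Hz rule per segment", {
  hot <- synthetic_spectrum(c(`65.0390625` = 450), index = 1L)  # 250 post-floor
  boundary <- synthetic_spectrum(c(`65.0390625` = 400), index = 2L)  # 200 exactly
  low_band <- synthetic_spectrum(c(`30.078125` = 10200), index = 3L)  # 10000 at 30 Hz
  out <- excise_artifacts(dejitter(list(hot, boundary, low_band)))
  expect_true(out[[1]]$excised)
  expect_match(out[[1]]$reason, "exceeds 200")
  expect_false(out[[2]]$excised)             # strict inequality at 200
  expect_false(out[[3]]$excised)             # rule only applies above 60 Hz
  expect_equal(attr(out, "n_excised"), 1L)

  # excision is a pure per-segment predicate: order-independent
  rev_out <- excise_artifacts(dejitter(list(low_band, boundary, hot)))
  expect_equal(vapply(rev_out, `[[`, logical(1), "excised"),
               rev(vapply(out, `[[`, logical(1), "excised")))
})

test_that("reconstruction inverts the floored spectrum and decimates to 60 Hz", {
  fs <- 200
  f <- 26 * fs / 1024
  s <- segment_fft(recording(300 * sin(2 * pi * f * (0:1023) / fs), fs))[[1]]
  out <- reconstruct_and_decimate(dejitter(list(s)))
  expect_equal(out$fs, 60)
  # oracle: analytic inverse of the floored spectrum is a 100 uV tone
  mid <- out$samples[80:230]                 # clear of resampler edges
  expect_equal(sqrt(mean(mid^2)) * sqrt(2), 100, tolerance = 0.02)

  zero <- segment_fft(recording(rep(0, 2048), fs))
  zout <- reconstruct_and_decimate(dejitter(zero))
  expect_lt(max(abs(zout$samples)), 1e-9)
})

test_that("excised segments are removed from the timeline, with gaps logged", {
  fs <- 200
  specs <- segment_fft(recording(rnorm(3 * 1024, 0, 10), fs))
  specs[[2]]$excised <- TRUE
  specs[[2]]$reason <- "test"
  out <- reconstruct_and_decimate(specs)
  expect_lte(abs(length(out$samples) - round(2 * (1024 / 200) * 60)), 1)
  expect_equal(attr(out, "gap_times_s"), 1024 / 200)
  expect_equal(attr(out, "excised_fraction"), 100 / 3, tolerance = 1e-9)

  for (s in seq_along(specs)) specs[[s]]$excised <- TRUE
  expect_error(reconstruct_and_decimate(specs), "all 3 segments excised")
})

test_that("band-limited tones above the floor survive the pipeline to within 2%", {
  fs <- 200
  amps <- c(500, 700, 450)
  freqs <- common_grid_hz(c(4, 17, 30))      # < 25 Hz, bin-centered twice
  t <- (0:(fs * 120 - 1)) / fs
  x <- rowSums(sapply(seq_along(freqs),
                      function(i) amps[i] * sin(2 * pi * freqs[i] * t)))
  clean <- clean_recording(recording(x, fs))
  sg <- spectrogram(clean)
  k <- round(freqs * 512 / 60) + 1
  recovered <- sg$amplitudes[k, 3]
  expect_equal(recovered, amps - 200, tolerance = 0.02)
})

test_that("the decimated output carries no significant aliased energy", {
  # a 35 Hz tone (above the 30 Hz output Nyquist, below the artifact
  # band) must be rejected by the anti-alias filter, not folded back
  fs <- 200
  f35 <- 179 * fs / 1024                     # ~34.96 Hz, bin-centered
  x <- tone(f35, 1000, 60)
  cfg <- qc_config(dejitter_floor = 0)       # isolate the resampling path
  out <- reconstruct_and_decimate(segment_fft(recording(x, fs), cfg), cfg)
  expect_lt(sum(out$samples^2) / sum(x^2), 0.01)
})
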