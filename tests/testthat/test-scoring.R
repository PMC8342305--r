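test_that("spectrogram columns recover bin-centered amplitudes at 60 Hz", {
  fs <- 60
  f <- 43 * fs / 512                          # 5.0391 Hz, bin-centered
  x <- 2 * sin(2 * pi * f * (0:1023) / fs)
  sg <- spectrogram(recording(x, fs))
  expect_equal(ncol(sg$amplitudes), 2L)
  k <- which.min(abs(sg$freqs - f))
  expect_equal(sg$amplitudes[k, 1], 2, tolerance = 1e-6)
  expect_equal(sg$amplitudes[k, 2], 2, tolerance = 1e-6)
  expect_equal(sg$amplitudes[k, 1], dft_amp(x[1:512], f, fs),
               tolerance = 1e-6)
  expect_equal(range(sg$freqs), c(0, 30))

  zg <- spectrogram(recording(rep(0, 1024), fs))
  expect_true(all(zg$amplitudes == 0))

  expect_equal(ncol(spectrogram(recording(rnorm(600), fs))$amplitudes), 1L)
  expect_error(spectrogram(recording(rnorm(500), fs)), "8.53")
})

test_that("the score is the arithmetic mean over focused-band cells", {
  expect_equal(mean_amplitude(flat_spectrogram(rep(1.5, 4))), 1.5)
  expect_equal(mean_amplitude(flat_spectrogram(c(0, 0, 2, 2))), 1.0)

  # a single active bin among 257, one column
  sg <- flat_spectrogram(0, n_freq = 257)
  sg$amplitudes[44, 1] <- 2
  expect_equal(mean_amplitude(sg), 2 / 257)
})

test_that("positivity is inclusive at the 1 uV cut-off", {
  expect_true(classify(1.0))
  expect_false(classify(0.999))
  expect_false(classify(0))
  expect_error(classify(-0.1), "non-negative")
})

test_that("episodes are maximal runs of active columns", {
  f1 <- episode_features(flat_spectrogram(c(0.2, 1.5, 1.5, 0.2)))
  expect_equal(f1$n_episodes, 1L)
  expect_equal(f1$longest_episode, 2 * 512 / 60, tolerance = 1e-9)
  expect_equal(f1$pct_time_positive, 50)
  expect_equal(f1$max_column_amplitude, 1.5)

  f2 <- episode_features(flat_spectrogram(c(0.2, 0.4, 0.1)))
  expect_equal(f2$n_episodes, 0L)
  expect_equal(f2$pct_time_positive, 0)

  f3 <- episode_features(flat_spectrogram(c(2, 0.5, 2)))
  expect_equal(f3$n_episodes, 2L)
})

test_that("excision gaps break episode runs", {
  col_dur <- 512 / 60
  joined <- episode_features(flat_spectrogram(c(2, 2, 2, 2)))
  expect_equal(joined$n_episodes, 1L)
  # a gap inside the second column splits the run
  split <- episode_features(flat_spectrogram(c(2, 2, 2, 2),
                                             gaps = 1.5 * col_dur))
  expect_equal(split$n_episodes, 2L)
  expect_equal(split$longest_episode, 2 * col_dur)
})

test_that("pattern labels follow the published archetypes", {
  # negative: no activity at all
  quiet <- simulate_pair(sim_config(seed = 21, duration_s = 240,
                                    n_reflux_events = 0, n_artifacts = 0))
  expect_equal(accel_score(quiet$accel)$pattern, "negative")

  # continuous: one uninterrupted >20 min episode
  cont <- simulate_pair(sim_config(seed = 22, duration_s = 1800,
                                   n_reflux_events = 1,
                                   event_duration_s = 1500,
                                   n_artifacts = 0))
  rc <- accel_score(cont$accel)
  expect_equal(rc$pattern, "continuous")
  expect_gte(rc$longest_episode_s, 1200)

  # rhythmic: ~4/min gated bursts; oracle = direct autocorrelation of
  # the 1 s envelope peaking near a 15 s lag
  ryt <- simulate_pair(sim_config(seed = 23, duration_s = 300,
                                  n_reflux_events = 1,
                                  event_duration_s = 240, rhythmic = TRUE,
                                  n_artifacts = 0))
  clean <- clean_recording(ryt$accel)
  env <- vapply(seq_len(length(clean$samples) %/% 60), function(i)
    sqrt(mean(clean$samples[((i - 1) * 60 + 1):(i * 60)]^2)), numeric(1))
  ac <- acf(env - mean(env), lag.max = 40, plot = FALSE)$acf[-1]
  expect_true(abs(which.max(ac[5:40]) + 4 - 15) <= 3)
  expect_equal(accel_score(ryt$accel)$pattern, "rhythmic")

  # intermittent: isolated short episodes, no dominant periodicity
  int <- simulate_pair(sim_config(seed = 24, duration_s = 600,
                                  n_reflux_events = 2, n_artifacts = 0))
  expect_equal(accel_score(int$accel)$pattern, "intermittent")
})

test_that("the score is scale-equivariant and time-reversal stable (floor 0)", {
  set.seed(31)
  fs <- 200
  x <- rnorm(fs * 60, 0, 50) + tone(common_grid_hz(9), 300, 60)
  qc0 <- qc_config(dejitter_floor = 0)
  score_of <- function(z)
    mean_amplitude(spectrogram(clean_recording(recording(z, fs), qc0)))
  s1 <- score_of(x)
  expect_equal(score_of(3 * x), 3 * s1, tolerance = 1e-6)
  # adding an in-band burst never decreases the score
  burst <- tone(common_grid_hz(6), 200, 60)
  expect_gte(score_of(x + burst) + 1e-9, s1)
  # classification is invariant to time reversal
  expect_equal(classify(score_of(rev(x))), classify(s1))
})

test_that("direct and reconstruction scoring paths agree on band-limited input", {
  fs <- 200
  t <- (0:(fs * 60 - 1)) / fs
  amps <- c(600, 500, 800)
  freqs <- common_grid_hz(c(5, 14, 27))
  x <- rowSums(sapply(seq_along(freqs),
                      function(i) amps[i] * sin(2 * pi * freqs[i] * t)))
  clean <- clean_recording(recording(x, fs))
  canonical <- mean_amplitude(spectrogram(clean))
  direct <- direct_score(attr(clean, "specs"))
  expect_equal(direct, canonical, tolerance = 0.05)
})

test_that("end-to-end report invariants hold on simulated recordings", {
  p <- simulate_pair(sim_config(seed = 41, duration_s = 300,
                                n_reflux_events = 2))
  rep <- accel_score(p$accel)
  expect_identical(rep$positive, rep$score_uV >= 1)
  expect_gte(rep$pct_time_positive, 0)
  expect_lte(rep$pct_time_positive, 100)
  expect_lte(rep$longest_episode_s, duration_seconds(p$accel))
  expect_true(rep$short_recording)           # 5 min < 30 min
  expect_equal(rep$config_echo$score$positive_cutoff, 1)
})
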