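test_that("identical seeds reproduce recordings bit-identically", {
  a <- simulate_pair(sim_config(seed = 9, duration_s = 60))
  b <- simulate_pair(sim_config(seed = 9, duration_s = 60))
  expect_identical(a$accel$samples, b$accel$samples)
  expect_identical(a$ph$samples, b$ph$samples)
  expect_identical(a$truth, b$truth)

  c_ <- simulate_pair(sim_config(seed = 10, duration_s = 60))
  expect_false(identical(a$accel$samples, c_$accel$samples))
})

test_that("a quiet configuration scores near zero and negative", {
  p <- simulate_pair(sim_config(seed = 12, duration_s = 120,
                                n_reflux_events = 0, mains_amp_uv = 0,
                                baseline_noise_uv = 0.01, n_artifacts = 0))
  rep <- accel_score(p$accel)
  expect_lt(rep$score_uV, 0.1)
  expect_false(rep$positive)
  expect_false(p$truth$expected_positive)
})

test_that("acid events produce exactly the expected pH episodes", {
  cfg <- sim_config(seed = 13, duration_s = 600, n_reflux_events = 3,
                    acid_fraction = 1, n_artifacts = 0)
  p <- simulate_pair(cfg)
  eps <- detect_acid_episodes(p$ph)
  expect_equal(nrow(eps), 3L)
  # each detected episode overlaps exactly one ground-truth interval
  for (i in seq_len(nrow(eps)))
    expect_true(any(eps$start_s[i] < p$truth$event_intervals$end_s &
                    eps$end_s[i] > p$truth$event_intervals$start_s))
})

test_that("non-acid events never cross the acid threshold", {
  for (seed in 14:18) {
    p <- simulate_pair(sim_config(seed = seed, duration_s = 600,
                                  n_reflux_events = 3, acid_fraction = 0,
                                  n_artifacts = 0))
    expect_gte(min(p$ph$samples), 4.3)
    expect_equal(nrow(detect_acid_episodes(p$ph)), 0L)
  }
})

test_that("mains contamination alone never scores positive", {
  for (amp in c(100, 500)) {
    p <- simulate_pair(sim_config(seed = 19, duration_s = 120,
                                  n_reflux_events = 0, n_artifacts = 0,
                                  mains_amp_uv = amp))
    expect_lt(accel_score(p$accel)$score_uV, 0.5)
  }
})

test_that("injected artifacts are excised with full recall", {
  p <- simulate_pair(sim_config(seed = 20, duration_s = 300,
                                n_reflux_events = 1, n_artifacts = 3))
  specs <- excise_artifacts(dejitter(segment_fft(notch_filter(p$accel))))
  excised <- which(vapply(specs, `[[`, logical(1), "excised"))
  seg_dur <- 1024 / 200
  # artifacts are generated wholly inside one analysis segment
  art <- p$truth$artifact_intervals
  art_segs <- floor(art$start_s / seg_dur) + 1
  expect_true(all(floor((art$end_s - 1e-9) / seg_dur) + 1 == art_segs))
  expect_true(all(art_segs %in% excised))          # 100% recall
})

test_that("cohort prevalence and seeding behave deterministically", {
  base <- sim_config(seed = 25, duration_s = 60, n_artifacts = 0)
  none <- cohort(10, 0, base)
  expect_true(all(!vapply(none, function(p) p$truth$expected_positive,
                          logical(1))))
  all_pos <- cohort(10, 1, base)
  expect_true(all(vapply(all_pos, function(p) p$truth$expected_positive,
                         logical(1))))

  half_a <- cohort(20, 0.5, base)
  half_b <- cohort(20, 0.5, base)
  n_pos <- sum(vapply(half_a, function(p) p$truth$expected_positive,
                      logical(1)))
  expect_identical(n_pos,
                   sum(vapply(half_b, function(p) p$truth$expected_positive,
                              logical(1))))
  expect_gt(n_pos, 3)
  expect_lt(n_pos, 17)
  expect_identical(half_a[[7]]$accel$samples, half_b[[7]]$accel$samples)
})

test_that("impossible event placements raise a generation error", {
  expect_error(simulate_pair(sim_config(seed = 1, duration_s = 30,
                                        n_reflux_events = 5,
                                        event_duration_s = 20)),
               "cannot fit")
})

test_that("simulation output round-trips through the on-disk layout", {
  dir <- withr::local_tempdir()
  p <- simulate_pair(sim_config(seed = 26, duration_s = 60))
  write_simulation(p, dir)
  acc <- read_recording(file.path(dir, "subject_001_accel.csv"))
  expect_equal(acc$fs, 200)
  expect_equal(acc$samples, p$accel$samples, tolerance = 1e-9)
  truth <- jsonlite::read_json(file.path(dir, "subject_001_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$expected_positive, p$truth$expected_positive)
})
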