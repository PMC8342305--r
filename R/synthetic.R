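#' Simulation configuration for paired accelerometer + pH recordings
#'
#' The generator emulates the signal structure the scoring pipeline
#' assumes: Gaussian baseline sensor noise, 60 Hz mains contamination,
#' low-frequency band-limited reflux bursts (optionally gated at ~4/min
#' to mimic the rhythmic pattern), broadband 61--100 Hz motion/handling
#' artifacts, and a paired pH trace in which only acid events dip below
#' pH 4.
#'
#' Event and artifact amplitudes are per-bin single-sided spectral
#' targets, referenced to a `ref_segment`-sample analysis window: an
#' `event_amp_uv` of 600 produces ~600 uV bins before de-jittering, so
#' ~400 uV survives the 200 uV spectral floor. Amplitudes below the
#' floor vanish entirely after de-jittering — "weak event" configs are
#' deliberate negative controls. These amplitudes are a synthetic
#' calibration chosen to straddle the 1 uV score cut-off, not a
#' physiological one.
#'
#' @param seed integer RNG seed; identical seeds give bit-identical
#'   output.
#' @param duration_s recording length in seconds (default 600).
#' @param fs accelerometer sampling rate, Hz (default 200).
#' @param ph_fs pH sampling rate, Hz (default 1).
#' @param baseline_noise_uv baseline sensor noise RMS, uV (default 30;
#'   its per-bin spectral amplitude is far below the 200 uV floor).
#' @param mains_amp_uv 60 Hz mains amplitude, uV (default 100).
#' @param n_reflux_events number of reflux bursts (default 1 in 10 min,
#'   i.e. the 6-events-per-hour default rate pro-rata).
#' @param event_amp_uv per-bin spectral amplitude of a burst, uV
#'   (default 600).
#' @param event_band frequency band of the bursts, Hz (default
#'   c(0.5, 10)).
#' @param event_duration_s burst duration, s (default 20).
#' @param rhythmic gate each burst at `4/min` sub-bursts (default
#'   FALSE).
#' @param n_artifacts number of broadband artifacts (default 1).
#' @param artifact_amp_uv per-bin spectral amplitude of an artifact in
#'   the 61--100 Hz band, uV (default 800, comfortably above the
#'   excision threshold after de-jittering).
#' @param artifact_duration_s artifact duration, s (default 2; artifacts
#'   are centered inside one reference analysis window so each lands in
#'   a single FFT segment).
#' @param acid_fraction probability that an event is acid (default 0.3:
#'   roughly 70% of reflux in preterm infants is non-acid).
#' @param ph_baseline baseline esophageal pH (default 6.5; milk feeds
#'   keep the preterm stomach near-neutral).
#' @param ph_drop_depth pH drop of an acid event (default 4, reaching
#'   ~pH 2.5).
#' @param ph_recovery_s exponential pH recovery time constant after an
#'   event, s (default 30).
#' @param ref_segment reference analysis window for the spectral
#'   amplitude calibration, samples (default 1024).
#' @export
sim_config <- function(seed = 1L, duration_s = 600, fs = 200, ph_fs = 1,
                       baseline_noise_uv = 30, mains_amp_uv = 100,
                       n_reflux_events = 1L, event_amp_uv = 600,
                       event_band = c(0.5, 10), event_duration_s = 20,
                       rhythmic = FALSE, n_artifacts = 1L,
                       artifact_amp_uv = 800, artifact_duration_s = 2,
                       acid_fraction = 0.3, ph_baseline = 6.5,
                       ph_drop_depth = 4, ph_recovery_s = 30,
                       ref_segment = 1024) {
  stopifnot(duration_s > 0, fs > 0, ph_fs > 0,
            baseline_noise_uv >= 0, mains_amp_uv >= 0,
            event_amp_uv >= 0, artifact_amp_uv >= 0,
            acid_fraction >= 0, acid_fraction <= 1,
            length(event_band) == 2L, event_band[1L] > 0,
            event_band[2L] > event_band[1L], event_band[2L] < fs / 2)
  structure(as.list(environment()), class = "sim_config")
}

# Band-limited unit-RMS Gaussian noise via FFT masking (deterministic
# under the current RNG state).
band_noise <- function(n, fs, band) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)                    # two-sided frequency
  X[f < band[1L] | f > band[2L]] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / stats::sd(y)
}

# Raised-cosine on/off envelope over [0, dur] with ramp_s edges.
burst_envelope <- function(n, fs, ramp_s = 1) {
  t <- (seq_len(n) - 1) / fs
  dur <- n / fs
  env <- rep(1, n)
  r <- pmin(ramp_s, dur / 4)
  up <- t < r
  down <- t > dur - r
  env[up] <- 0.5 - 0.5 * cos(pi * t[up] / r)
  env[down] <- 0.5 - 0.5 * cos(pi * (dur - t[down]) / r)
  env
}

# Draw k non-overlapping intervals of length dur inside [pad, total-pad],
# with at least gap_s clearance; error if they cannot fit.
place_intervals <- function(k, dur, total, gap_s = 2, pad = 2,
                            max_tries = 200L) {
  if (k == 0L) return(numeric(0))
  if (k * (dur + gap_s) + 2 * pad > total)
    stop(sprintf("cannot fit %d non-overlapping %.3g s intervals in %.3g s",
                 k, dur, total), call. = FALSE)
  for (i in seq_len(max_tries)) {
    starts <- sort(stats::runif(k, pad, total - pad - dur))
    if (k == 1L || all(diff(starts) >= dur + gap_s)) return(starts)
  }
  stop(sprintf("failed to place %d non-overlapping intervals after %d tries",
               k, max_tries), call. = FALSE)
}

#' Simulate one paired accelerometer + pH recording
#'
#' Returns the accelerometer trace, the paired pH trace and the ground
#' truth used to generate them. The pH trace dips below the acid
#' threshold only for acid events; non-acid events produce shallow dips
#' clamped (by construction) above pH 4.3, mirroring the clinically
#' observed accelerometry-positive/pH-silent reflux.
#'
#' @param cfg a [sim_config()].
#' @return list with `accel` ([recording()]), `ph` ([ph_recording()])
#'   and `truth` (list: `event_intervals` data.frame with `start_s`,
#'   `end_s`, `is_acid`; `artifact_intervals` data.frame;
#'   `expected_positive`).
#' @export
simulate_pair <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(cfg$seed)

  n <- round(cfg$duration_s * cfg$fs)
  t <- (seq_len(n) - 1) / cfg$fs
  accel <- stats::rnorm(n, 0, cfg$baseline_noise_uv) +
    cfg$mains_amp_uv * sin(2 * pi * 60 * t)

  # spectral-amplitude -> time-RMS calibration (reference segment)
  bins_in_ref <- function(band) {
    f <- (0:(cfg$ref_segment %/% 2)) * cfg$fs / cfg$ref_segment
    max(sum(f >= band[1L] & f <= band[2L]), 1L)
  }

  # reflux events
  ev_starts <- place_intervals(cfg$n_reflux_events, cfg$event_duration_s,
                               cfg$duration_s)
  ev_sigma <- cfg$event_amp_uv * sqrt(bins_in_ref(cfg$event_band) / 2)
  is_acid <- if (cfg$n_reflux_events > 0L)
    stats::runif(cfg$n_reflux_events) < cfg$acid_fraction else logical(0)
  for (s in ev_starts) {
    i0 <- round(s * cfg$fs) + 1L
    m <- round(cfg$event_duration_s * cfg$fs)
    idx <- i0:(i0 + m - 1L)
    env <- burst_envelope(m, cfg$fs)
    if (cfg$rhythmic) {
      period <- 60 / 4                    # 4 sub-bursts per minute
      tt <- (seq_len(m) - 1) / cfg$fs
      gate <- 0.5 - 0.5 * cos(2 * pi * tt / period)
      env <- env * gate^2                 # sharpened on/off at 4/min
    }
    accel[idx] <- accel[idx] +
      ev_sigma * env * band_noise(m, cfg$fs, cfg$event_band)
  }

  # broadband artifacts, centered in free reference windows
  seg_dur <- cfg$ref_segment / cfg$fs
  n_seg <- floor(cfg$duration_s / seg_dur)
  art_starts <- numeric(0)
  if (cfg$n_artifacts > 0L) {
    seg_free <- vapply(seq_len(n_seg) - 1L, function(k) {
      s0 <- k * seg_dur; s1 <- s0 + seg_dur
      !any(ev_starts < s1 & ev_starts + cfg$event_duration_s > s0)
    }, logical(1L))
    free <- which(seg_free)
    if (length(free) < cfg$n_artifacts)
      stop("cannot fit artifacts outside event intervals", call. = FALSE)
    picked <- sort(sample(free, cfg$n_artifacts)) - 1L
    art_starts <- picked * seg_dur +
      (seg_dur - min(cfg$artifact_duration_s, seg_dur)) / 2
    art_band <- c(61, min(100, cfg$fs / 2 - 1))
    duty <- min(1, cfg$artifact_duration_s / seg_dur)
    art_sigma <- cfg$artifact_amp_uv *
      sqrt(bins_in_ref(art_band) / 2) / sqrt(duty)
    for (s in art_starts) {
      i0 <- round(s * cfg$fs) + 1L
      m <- round(min(cfg$artifact_duration_s, seg_dur) * cfg$fs)
      idx <- i0:(i0 + m - 1L)
      accel[idx] <- accel[idx] +
        art_sigma * burst_envelope(m, cfg$fs, ramp_s = 0.1) *
        band_noise(m, cfg$fs, art_band)
    }
  }

  # paired pH trace: near-neutral baseline with slow drift; acid events
  # dip below threshold, non-acid events stay above it by construction
  n_ph <- round(cfg$duration_s * cfg$ph_fs)
  tp <- (seq_len(n_ph) - 1) / cfg$ph_fs
  ph <- cfg$ph_baseline + 0.3 * sin(2 * pi * tp / 1200)
  acid_floor <- 4.3                       # non-acid dips never go below
  for (j in seq_along(ev_starts)) {
    s0 <- ev_starts[j]; s1 <- s0 + cfg$event_duration_s
    depth <- if (is_acid[j]) cfg$ph_drop_depth else 1.5
    g <- numeric(n_ph)
    g[tp >= s0 & tp < s1] <- 1
    after <- tp >= s1
    g[after] <- exp(-(tp[after] - s1) / cfg$ph_recovery_s)
    dip <- ph - depth * g
    ph <- if (is_acid[j]) dip else pmax(dip, pmin(ph, acid_floor))
  }
  ph <- pmin(pmax(ph, 0.5), 14)

  truth <- list(
    event_intervals = data.frame(start_s = ev_starts,
                                 end_s = ev_starts + cfg$event_duration_s,
                                 is_acid = is_acid),
    artifact_intervals = data.frame(
      start_s = art_starts,
      end_s = art_starts + min(cfg$artifact_duration_s, seg_dur)),
    expected_positive = cfg$n_reflux_events > 0L && cfg$event_amp_uv > 0)

  subject <- sprintf("sim_seed%d", cfg$seed)
  list(accel = recording(accel, fs = cfg$fs, subject_id = subject),
       ph = ph_recording(ph, fs = cfg$ph_fs, subject_id = subject),
       truth = truth)
}

# Derives a per-subject seed from the master seed (splittable counter
# scheme, kept below 2^31).
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 48271 + 7919 * as.numeric(i)) %%
               2147483647)
}

#' Simulate a cohort of paired recordings
#'
#' A fraction `prevalence` of subjects carry reflux events
#' (`expected_positive` TRUE); the rest are quiet (zero events). All
#' per-subject randomness derives deterministically from the master
#' seed, so cohorts are reproducible regardless of generation order.
#'
#' @param n number of subjects.
#' @param prevalence probability a subject is event-bearing.
#' @param base_cfg a [sim_config()]; its `seed` is the master seed.
#' @return list of `n` elements as returned by [simulate_pair()], each
#'   with the derived `seed` attached.
#' @export
cohort <- function(n, prevalence, base_cfg = sim_config()) {
  stopifnot(n > 0, prevalence >= 0, prevalence <= 1)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(base_cfg$seed)
  bearing <- stats::runif(n) < prevalence
  lapply(seq_len(n), function(i) {
    cfg_i <- base_cfg
    cfg_i$seed <- derive_seed(base_cfg$seed, i)
    if (!bearing[i]) cfg_i$n_reflux_events <- 0L
    pair <- simulate_pair(cfg_i)
    pair$seed <- cfg_i$seed
    pair
  })
}

#' Write a simulated pair (or cohort) to disk
#'
#' One accelerometer CSV, one pH CSV and one ground-truth JSON per
#' subject, in the layout the `simulate` CLI command produces.
#'
#' @param pairs output of [simulate_pair()] (a single pair) or
#'   [cohort()] (a list of pairs).
#' @param dir output directory (created if needed).
#' @export
write_simulation <- function(pairs, dir) {
  if (!is.null(pairs$accel)) pairs <- list(pairs)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    base <- file.path(dir, sprintf("subject_%03d", i))
    write_recording(p$accel, paste0(base, "_accel.csv"))
    write_recording(p$ph, paste0(base, "_ph.csv"))
    jsonlite::write_json(p$truth, paste0(base, "_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}
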