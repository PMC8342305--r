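#' pH-metry configuration
#'
#' Settings for acid-episode detection and the Boix-Ochoa composite
#' score. An acid reflux episode is a maximal run of samples with pH
#' below `acid_threshold` lasting at least `min_episode_s`; the
#' composite sums six normalised acid-exposure components and is called
#' positive when strictly greater than `cutoff` (16.6, the conventional
#' threshold for significant acidic reflux).
#'
#' @param acid_threshold pH below which esophageal exposure counts as
#'   acid (default 4.0).
#' @param min_episode_s minimum episode duration in seconds (default
#'   15 s, debouncing probe-artifact spikes).
#' @param long_episode_min duration in minutes above which an episode
#'   counts as "long" (default 5).
#' @param cutoff composite-score positivity threshold (default 16.6,
#'   strict `>`).
#' @param component_norms normative means and SDs for the six composite
#'   components, as returned by [identity_norms()] or
#'   [placeholder_norms()], or a data.frame with columns `name`,
#'   `reference_mean`, `reference_sd`. The published normative values
#'   are not bundled; supply your laboratory's reference set. `NULL`
#'   (the default) makes [boix_ochoa()] raise a configuration error.
#' @param hysteresis_ph optional recovery hysteresis: once an episode
#'   starts, it ends only when pH rises to `acid_threshold +
#'   hysteresis_ph` (default 0 = none).
#' @export
ph_config <- function(acid_threshold = 4.0, min_episode_s = 15,
                      long_episode_min = 5, cutoff = 16.6,
                      component_norms = NULL, hysteresis_ph = 0) {
  if (acid_threshold <= 0 || acid_threshold >= 14)
    stop("`acid_threshold` must be inside (0, 14)", call. = FALSE)
  if (cutoff <= 0) stop("`cutoff` must be > 0", call. = FALSE)
  if (!is.null(component_norms)) {
    component_norms <- as.data.frame(component_norms)
    stopifnot(all(c("name", "reference_mean", "reference_sd") %in%
                    names(component_norms)))
    if (any(component_norms$reference_sd <= 0))
      stop("all `reference_sd` must be > 0", call. = FALSE)
  }
  structure(list(acid_threshold = acid_threshold,
                 min_episode_s = min_episode_s,
                 long_episode_min = long_episode_min,
                 cutoff = cutoff, component_norms = component_norms,
                 hysteresis_ph = hysteresis_ph),
            class = "ph_config")
}

boix_ochoa_component_names <- c(
  "pct_time_acid", "pct_time_acid_upright", "pct_time_acid_supine",
  "n_episodes", "n_long_episodes", "longest_episode_min")

#' Identity component norms (mean 0, SD 1)
#'
#' With identity norms the composite reduces to
#' `sum(max(observed + 1, 0))` over the six components — useful for
#' worked examples and tests where the raw component values are the
#' quantity of interest.
#' @export
identity_norms <- function() {
  data.frame(name = boix_ochoa_component_names,
             reference_mean = 0, reference_sd = 1)
}

#' Synthetic placeholder component norms
#'
#' A clearly synthetic stand-in for the published normative means/SDs of
#' the six Boix-Ochoa components, which are not bundled with this
#' package. These values are chosen only so that a frankly acidic trace
#' scores far above 16.6 and a neutral trace far below; they are NOT
#' physiological reference data and results computed with them must not
#' be interpreted clinically. Every [boix_ochoa()] result echoes the
#' norms used.
#' @export
placeholder_norms <- function() {
  data.frame(
    name = boix_ochoa_component_names,
    reference_mean = c(2, 2, 2, 10, 1, 4),
    reference_sd = c(1.5, 1.5, 1.5, 8, 1.5, 4))
}

#' Detect acid reflux episodes in a pH trace
#'
#' An episode is a maximal run of consecutive samples with pH strictly
#' below the acid threshold, lasting at least `min_episode_s`. Invalid
#' (`NA`) samples never belong to an episode. Intervals are half-open
#' `[start_s, end_s)` on the recording's time axis.
#'
#' @param ph a [ph_recording()].
#' @param cfg a [ph_config()].
#' @return data.frame with columns `start_s`, `end_s`, `duration_s`.
#' @export
detect_acid_episodes <- function(ph, cfg = ph_config()) {
  stopifnot(inherits(ph, "ph_recording"))
  x <- ph$samples
  acid <- !is.na(x) & x < cfg$acid_threshold
  if (cfg$hysteresis_ph > 0 && any(acid)) {
    # once in an episode, stay until pH recovers past threshold + hysteresis
    release <- cfg$acid_threshold + cfg$hysteresis_ph
    in_ep <- FALSE
    for (i in seq_along(x)) {
      if (is.na(x[i])) { in_ep <- FALSE; next }
      if (!in_ep && x[i] < cfg$acid_threshold) in_ep <- TRUE
      else if (in_ep && x[i] >= release) in_ep <- FALSE
      acid[i] <- in_ep && !is.na(x[i])
    }
  }
  r <- rle(acid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths / ph$fs >= cfg$min_episode_s)
  data.frame(start_s = (starts[keep] - 1L) / ph$fs,
             end_s = ends[keep] / ph$fs,
             duration_s = r$lengths[keep] / ph$fs)
}

#' Composite from observed component values
#'
#' Each component contributes `max((observed - reference_mean) /
#' reference_sd + 1, 0)`; the composite is the sum over the six
#' components (a DeMeester-style normalised sum).
#'
#' @param observed named (or ordered) numeric vector of the six
#'   component values.
#' @param norms norms data.frame (see [ph_config()]).
#' @export
boix_ochoa_composite <- function(observed, norms) {
  norms <- as.data.frame(norms)
  if (!is.null(names(observed)) && all(norms$name %in% names(observed)))
    observed <- observed[norms$name]
  stopifnot(length(observed) == nrow(norms))
  sum(pmax((as.numeric(observed) - norms$reference_mean) /
             norms$reference_sd + 1, 0))
}

#' Boix-Ochoa composite pH-metry score
#'
#' Computes the six acid-exposure components — percent time pH below
#' threshold (total, upright, supine), episode count, number of long
#' (>= 5 min) episodes, and longest episode in minutes — normalises each
#' against reference norms and sums them. The result is positive when
#' the composite strictly exceeds the cut-off (16.6), indicating
#' significant acidic reflux. Recordings shorter than 24 h are scored
#' but flagged, since several components are duration-dependent.
#'
#' When no postural track is available (preterm infants are nursed
#' supine), the upright and supine components both take the total-time
#' value and the postural mode is recorded in the result.
#'
#' @param ph a [ph_recording()].
#' @param episodes optional precomputed [detect_acid_episodes()] output.
#' @param position_track optional character vector (one of `"upright"`,
#'   `"supine"` per sample) aligned with `ph$samples`.
#' @param cfg a [ph_config()]; `component_norms` must be set.
#' @return a `boix_ochoa_result` with the component statistics, the
#'   composite, the positivity call, the postural mode, a `short_study`
#'   flag (< 24 h) and an echo of the norms used.
#' @export
boix_ochoa <- function(ph, episodes = NULL, position_track = NULL,
                       cfg = ph_config()) {
  stopifnot(inherits(ph, "ph_recording"))
  if (is.null(cfg$component_norms))
    stop(paste("`component_norms` not configured: supply the normative",
               "means/SDs for the six composite components (see",
               "?ph_config; identity_norms() and placeholder_norms()",
               "are available for non-clinical use)"), call. = FALSE)
  if (is.null(episodes)) episodes <- detect_acid_episodes(ph, cfg)
  valid <- !is.na(ph$samples)
  acid <- valid & ph$samples < cfg$acid_threshold
  pct_acid_of <- function(mask) {
    denom <- sum(valid & mask)
    if (denom == 0) 0 else 100 * sum(acid & mask) / denom
  }
  pct_total <- pct_acid_of(rep(TRUE, length(valid)))
  if (is.null(position_track)) {
    pct_up <- pct_total
    pct_sup <- pct_total
    postural_mode <- "total_for_postural"
  } else {
    stopifnot(length(position_track) == length(ph$samples))
    pct_up <- pct_acid_of(position_track == "upright")
    pct_sup <- pct_acid_of(position_track == "supine")
    postural_mode <- "tracked"
  }
  longest_min <- if (nrow(episodes)) max(episodes$duration_s) / 60 else 0
  n_long <- sum(episodes$duration_s / 60 >= cfg$long_episode_min)
  observed <- c(pct_time_acid = pct_total,
                pct_time_acid_upright = pct_up,
                pct_time_acid_supine = pct_sup,
                n_episodes = nrow(episodes),
                n_long_episodes = n_long,
                longest_episode_min = longest_min)
  composite <- boix_ochoa_composite(observed, cfg$component_norms)
  structure(list(
    pct_time_acid = pct_total,
    pct_time_acid_upright = pct_up,
    pct_time_acid_supine = pct_sup,
    n_episodes = nrow(episodes),
    n_long_episodes = n_long,
    longest_episode_min = longest_min,
    composite = composite,
    positive = composite > cfg$cutoff,
    cutoff = cfg$cutoff,
    postural_mode = postural_mode,
    short_study = duration_seconds(ph) < 24 * 3600,
    norms_used = cfg$component_norms),
    class = "boix_ochoa_result")
}

#' @export
print.boix_ochoa_result <- function(x, ...) {
  cat(sprintf("<boix_ochoa_result> composite %.2f (%s, cut-off > %g)%s\n",
              x$composite, if (x$positive) "POSITIVE" else "negative",
              x$cutoff, if (x$short_study) "  [<24 h study]" else ""))
  cat(sprintf("  %% time pH acid %.2f  episodes %d (long %d)  longest %.1f min\n",
              x$pct_time_acid, x$n_episodes, x$n_long_episodes,
              x$longest_episode_min))
  cat(sprintf("  postural mode: %s\n", x$postural_mode))
  invisible(x)
}
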