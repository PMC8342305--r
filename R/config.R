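# YAML configuration: one file with optional sections [qc], [score],
# [ph], [sim] whose keys mirror the corresponding *_config() arguments.

#' Load pipeline configuration from YAML
#'
#' Reads a YAML file with optional top-level sections `qc`, `score`,
#' `ph` and `sim`; each key overrides the corresponding default of
#' [qc_config()], [score_config()], [ph_config()] or [sim_config()].
#' Unknown keys are an error (they usually indicate a typo that would
#' otherwise silently fall back to a default).
#'
#' @param path YAML file path, or `NULL` for all defaults.
#' @return list with elements `qc`, `score`, `ph`, `sim`.
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else {
    if (!file.exists(path))
      stop(sprintf("config file not found: %s", path), call. = FALSE)
    yaml::read_yaml(path)
  }
  known <- c("qc", "score", "ph", "sim")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop(sprintf("unknown config section(s): %s",
                 paste(extra, collapse = ", ")), call. = FALSE)
  build <- function(fn, section) {
    args <- raw[[section]] %||% list()
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad))
      stop(sprintf("unknown key(s) in [%s]: %s", section,
                   paste(bad, collapse = ", ")), call. = FALSE)
    do.call(fn, args)
  }
  list(qc = build(qc_config, "qc"),
       score = build(score_config, "score"),
       ph = build(ph_config, "ph"),
       sim = build(sim_config, "sim"))
}
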