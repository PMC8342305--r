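#' Build a table of paired study records
#'
#' @param study_id character vector of study identifiers.
#' @param accel_positive,ph_positive logical vectors of the paired
#'   binary calls.
#' @param surgical,on_ger_meds optional logical subgroup flags.
#' @param accel_score,boix_ochoa optional numeric scores.
#' @return a `study_records` data.frame.
#' @export
study_records <- function(study_id, accel_positive, ph_positive,
                          surgical = FALSE, on_ger_meds = FALSE,
                          accel_score = NA_real_, boix_ochoa = NA_real_) {
  df <- data.frame(study_id = as.character(study_id),
                   accel_positive = as.logical(accel_positive),
                   ph_positive = as.logical(ph_positive),
                   surgical = as.logical(surgical),
                   on_ger_meds = as.logical(on_ger_meds),
                   accel_score_uV = as.numeric(accel_score),
                   boix_ochoa = as.numeric(boix_ochoa))
  if (anyNA(df$accel_positive) || anyNA(df$ph_positive))
    stop("accel_positive and ph_positive must be TRUE/FALSE for every study",
         call. = FALSE)
  class(df) <- c("study_records", "data.frame")
  df
}

#' 2x2 contingency table of paired diagnostic calls
#'
#' @param both_pos accelerometry-positive and pH-positive count.
#' @param accel_pos_ph_neg accelerometry-positive, pH-negative count
#'   (the non-acid-reflux cell).
#' @param accel_neg_ph_pos accelerometry-negative, pH-positive count.
#' @param both_neg concordant-negative count.
#' @export
contingency_table <- function(both_pos, accel_pos_ph_neg,
                              accel_neg_ph_pos, both_neg) {
  cells <- c(both_pos = both_pos, accel_pos_ph_neg = accel_pos_ph_neg,
             accel_neg_ph_pos = accel_neg_ph_pos, both_neg = both_neg)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  structure(c(as.list(cells), list(total = sum(cells))),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$both_pos, x$accel_pos_ph_neg,
                x$accel_neg_ph_pos, x$both_neg),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("accel+", "accel-"), c("pH+", "pH-")))
  cat(sprintf("<contingency_table> n = %d\n", x$total))
  print(m)
  invisible(x)
}

#' Tabulate paired calls into a 2x2 table
#'
#' @param records a [study_records()] data.frame.
#' @param subgroup optional: `"surgical"` or `"on_ger_meds"` to restrict
#'   to the flagged subgroup before counting.
#' @return a [contingency_table()].
#' @export
tabulate_studies <- function(records, subgroup = NULL) {
  if (!is.null(subgroup)) {
    subgroup <- match.arg(subgroup, c("surgical", "on_ger_meds"))
    records <- records[isTRUE_vec(records[[subgroup]]), , drop = FALSE]
  }
  if (!nrow(records))
    stop("no study records left after subgroup filtering", call. = FALSE)
  a <- records$accel_positive
  p <- records$ph_positive
  contingency_table(sum(a & p), sum(a & !p), sum(!a & p), sum(!a & !p))
}

isTRUE_vec <- function(x) !is.na(x) & x

rate_pct <- function(num, denom) {
  if (denom == 0) NA_real_ else 100 * num / denom
}

#' Diagnostic rates from a paired 2x2 table
#'
#' Neither method is an a-priori gold standard for non-acid reflux, so
#' the roles are explicit: with `reference = "ph"` the pH call is
#' treated as the test and the accelerometric call as the condition it
#' should confirm, so `ppv` is the fraction of pH-positive studies that
#' are also accelerometry-positive (the positive predictive value as
#' reported clinically); `sensitivity` is the fraction of accelerometry-positive
#' studies that pH detects. With `reference = "accel"` the roles swap.
#' `accel_pos_ph_neg_fraction` is always the fraction of
#' accelerometry-positive studies with a negative pH score (the presumed
#' non-acid-reflux fraction). Rates with a zero denominator are
#' reported as `NA` ("not applicable"), never as 0. Exact rational
#' values are returned; `round_pct()` formats to 1 decimal.
#'
#' @param t a [contingency_table()].
#' @param reference `"ph"` (default) or `"accel"`.
#' @return named list of rates in percent: `ppv`, `npv`, `sensitivity`,
#'   `specificity`, `accel_pos_ph_neg_fraction`.
#' @export
diagnostics <- function(t, reference = c("ph", "accel")) {
  reference <- match.arg(reference)
  stopifnot(inherits(t, "contingency_table"))
  bp <- t$both_pos; apn <- t$accel_pos_ph_neg
  anp <- t$accel_neg_ph_pos; bn <- t$both_neg
  out <- if (reference == "ph") list(
    ppv = rate_pct(bp, bp + anp),
    npv = rate_pct(bn, bn + apn),
    sensitivity = rate_pct(bp, bp + apn),
    specificity = rate_pct(bn, bn + anp)
  ) else list(
    ppv = rate_pct(bp, bp + apn),
    npv = rate_pct(bn, bn + anp),
    sensitivity = rate_pct(bp, bp + anp),
    specificity = rate_pct(bn, bn + apn)
  )
  out$accel_pos_ph_neg_fraction <- rate_pct(apn, bp + apn)
  out$reference <- reference
  out
}

#' Round rates to the reporting precision (1 decimal, percent)
#' @param rates output of [diagnostics()].
#' @export
round_pct <- function(rates) {
  lapply(rates, function(v) if (is.numeric(v)) round(v, 1) else v)
}

#' Cohort fixtures encoding the published study margins
#'
#' Synthetic per-study tables whose cell counts exactly encode the
#' reported clinical cohorts, for worked examples and validation of the
#' concordance arithmetic (no raw recordings are distributed):
#' \describe{
#'   \item{full_cohort}{85 paired studies: 18 concordant positive, 42
#'     accelerometry-positive/pH-negative (non-acid reflux), 2
#'     accelerometry-negative/pH-positive, 23 concordant negative.}
#'   \item{surgical}{11 infants requiring anti-reflux surgery: 2 both
#'     positive, 8 accelerometry-positive with false-negative pH, 1 both
#'     negative (10/11 accelerometry-positive).}
#'   \item{medicated}{20 infants on anti-reflux medication: 19/20
#'     pH-negative; 13 accelerometry-positive in total; no study was
#'     pH-positive with negative accelerometry (cells 1/12/0/7).}
#' }
#'
#' @param name fixture name.
#' @return a [study_records()] data.frame.
#' @export
build_fixture <- function(name = c("full_cohort", "surgical", "medicated")) {
  if (!is.character(name) || !length(name) ||
      !name[1L] %in% c("full_cohort", "surgical", "medicated"))
    stop(sprintf("unknown fixture name: %s",
                 paste(name, collapse = ", ")), call. = FALSE)
  name <- match.arg(name)
  from_cells <- function(prefix, bp, apn, anp, bn, ...) {
    n <- bp + apn + anp + bn
    study_records(
      study_id = sprintf("%s_%03d", prefix, seq_len(n)),
      accel_positive = rep(c(TRUE, TRUE, FALSE, FALSE),
                           times = c(bp, apn, anp, bn)),
      ph_positive = rep(c(TRUE, FALSE, TRUE, FALSE),
                        times = c(bp, apn, anp, bn)),
      ...)
  }
  switch(name,
    full_cohort = from_cells("study", 18, 42, 2, 23),
    surgical = from_cells("surg", 2, 8, 0, 1, surgical = TRUE),
    medicated = from_cells("med", 1, 12, 0, 7, on_ger_meds = TRUE))
}

#' Read a study-record CSV
#'
#' Columns: `study_id, accel_positive, ph_positive, surgical,
#' on_ger_meds, accel_score_uV, boix_ochoa` (the last four optional).
#' @param path CSV path.
#' @export
read_study_records <- function(path) {
  if (!file.exists(path))
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path)
  if (!nrow(df)) stop(sprintf("empty study table: %s", path), call. = FALSE)
  need <- c("study_id", "accel_positive", "ph_positive")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required columns: %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  study_records(df$study_id, df$accel_positive, df$ph_positive,
                surgical = df$surgical %||% FALSE,
                on_ger_meds = df$on_ger_meds %||% FALSE,
                accel_score = df$accel_score_uV %||% NA_real_,
                boix_ochoa = df$boix_ochoa %||% NA_real_)
}
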