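# Observed-vs-expected b/tsDMARD treatment-difficulty index.
#
# Per patient: actual count A = previous b/tsDMARDs + 1 (the current
# therapy counts), rate of failure ROF = A / follow-up months; the cohort
# 75th percentile of ROF calibrates the expected count
# E = ceiling(rate75 * months); the ratio A / E proxies treatment
# difficulty (> 1: potentially difficult to treat; > 1.5: highly so).

#' Actual b/tsDMARD count
#'
#' Adds one to the number of previous b/tsDMARDs so the present therapy
#' is counted.
#'
#' @param n_prev_btsdmards nonnegative integer vector.
#' @return integer vector `n_prev_btsdmards + 1`.
#' @export
compute_actual_count <- function(n_prev_btsdmards) {
  if (any(is.na(n_prev_btsdmards)) || any(n_prev_btsdmards < 0) ||
      any(n_prev_btsdmards != round(n_prev_btsdmards))) {
    stop("n_prev_btsdmards must be nonnegative integers", call. = FALSE)
  }
  as.integer(n_prev_btsdmards + 1)
}

#' 75th percentile of the failure-rate distribution
#'
#' The cohort cut-off that calibrates the expected count. The quantile
#' estimator defaults to linear interpolation of order statistics
#' (`type = 7`); the index is threshold dependent, so the estimator is
#' selectable.
#'
#' @param rofs positive numeric vector of per-patient failure rates
#'   (drugs per month).
#' @param type quantile algorithm passed to [stats::quantile()].
#' @return the 75th percentile.
#' @export
rate75 <- function(rofs, type = 7) {
  if (length(rofs) == 0) stop("empty rate vector", call. = FALSE)
  if (any(is.na(rofs)) || any(rofs <= 0)) {
    stop("failure rates must be positive and observed", call. = FALSE)
  }
  quantile(rofs, 0.75, type = type, names = FALSE)
}

#' Expected b/tsDMARD count
#'
#' `ceiling(rate75 * months)`: the count a patient switching at the
#' cohort's 75th-percentile rate would have accrued over their own
#' follow-up, rounded up to an integer (so always >= 1).
#'
#' @param rate75 positive scalar cut-off rate (drugs per month).
#' @param months positive follow-up months (vectorized).
#' @return positive integer vector.
#' @export
expected_count <- function(rate75, months) {
  if (any(rate75 <= 0) || any(months <= 0)) {
    stop("rate75 and months must be positive", call. = FALSE)
  }
  as.integer(ceiling(rate75 * months))
}

#' Difficulty ratio and flag
#'
#' `ratio = actual / expected`; a ratio of exactly 1 is classified
#' respondent (difficulty starts strictly above 1), ratios in (1, 1.5]
#' flag a potential D2T patient, above 1.5 a highly potential one.
#'
#' @param actual,expected positive integer vectors.
#' @return data frame with `ratio` and `flag` (factor `respondent`,
#'   `potential_d2t`, `high_potential_d2t`).
#' @export
difficulty_ratio <- function(actual, expected) {
  if (any(actual < 1) || any(expected < 1)) {
    stop("actual and expected counts must be >= 1", call. = FALSE)
  }
  ratio <- actual / expected
  flag <- cut(ratio, breaks = c(-Inf, 1, 1.5, Inf),
              labels = c("respondent", "potential_d2t", "high_potential_d2t"),
              right = TRUE)
  data.frame(ratio = ratio, flag = flag)
}

#' Compute the treatment-difficulty index for a cohort
#'
#' Runs the full index: actual counts, per-patient failure rates, the
#' cohort 75th-percentile cut-off (recomputed per cohort unless a frozen
#' reference cut-off is supplied), expected counts, ratios and flags.
#'
#' @param cohort cohort data frame with `n_prev_btsdmards` and the
#'   follow-up column.
#' @param time_col follow-up column name (default months since PsA
#'   diagnosis, the only duration in the cohort schema; point it at a
#'   time-on-b/tsDMARD column if one exists).
#' @param quantile_type quantile estimator for the cut-off.
#' @param frozen_rate75 optional externally fixed cut-off; when given,
#'   the cohort's own 75th percentile is not used.
#' @return object of class `difficulty_index`: `$table` (per-patient
#'   `patient_id`, `actual_count`, `follow_up_months`, `rof`,
#'   `expected_count`, `ratio`, `flag`) and `$summary` (`rate75`,
#'   `quantile_type`, `frozen`, `n`, `n_ratio_gt1`, `prop_ratio_gt1`,
#'   `n_ratio_gt1.5`).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 100, seed = 7))
#' idx <- difficulty_index(cohort)
#' idx$summary$prop_ratio_gt1
difficulty_index <- function(cohort, time_col = "months_since_diagnosis",
                             quantile_type = 7, frozen_rate75 = NULL) {
  months <- cohort[[time_col]]
  if (is.null(months)) stop("no column '", time_col, "'", call. = FALSE)
  if (any(is.na(months)) || any(months <= 0)) {
    stop("follow-up months must be positive and observed", call. = FALSE)
  }
  actual <- compute_actual_count(cohort$n_prev_btsdmards)
  rof <- actual / months
  cut_off <- if (is.null(frozen_rate75)) {
    rate75(rof, type = quantile_type)
  } else {
    stopifnot(frozen_rate75 > 0)
    frozen_rate75
  }
  expected <- expected_count(cut_off, months)
  dr <- difficulty_ratio(actual, expected)
  table <- data.frame(patient_id = cohort$patient_id,
                      actual_count = actual,
                      follow_up_months = months,
                      rof = rof,
                      expected_count = expected,
                      ratio = dr$ratio,
                      flag = dr$flag)
  summary <- list(rate75 = cut_off,
                  quantile_type = quantile_type,
                  frozen = !is.null(frozen_rate75),
                  n = nrow(table),
                  n_ratio_gt1 = sum(dr$ratio > 1),
                  prop_ratio_gt1 = mean(dr$ratio > 1),
                  n_ratio_gt1.5 = sum(dr$ratio > 1.5))
  structure(list(table = table, summary = summary),
            class = "difficulty_index")
}

#' @export
print.difficulty_index <- function(x, ...) {
  s <- x$summary
  cat("Treatment-difficulty index: n =", s$n,
      "| rate75 =", format(s$rate75, digits = 4),
      if (s$frozen) "(frozen)" else "(cohort quantile)", "\n")
  cat("ratio > 1:", s$n_ratio_gt1,
      sprintf("(%.1f%%)", 100 * s$prop_ratio_gt1),
      "| ratio > 1.5:", s$n_ratio_gt1.5, "\n")
  invisible(x)
}
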