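# Synthetic cohort generation: covariates, planted drug counts, MCAR holes.

#' Generate a synthetic PsA cohort
#'
#' Draws `n_patients` patient records with the marginal structure given by
#' the configuration (covariates sampled independently — the emulated
#' registry publishes marginals only), fills the b/tsDMARD counts from the
#' planted count-generating model via [simulate_drug_counts()], then
#' punches MCAR holes via [apply_missingness()]. With the same
#' configuration and seed the output table is identical.
#'
#' @param config a [cohort_config()].
#' @return a `data.frame`, one row per patient; missing entries are `NA`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 50, seed = 1))
#' nrow(cohort)
generate_cohort <- function(config) {
  validate_cohort_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_patients
  pv <- config$prevalences
  sd_ <- config$score_distributions

  draw <- function(p) runif(n) < p
  cohort <- data.frame(
    patient_id = seq_len(n),
    sex = ifelse(draw(pv$male), "M", "F"),
    age_years = sample_score(sd_$age_years, n),
    psa_subset = sample(names(pv$psa_subset), n, replace = TRUE,
                        prob = pv$psa_subset),
    has_psoriasis = draw(pv$has_psoriasis),
    stringsAsFactors = FALSE
  )
  for (sub in c("pso_plaque", "pso_scalp", "pso_nail",
                "pso_palmoplantar", "pso_guttate")) {
    cohort[[sub]] <- cohort$has_psoriasis & draw(pv[[sub]])
  }
  for (flag in c("obesity", "smoker", "osteoarthritis", "fibromyalgia",
                 "dactylitis_history", "ibd", "steroid_use",
                 "csdmard_combo", "management_problematic")) {
    cohort[[flag]] <- draw(pv[[flag]])
  }
  cohort$steroid_dose_mg <-
    ifelse(cohort$steroid_use, sample_score(sd_$steroid_dose_mg, n), 0)
  for (score in c("dapsa", "phga", "pga", "haq", "rdci", "bsa_pct",
                  "months_since_diagnosis")) {
    cohort[[score]] <- sample_score(sd_[[score]], n)
  }

  cohort <- simulate_drug_counts(cohort, config$effect_spec)
  apply_missingness(cohort, config$missingness)
}

#' Fill b/tsDMARD counts from a planted Poisson rate model
#'
#' The actual b/tsDMARD count for patient *i* is drawn as
#' `A_i = 1 + Poisson(T_i * base_rate * exp(x_i' beta))`, where `T_i` is
#' `months_since_diagnosis`: every treated patient carries at least the
#' current therapy, and the switches beyond it accrue at a per-month rate
#' modified by the planted log rate ratios. `n_prev_btsdmards` is set to
#' `A_i - 1`.
#'
#' @param cohort cohort data frame (see [generate_cohort()]).
#' @param effect_spec list with `base_rate` (>= 0, drugs/month) and
#'   `coefficients`, a named numeric vector of log rate ratios on cohort
#'   columns (binary flags enter as 0/1).
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return the cohort with `n_prev_btsdmards` filled.
#' @export
simulate_drug_counts <- function(cohort, effect_spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.numeric(effect_spec$base_rate) || effect_spec$base_rate < 0) {
    stop("effect_spec base_rate must be nonnegative", call. = FALSE)
  }
  beta <- effect_spec$coefficients
  eta <- rep(0, nrow(cohort))
  for (nm in names(beta)) {
    if (is.null(cohort[[nm]])) {
      stop("effect_spec names unknown cohort column '", nm, "'", call. = FALSE)
    }
    eta <- eta + beta[[nm]] * as.numeric(cohort[[nm]])
  }
  rate <- effect_spec$base_rate * exp(eta)
  extra <- rpois(nrow(cohort), cohort$months_since_diagnosis * rate)
  cohort$n_prev_btsdmards <- extra
  cohort
}

# fields that must always stay observed: the index and follow-up time
# are computable for every patient
protected_fields <- c("patient_id", "n_prev_btsdmards", "months_since_diagnosis")

#' Apply MCAR missingness to a cohort
#'
#' Each named field is independently set to `NA` with its configured
#' probability. Drug counts, follow-up time and patient ids are never
#' eligible.
#'
#' @param cohort cohort data frame.
#' @param missingness named numeric vector of per-field rates in `[0, 1]`.
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return the cohort with `NA` entries inserted.
#' @export
apply_missingness <- function(cohort, missingness, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  for (nm in names(missingness)) {
    r <- missingness[[nm]]
    if (!is.numeric(r) || !is.finite(r) || r < 0 || r > 1) {
      stop("missingness rate '", nm, "' must lie in [0, 1]", call. = FALSE)
    }
    if (nm %in% protected_fields) {
      stop("field '", nm, "' may not be set missing", call. = FALSE)
    }
    if (is.null(cohort[[nm]])) {
      stop("missingness names unknown cohort column '", nm, "'", call. = FALSE)
    }
    cohort[[nm]][runif(nrow(cohort)) < r] <- NA
  }
  cohort
}

#' Write / read a cohort table
#'
#' Comma-separated text with a header row; missing entries are empty
#' cells. Doubles are written with 17 significant digits so a written
#' cohort reads back equal to the original.
#'
#' @param cohort cohort data frame.
#' @param path file path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns the cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  for (nm in names(out)) {
    if (is.double(out[[nm]])) {
      v <- formatC(out[[nm]], digits = 17, format = "g")
      v[is.na(out[[nm]])] <- NA
      out[[nm]] <- v
    }
  }
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, na.strings = "")
}
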