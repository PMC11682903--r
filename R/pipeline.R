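# End-to-end orchestration: simulate/load -> classify -> index ->
# univariate screen -> bagged multivariable model -> report.

#' Percentage on nonmissing denominator, one decimal
#'
#' The reporting convention used throughout: `round(100 * count /
#' denominator, 1)` (e.g. 140 of 267 male -> 52.4).
#'
#' @param count,denominator counts.
#' @return numeric percentage rounded to one decimal.
#' @export
pct <- function(count, denominator) {
  round(100 * count / denominator, 1)
}

#' Cohort descriptive summary
#'
#' Count (%) for logical and categorical columns (percentages on the
#' nonmissing denominator, one decimal), median \[Q1, Q3\] for numeric
#' columns (linear-interpolation quantiles, matching the index
#' cut-off estimator).
#'
#' @param cohort nonempty cohort data frame.
#' @param quantile_type quantile algorithm for the continuous summaries.
#' @return data frame: `variable`, `level`, `n`, `denom`, `pct`,
#'   `median`, `q1`, `q3` (the latter three `NA` for categoricals).
#' @export
summarize_cohort <- function(cohort, quantile_type = 7) {
  stopifnot(nrow(cohort) > 0)
  rows <- list()
  add <- function(...) rows[[length(rows) + 1]] <<- data.frame(...)
  for (nm in setdiff(names(cohort), "patient_id")) {
    x <- cohort[[nm]]
    denom <- sum(!is.na(x))
    if (is.logical(x)) {
      n <- sum(x, na.rm = TRUE)
      add(variable = nm, level = "TRUE", n = n, denom = denom,
          pct = if (denom > 0) pct(n, denom) else NA_real_,
          median = NA_real_, q1 = NA_real_, q3 = NA_real_)
    } else if (is.character(x) || is.factor(x)) {
      for (lev in sort(unique(x[!is.na(x)]))) {
        n <- sum(x == lev, na.rm = TRUE)
        add(variable = nm, level = as.character(lev), n = n, denom = denom,
            pct = pct(n, denom),
            median = NA_real_, q1 = NA_real_, q3 = NA_real_)
      }
    } else if (is.numeric(x)) {
      if (denom == 0) {
        add(variable = nm, level = NA_character_, n = 0L, denom = 0L,
            pct = NA_real_, median = NA_real_, q1 = NA_real_, q3 = NA_real_)
      } else {
        q <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE,
                      type = quantile_type, names = FALSE)
        add(variable = nm, level = NA_character_, n = denom, denom = denom,
            pct = NA_real_, median = q[2], q1 = q[1], q3 = q[3])
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-stratum covariate distributions
#'
#' Descriptive summaries of the listed covariates conditional on a
#' stratum label (e.g. predicted-ratio strata `<=1`, `(1,1.5]`,
#' `>1.5`).
#'
#' @param cohort cohort data frame.
#' @param strata factor/character vector, one label per row.
#' @param covariates columns to summarize (default: all but
#'   `patient_id`).
#' @return data frame: `stratum` column prepended to
#'   [summarize_cohort()] rows per stratum.
#' @export
stratified_distributions <- function(cohort, strata, covariates = NULL) {
  stopifnot(length(strata) == nrow(cohort))
  if (is.null(covariates)) covariates <- setdiff(names(cohort), "patient_id")
  out <- lapply(levels(factor(strata)), function(s) {
    sub <- cohort[strata == s, covariates, drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    cbind(stratum = s, n_stratum = nrow(sub), summarize_cohort(sub))
  })
  do.call(rbind, out)
}

#' Default model covariate codings
#'
#' The covariate set explored for association with treatment difficulty:
#' sex (reference male), PsA-predominant subset (reference peripheral),
#' presence of psoriasis plus one presence/absence dummy per psoriasis
#' subtype (patients can carry several subtypes, so subtypes are not
#' mutually exclusive levels), obesity, smoking, dactylitis history,
#' osteoarthritis, fibromyalgia, corticosteroid use, and the
#' clinimetric scores. DAPSA and HAQ get 3-knot restricted cubic
#' splines; PhGA is coded linear (its heavy point mass at 0 degenerates
#' quantile-based knots). Guttate psoriasis and IBD are omitted by
#' default: at their cohort prevalences (about 1%) they are routinely
#' absent from bootstrap resamples, which the bagging stage treats as
#' degenerate; add them back via a custom coding list for larger
#' cohorts.
#'
#' @return list of covariate codings for [prepare_design()].
#' @export
default_model_covariates <- function() {
  list(cov_factor("sex", ref = "M"),
       cov_factor("psa_subset", ref = "peripheral"),
       cov_binary("has_psoriasis"),
       cov_binary("pso_plaque"), cov_binary("pso_scalp"),
       cov_binary("pso_nail"), cov_binary("pso_palmoplantar"),
       cov_binary("obesity"), cov_binary("smoker"),
       cov_binary("dactylitis_history"), cov_binary("osteoarthritis"),
       cov_binary("fibromyalgia"),
       cov_binary("steroid_use"),
       cov_rcs("dapsa", n_knots = 3),
       cov_linear("phga"),
       cov_rcs("haq", n_knots = 3))
}

#' Pipeline configuration
#'
#' @param cohort optional pre-built cohort data frame or path to a
#'   cohort CSV; if `NULL`, a synthetic cohort is generated from
#'   `cohort_config`.
#' @param cohort_config a [cohort_config()] for synthetic input.
#' @param criteria a [d2t_criteria()].
#' @param covariates model covariate codings (see
#'   [default_model_covariates()]).
#' @param quantile_type quantile estimator for the index cut-off.
#' @param n_resamples bootstrap resamples for the bagging stage.
#' @param seed master seed for the bagging stage (and the synthetic
#'   cohort when its config carries no seed).
#' @param outdir optional output directory; when given, every stage
#'   writes its table as CSV plus a plain-text run manifest.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = NULL,
                            cohort_config = psad2t::cohort_config(),
                            criteria = d2t_criteria(),
                            covariates = default_model_covariates(),
                            quantile_type = 7,
                            n_resamples = 1000,
                            seed = 1,
                            outdir = NULL) {
  structure(list(cohort = cohort, cohort_config = cohort_config,
                 criteria = criteria, covariates = covariates,
                 quantile_type = quantile_type,
                 n_resamples = n_resamples, seed = seed, outdir = outdir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Accepts a nested key/value file mirroring [pipeline_config()] and
#' [cohort_config()] fields (`n_patients`, `prevalences`,
#' `effect_spec`, `missingness`, `n_resamples`, `seed`, ...); anything
#' omitted keeps its default.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cc_args <- list()
  for (nm in c("n_patients", "seed")) {
    if (!is.null(raw[[nm]])) cc_args[[nm]] <- raw[[nm]]
  }
  if (!is.null(raw$prevalences)) {
    prev <- default_prevalences()
    for (nm in names(raw$prevalences)) prev[[nm]] <- raw$prevalences[[nm]]
    cc_args$prevalences <- prev
  }
  if (!is.null(raw$effect_spec)) {
    es <- default_effect_spec()
    if (!is.null(raw$effect_spec$base_rate)) {
      es$base_rate <- raw$effect_spec$base_rate
    }
    if (!is.null(raw$effect_spec$coefficients)) {
      es$coefficients <- unlist(raw$effect_spec$coefficients)
    }
    cc_args$effect_spec <- es
  }
  if (!is.null(raw$missingness)) cc_args$missingness <- unlist(raw$missingness)
  pc_args <- list(cohort_config = do.call(cohort_config, cc_args))
  for (nm in c("quantile_type", "n_resamples", "seed", "outdir")) {
    if (!is.null(raw[[nm]])) pc_args[[nm]] <- raw[[nm]]
  }
  if (!is.null(raw$cohort_path)) pc_args$cohort <- raw$cohort_path
  do.call(pipeline_config, pc_args)
}

write_stage <- function(outdir, name, table) {
  if (!is.null(outdir)) {
    utils::write.csv(table, file.path(outdir, paste0(name, ".csv")),
                     row.names = FALSE, na = "")
  }
}

#' Run the full treatment-difficulty analysis
#'
#' Stages, mirroring the study design: (1) simulate or load the cohort;
#' (2) descriptive summary; (3) D2T classification with Firth-penalized
#' univariate associations; (4) difficulty index with the cohort
#' 75th-percentile cut-off; (5) univariate Poisson-offset screen, one
#' model per covariate; (6) complete-case filtering, full multivariable
#' model, bootstrap-bagged backward-AIC selection, zero-imputed
#' averaging, per-patient predicted ratios with >1 / >1.5 strata, and
#' the nomogram. Idempotent for a given seed.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with every stage's result: `cohort`,
#'   `summary`, `d2t`, `firth`, `index`, `univariate`, `nonlinearity`,
#'   `complete`, `full_fit`, `adjusted`, `backward`, `bagging`,
#'   `final`, `predictions`, `strata_distributions`, `nomogram`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  manifest <- list(seed = config$seed, n_resamples = config$n_resamples)

  # -- stage 1: cohort ------------------------------------------------
  cohort <- config$cohort
  if (is.null(cohort)) {
    cc <- config$cohort_config
    if (is.null(cc$seed)) cc$seed <- config$seed
    cohort <- generate_cohort(cc)
    manifest$cohort_source <- "synthetic"
  } else if (is.character(cohort)) {
    manifest$cohort_source <- cohort
    cohort <- read_cohort(cohort)
  } else {
    manifest$cohort_source <- "supplied data frame"
  }
  manifest$n_enrolled <- nrow(cohort)
  write_stage(outdir, "cohort", cohort)

  # -- stage 2: descriptives ------------------------------------------
  summary_tab <- summarize_cohort(cohort, config$quantile_type)
  write_stage(outdir, "cohort_summary", summary_tab)

  # -- stage 3: D2T classification + Firth univariate -----------------
  d2t <- classify_d2t(cohort, config$criteria)
  manifest$n_d2t <- sum(d2t$is_d2t)
  manifest$pct_d2t <- pct(sum(d2t$is_d2t), nrow(d2t))
  manifest$n_indeterminate <- sum(d2t$indeterminate)
  write_stage(outdir, "d2t_status", d2t)

  firth_covs <- c("sex_female", "osteoarthritis", "fibromyalgia",
                  "steroid_use", "obesity", "smoker", "pga", "phga",
                  "dapsa", "haq")
  cohort$sex_female <- cohort$sex == "F"
  firth_tab <- do.call(rbind, lapply(firth_covs, function(cv) {
    tryCatch(firth_univariate(cohort, d2t$is_d2t, cv),
             error = function(e) {
               message("firth_univariate skipped '", cv, "': ",
                       conditionMessage(e))
               NULL
             })
  }))
  cohort$sex_female <- NULL
  write_stage(outdir, "d2t_firth_univariate", firth_tab)

  # -- stage 4: difficulty index --------------------------------------
  idx <- difficulty_index(cohort, quantile_type = config$quantile_type)
  manifest$rate75 <- idx$summary$rate75
  manifest$n_ratio_gt1 <- idx$summary$n_ratio_gt1
  manifest$pct_ratio_gt1 <- pct(idx$summary$n_ratio_gt1, idx$summary$n)
  write_stage(outdir, "difficulty_index", idx$table)

  cohort$actual_count <- idx$table$actual_count
  cohort$log_expected <- log(idx$table$expected_count)

  # -- stage 5: univariate Poisson-offset screen ----------------------
  uni_rows <- list()
  nl_rows <- list()
  for (spec in config$covariates) {
    sub <- cohort[!is.na(cohort[[spec$name]]), , drop = FALSE]
    des <- prepare_design(sub, list(spec))
    fit <- fit_poisson_offset(sub$actual_count, des$X, sub$log_expected,
                              blocks = des$blocks)
    uni_rows[[spec$name]] <- cbind(adjustment = "unadjusted",
                                   relative_difficulty(fit, des))
    if (spec$type == "rcs") {
      nl_idx <- des$blocks[[spec$name]][-1]
      wt <- wald_test(fit, nl_idx)
      nl_rows[[spec$name]] <- data.frame(covariate = spec$name,
                                         statistic = wt$statistic,
                                         df = wt$df, p_value = wt$p_value)
    }
  }
  univariate <- do.call(rbind, uni_rows)
  rownames(univariate) <- NULL
  nonlinearity <- do.call(rbind, nl_rows)
  write_stage(outdir, "univariate_effects", univariate)
  write_stage(outdir, "nonlinearity_wald", nonlinearity)

  # -- stage 6: multivariable model -----------------------------------
  cov_names <- vapply(config$covariates, `[[`, "", "name")
  complete <- complete_cases(cohort, cov_names)
  manifest$n_complete <- nrow(complete)
  manifest$n_incomplete_dropped <- attr(complete, "n_dropped")

  design <- prepare_design(complete, config$covariates)
  full_fit <- fit_poisson_offset(complete$actual_count, design$X,
                                 complete$log_expected,
                                 blocks = design$blocks)
  adjusted <- cbind(adjustment = "adjusted",
                    relative_difficulty(full_fit, design))
  write_stage(outdir, "adjusted_effects", adjusted)

  backward <- backward_aic(complete$actual_count, design$X,
                           complete$log_expected, design$blocks)
  manifest$backward_selected <- paste(backward$selected, collapse = "+")

  bag <- bootstrap_bag(complete$actual_count, design$X,
                       complete$log_expected, design$blocks,
                       n_resamples = config$n_resamples,
                       seed = config$seed)
  manifest$n_degenerate_resamples <- bag$n_degenerate
  write_stage(outdir, "selection_frequency",
              data.frame(covariate = names(bag$selection_frequency),
                         frequency = unname(bag$selection_frequency)))
  write_stage(outdir, "coefficient_draws",
              as.data.frame(bag$coefficient_draws))
  write_stage(outdir, "resample_log", bag$resample_log)

  final <- average_coefficients(bag, design)
  write_stage(outdir, "final_coefficients",
              data.frame(term = names(final$coefficients),
                         coefficient = unname(final$coefficients)))

  predictions <- predict_and_stratify(final, complete)
  manifest$n_predicted_gt1 <- sum(predictions$predicted_ratio > 1)
  manifest$pct_predicted_gt1 <- pct(manifest$n_predicted_gt1,
                                    nrow(predictions))
  write_stage(outdir, "predicted_ratio", predictions)

  strata_dist <- stratified_distributions(
    complete, predictions$stratum,
    covariates = c(cov_names, "actual_count"))
  write_stage(outdir, "strata_distributions", strata_dist)

  nomo <- nomogram_table(final, complete)
  write_stage(outdir, "nomogram", nomo$table)

  if (!is.null(outdir)) {
    lines <- paste0(names(manifest), ": ",
                    vapply(manifest, function(v) paste(format(v), collapse = " "), ""))
    writeLines(lines, file.path(outdir, "manifest.txt"))
  }
  invisible(list(cohort = cohort, summary = summary_tab, d2t = d2t,
                 firth = firth_tab, index = idx, univariate = univariate,
                 nonlinearity = nonlinearity, complete = complete,
                 full_fit = full_fit, adjusted = adjusted,
                 backward = backward, bagging = bag, final = final,
                 predictions = predictions,
                 strata_distributions = strata_dist,
                 nomogram = nomo, manifest = manifest))
}
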