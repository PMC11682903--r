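# Configuration objects for the synthetic PsA cohort generator.

#' Parametric specification of a continuous clinimetric score
#'
#' Small tagged list describing the sampling distribution of one continuous
#' (or count-valued) patient-level variable. Supported families:
#'
#' * `"gamma"`: gamma with `shape` and `rate` — right-skewed, nonnegative;
#'   the default family for scores summarised by median and IQR.
#' * `"zi_gamma"`: zero-inflated gamma, point mass `p0` at 0 plus a gamma
#'   tail, optionally capped at `cap` (for bounded instruments such as the
#'   0-10 global assessments or the 0-3 HAQ).
#' * `"lognormal"`: log-normal with `meanlog`, `sdlog`, left-truncated at
#'   `min` by inverse-CDF sampling.
#' * `"poisson"`: Poisson with mean `lambda` (integer-valued indices).
#'
#' @param type one of `"gamma"`, `"zi_gamma"`, `"lognormal"`, `"poisson"`.
#' @param ... family parameters as named values (see above).
#' @return an object of class `score_spec`.
#' @export
score_spec <- function(type = c("gamma", "zi_gamma", "lognormal", "poisson"), ...) {
  type <- match.arg(type)
  spec <- c(list(type = type), list(...))
  needed <- switch(type,
    gamma     = c("shape", "rate"),
    zi_gamma  = c("p0", "shape", "rate"),
    lognormal = c("meanlog", "sdlog"),
    poisson   = "lambda"
  )
  missing <- setdiff(needed, names(spec))
  if (length(missing) > 0) {
    stop("score_spec('", type, "') requires parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(spec, class = "score_spec")
}

#' Fit gamma parameters to a median and interquartile range
#'
#' Finds the gamma `shape` and `rate` whose 25th/50th/75th percentiles best
#' match the supplied quartiles (least squares on the quantile scale via
#' Nelder-Mead). Used to turn published median \[Q1, Q3\] summaries into a
#' sampling distribution.
#'
#' @param q1,med,q3 target quartiles, `0 <= q1 <= med <= q3`, `q3 > 0`.
#' @return a `score_spec` of type `"gamma"`.
#' @export
#' @examples
#' match_gamma_quartiles(1.11, 4.2, 9.25) # DAPSA-like skew
match_gamma_quartiles <- function(q1, med, q3) {
  stopifnot(q1 <= med, med <= q3, q3 > 0)
  target <- c(q1, med, q3)
  obj <- function(par) {
    q <- qgamma(c(0.25, 0.5, 0.75), shape = exp(par[1]), rate = exp(par[2]))
    sum((q - target)^2)
  }
  # moment-style start: lognormal-ish guess from the quartile spread
  start_shape <- if (q1 > 0) (2 * med / (q3 - q1))^2 else 1
  start <- log(c(max(start_shape, 0.1), max(start_shape, 0.1) / max(med, 0.1)))
  fit <- optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  score_spec("gamma", shape = exp(fit$par[1]), rate = exp(fit$par[2]))
}

sample_score <- function(spec, n) {
  stopifnot(inherits(spec, "score_spec"))
  switch(spec$type,
    gamma = rgamma(n, shape = spec$shape, rate = spec$rate),
    zi_gamma = {
      x <- rgamma(n, shape = spec$shape, rate = spec$rate)
      x[runif(n) < spec$p0] <- 0
      if (!is.null(spec$cap)) x <- pmin(x, spec$cap)
      x
    },
    lognormal = {
      lo <- if (is.null(spec$min)) 0 else spec$min
      # inverse-CDF truncation keeps one uniform draw per patient
      p_lo <- stats::plnorm(lo, spec$meanlog, spec$sdlog)
      qlnorm(p_lo + runif(n) * (1 - p_lo), spec$meanlog, spec$sdlog)
    },
    poisson = rpois(n, spec$lambda)
  )
}

default_prevalences <- function() {
  subset_raw <- c(axial = 0.109, peripheral = 0.723,
                  "axial+peripheral" = 0.139, enthesitic = 0.045)
  list(
    male = 0.524,
    psa_subset = subset_raw / sum(subset_raw),
    has_psoriasis = 0.785,
    # conditional on skin psoriasis; a patient may carry several subtypes
    pso_plaque = 0.814, pso_scalp = 0.176, pso_nail = 0.147,
    pso_palmoplantar = 0.083, pso_guttate = 0.010,
    obesity = 0.111, smoker = 0.275,
    osteoarthritis = 0.258, fibromyalgia = 0.157,
    dactylitis_history = 0.150, ibd = 0.015,
    steroid_use = 0.116, csdmard_combo = 0.341,
    management_problematic = 0.25
  )
}

default_score_distributions <- function() {
  list(
    age_years = match_gamma_quartiles(46, 53, 61),
    dapsa = match_gamma_quartiles(1.11, 4.2, 9.25),
    phga = score_spec("zi_gamma", p0 = 0.55, shape = 1.2, rate = 1, cap = 10),
    pga = score_spec("zi_gamma", p0 = 0.28, shape = 2, rate = 0.7, cap = 10),
    haq = score_spec("zi_gamma", p0 = 0.30, shape = 1, rate = 3.5, cap = 3),
    rdci = score_spec("poisson", lambda = 0.7),
    bsa_pct = score_spec("zi_gamma", p0 = 0.35, shape = 1, rate = 0.3, cap = 100),
    months_since_diagnosis = score_spec("lognormal",
      meanlog = log(154.5),
      sdlog = log(249.25 / 89) / (2 * qnorm(0.75)),
      min = 3),
    steroid_dose_mg = score_spec("gamma", shape = 2, rate = 0.4)
  )
}

default_effect_spec <- function() {
  list(
    base_rate = 0.003, # b/tsDMARD switches per month, reference patient
    coefficients = c(fibromyalgia = log(2),
                     steroid_use = log(1.5),
                     pso_nail = log(1.4))
  )
}

default_missingness <- function() {
  rep_named <- function(nms, x) setNames(rep(x, length(nms)), nms)
  rep_named(c("dapsa", "phga", "pga", "haq", "rdci", "bsa_pct",
              "obesity", "smoker"), 0.08)
}

#' Configuration for the synthetic PsA cohort generator
#'
#' Bundles the sample size, marginal prevalences, score distributions, the
#' planted count-generating model, and MCAR missingness rates. Defaults
#' emulate a published single-centre b/tsDMARD-treated PsA cohort of 267
#' patients (e.g. 52.4% male, 15.7% fibromyalgia, 11.6% corticosteroid
#' use, 72% peripheral-predominant arthritis; median disease duration
#' 154.5 months).
#'
#' @param n_patients cohort size (default 267).
#' @param prevalences named list of binary prevalences plus the
#'   `psa_subset` probability vector; probabilities in `[0, 1]`.
#' @param score_distributions named list of [score_spec()] objects.
#' @param effect_spec list with `base_rate` (b/tsDMARD initiations per
#'   month at covariate zero) and `coefficients` (named log rate ratios)
#'   for the planted drug-count model.
#' @param missingness named vector of MCAR missingness probabilities.
#' @param seed RNG seed used by [generate_cohort()]; `NULL` leaves the
#'   RNG state untouched.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 267,
                          prevalences = default_prevalences(),
                          score_distributions = default_score_distributions(),
                          effect_spec = default_effect_spec(),
                          missingness = default_missingness(),
                          seed = NULL) {
  config <- structure(
    list(n_patients = n_patients, prevalences = prevalences,
         score_distributions = score_distributions,
         effect_spec = effect_spec, missingness = missingness, seed = seed),
    class = "cohort_config")
  validate_cohort_config(config)
  config
}

validate_cohort_config <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.numeric(config$n_patients) || length(config$n_patients) != 1 ||
      config$n_patients < 1 || config$n_patients != round(config$n_patients)) {
    stop("n_patients must be a positive integer", call. = FALSE)
  }
  for (nm in names(config$prevalences)) {
    p <- config$prevalences[[nm]]
    if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
      stop("prevalence '", nm, "' must lie in [0, 1]", call. = FALSE)
    }
    if (length(p) > 1 && abs(sum(p) - 1) > 1e-8) {
      stop("probability vector '", nm, "' must sum to 1", call. = FALSE)
    }
  }
  for (nm in names(config$missingness)) {
    r <- config$missingness[[nm]]
    if (!is.numeric(r) || !is.finite(r) || r < 0 || r > 1) {
      stop("missingness rate '", nm, "' must lie in [0, 1]", call. = FALSE)
    }
  }
  if (!is.numeric(config$effect_spec$base_rate) ||
      config$effect_spec$base_rate < 0) {
    stop("effect_spec base_rate must be nonnegative", call. = FALSE)
  }
  invisible(config)
}
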