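# Rule-based D2T classification and Firth-penalized univariate associations.

#' Three-criterion difficult-to-treat (D2T) rule
#'
#' The preliminary D2T definition for PsA, adapted from the EULAR D2T-RA
#' criteria, requires all three of: (1) failure of at least
#' `min_failed_btsdmards` b/tsDMARDs (the current therapy is not counted
#' as a failure), (2) disease activity at least moderate — by default
#' DAPSA strictly above 14, and (3) management of signs and symptoms
#' perceived as problematic by the treating rheumatologist.
#'
#' @param min_failed_btsdmards minimum failed b/tsDMARD count (default 2).
#' @param dapsa_threshold DAPSA value strictly above which criterion 2 is
#'   met (default 14, the moderate-activity boundary).
#' @param management_problematic_required logical; if `FALSE` criterion 3
#'   always passes (default `TRUE`).
#' @param require_distinct_moa logical; the adapted definition asks for
#'   distinct mechanisms of action, but the cohort schema carries no
#'   per-drug mechanism data, so the rule degrades to a pure count —
#'   retained as a flag for schemas that do carry it (default `TRUE`,
#'   evaluated count-only here).
#' @return object of class `d2t_criteria`.
#' @export
d2t_criteria <- function(min_failed_btsdmards = 2,
                         dapsa_threshold = 14,
                         management_problematic_required = TRUE,
                         require_distinct_moa = TRUE) {
  stopifnot(min_failed_btsdmards >= 1, dapsa_threshold >= 0)
  structure(list(min_failed_btsdmards = min_failed_btsdmards,
                 dapsa_threshold = dapsa_threshold,
                 management_problematic_required = management_problematic_required,
                 require_distinct_moa = require_distinct_moa),
            class = "d2t_criteria")
}

#' DAPSA disease-activity category
#'
#' Partitions the DAPSA composite score into remission / low / moderate /
#' high activity. Boundaries belong to the lower category (the usual
#' `<=` convention): remission `<= 4`, low `<= 14`, moderate `<= 28`,
#' high `> 28` under the default cutpoints.
#'
#' @param dapsa numeric vector of DAPSA scores, `>= 0`; `NA` propagates.
#' @param cutpoints strictly increasing vector of three upper bounds.
#' @return factor with levels `remission`, `low`, `moderate`, `high`.
#' @export
#' @examples
#' dapsa_category(c(0, 4, 14, 28, 28.01))
dapsa_category <- function(dapsa, cutpoints = c(4, 14, 28)) {
  stopifnot(length(cutpoints) == 3, all(diff(cutpoints) > 0))
  if (any(dapsa < 0, na.rm = TRUE)) stop("dapsa must be >= 0", call. = FALSE)
  cut(dapsa, breaks = c(-Inf, cutpoints, Inf),
      labels = c("remission", "low", "moderate", "high"), right = TRUE)
}

#' Classify patients as difficult-to-treat
#'
#' Evaluates the three-criterion rule per patient. A patient missing a
#' field needed by an enabled criterion is flagged `indeterminate` and is
#' not counted as D2T.
#'
#' @param cohort cohort data frame with `n_prev_btsdmards`, `dapsa` and
#'   `management_problematic` columns.
#' @param criteria a [d2t_criteria()] object.
#' @return data frame with per-criterion pass flags
#'   (`criterion_failures`, `criterion_activity`, `criterion_management`),
#'   `is_d2t`, `indeterminate` and `dapsa_category`.
#' @export
classify_d2t <- function(cohort, criteria = d2t_criteria()) {
  stopifnot(inherits(criteria, "d2t_criteria"))
  if (any(is.na(cohort$n_prev_btsdmards))) {
    stop("n_prev_btsdmards must be observed for every patient", call. = FALSE)
  }
  c1 <- cohort$n_prev_btsdmards >= criteria$min_failed_btsdmards
  c2 <- cohort$dapsa > criteria$dapsa_threshold
  c3 <- if (criteria$management_problematic_required) {
    cohort$management_problematic
  } else {
    rep(TRUE, nrow(cohort))
  }
  indeterminate <- is.na(c1) | is.na(c2) | is.na(c3)
  is_d2t <- !indeterminate & c1 & c2 & c3
  n_ind <- sum(indeterminate)
  if (n_ind > 0) {
    message("classify_d2t: ", n_ind,
            " patient(s) indeterminate (missing criterion fields), not counted as D2T")
  }
  data.frame(patient_id = cohort$patient_id,
             criterion_failures = c1,
             criterion_activity = c2,
             criterion_management = c3,
             is_d2t = is_d2t,
             indeterminate = indeterminate,
             dapsa_category = dapsa_category(cohort$dapsa))
}

# Firth-penalized logistic regression: Newton iteration on the modified
# score U*(b) = X'(y - pi + h (1/2 - pi)), h = hat diagonal, with
# step-halving on the penalized log-likelihood  l(b) + 1/2 log det I(b).
firth_fit <- function(X, y, maxit = 100, tol = 1e-10) {
  p <- ncol(X)
  beta <- rep(0, p)
  pen_loglik <- function(beta) {
    eta <- drop(X %*% beta)
    pi <- plogis(eta)
    ll <- sum(y * eta - ifelse(eta > 30, eta, log1p(exp(eta))))
    info <- crossprod(X, X * (pi * (1 - pi)))
    ll + 0.5 * as.numeric(determinant(info, logarithm = TRUE)$modulus)
  }
  pl_old <- pen_loglik(beta)
  converged <- FALSE
  iter <- 0
  info_inv <- NULL
  for (iter in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    pi <- plogis(eta)
    w <- pi * (1 - pi)
    info <- crossprod(X, X * w)
    info_inv <- solve(info)
    h <- rowSums((X %*% info_inv) * (X * w))
    score <- drop(crossprod(X, y - pi + h * (0.5 - pi)))
    step <- drop(info_inv %*% score)
    # step-halving: never decrease the penalized likelihood
    for (half in 0:10) {
      cand <- beta + step / 2^half
      pl_new <- pen_loglik(cand)
      if (pl_new >= pl_old - 1e-12) break
    }
    beta <- cand
    moved <- max(abs(step / 2^half))
    pl_old <- pl_new
    if (moved < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  pi <- plogis(eta)
  info <- crossprod(X, X * (pi * (1 - pi)))
  list(coefficients = setNames(beta, colnames(X)),
       vcov = solve(info),
       pen_loglik = pen_loglik(beta),
       iter = iter, converged = converged)
}

#' Univariate Firth-penalized logistic association
#'
#' Fits a single-covariate logistic regression of a rare outcome (here:
#' D2T status) with the Jeffreys-prior penalty `1/2 log det I(beta)`.
#' The penalty keeps estimates finite under complete separation and
#' reduces small-sample bias — appropriate when only a handful of
#' patients are D2T. The odds ratio is per unit of the covariate; the
#' 95% interval is Wald, from the inverse penalized information.
#'
#' @param cohort cohort data frame.
#' @param outcome logical vector of outcome flags (one per row), or the
#'   name of a logical column.
#' @param covariate name of the covariate column (binary flags enter as
#'   0/1; continuous covariates per unit).
#' @return one-row data frame: `covariate`, `n`, `events`, `beta`, `se`,
#'   `odds_ratio`, `ci_low`, `ci_high`.
#' @export
firth_univariate <- function(cohort, outcome, covariate) {
  y <- if (is.character(outcome) && length(outcome) == 1) {
    cohort[[outcome]]
  } else {
    outcome
  }
  x <- as.numeric(cohort[[covariate]])
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- as.numeric(y[keep])
  if (sum(y) < 1) stop("outcome has no events", call. = FALSE)
  if (length(unique(x)) < 2) {
    stop("covariate '", covariate, "' has zero variance", call. = FALSE)
  }
  X <- cbind("(Intercept)" = 1, x)
  colnames(X)[2] <- covariate
  fit <- firth_fit(X, y)
  b <- fit$coefficients[2]
  se <- sqrt(fit$vcov[2, 2])
  z <- qnorm(0.975)
  data.frame(covariate = covariate, n = length(y), events = sum(y),
             beta = unname(b), se = se,
             odds_ratio = exp(unname(b)),
             ci_low = exp(unname(b) - z * se),
             ci_high = exp(unname(b) + z * se),
             row.names = NULL)
}
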