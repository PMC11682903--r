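# Poisson GLM with log link and log-expected offset; Wald tests;
# exponentiated effect reporting.

#' Fit a Poisson regression with an offset
#'
#' Maximum likelihood for `y_i ~ Poisson(mu_i)`,
#' `log mu_i = x_i' beta + offset_i`, by iteratively reweighted least
#' squares (via `stats::glm.fit`). With `offset = log(expected count)`
#' the exponentiated linear predictor is the modeled actual-to-expected
#' ratio, so `exp(beta)` is a relative treatment difficulty. The
#' covariance is the inverse Fisher information at the optimum.
#'
#' @param y nonnegative integer response (actual b/tsDMARD counts).
#' @param X design matrix with intercept column (see [prepare_design()]),
#'   full column rank.
#' @param offset numeric offset vector (log expected counts); defaults
#'   to zero.
#' @param blocks optional named list of covariate column blocks, carried
#'   along for block-wise selection.
#' @return object of class `poisson_offset_fit`: `coefficients`, `vcov`,
#'   `loglik`, `aic`, `fitted`, `deviance`, `iter`, plus the training
#'   `y`, `X`, `offset`, `blocks`.
#' @export
fit_poisson_offset <- function(y, X, offset = rep(0, length(y)), blocks = NULL) {
  X <- as.matrix(X)
  if (any(y < 0) || any(y != round(y))) {
    stop("y must be nonnegative integer counts", call. = FALSE)
  }
  if (any(!is.finite(offset))) stop("offset must be finite", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  fit <- glm.fit(X, y, family = poisson(), offset = offset,
                 control = list(epsilon = 1e-12, maxit = 100))
  if (!fit$converged) {
    stop("IRLS did not converge in ", fit$iter, " iterations (deviance ",
         format(fit$deviance), ")", call. = FALSE)
  }
  mu <- fit$fitted.values
  info <- crossprod(X, X * mu)
  vcov <- solve(info)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  ll <- sum(dpois(y, mu, log = TRUE))
  structure(list(coefficients = setNames(fit$coefficients, colnames(X)),
                 vcov = vcov, loglik = ll,
                 aic = -2 * ll + 2 * ncol(X),
                 fitted = mu, deviance = fit$deviance, iter = fit$iter,
                 y = y, X = X, offset = offset, blocks = blocks),
            class = "poisson_offset_fit")
}

#' @export
print.poisson_offset_fit <- function(x, ...) {
  cat("Poisson offset fit:", length(x$coefficients), "coefficients,",
      "logLik", format(x$loglik, digits = 6),
      "AIC", format(x$aic, digits = 6), "\n")
  print(x$coefficients)
  invisible(x)
}

#' Wald chi-square test on a coefficient subset
#'
#' `W = b_S' V_S^{-1} b_S` against chi-square with `|S|` degrees of
#' freedom; used in particular to test the joint nullity of the
#' nonlinear spline columns of a covariate.
#'
#' @param fit a `poisson_offset_fit`.
#' @param term_indices integer (or name) vector of coefficient indices;
#'   an empty set gives statistic 0 and p = 1.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
wald_test <- function(fit, term_indices) {
  if (is.character(term_indices)) {
    term_indices <- match(term_indices, names(fit$coefficients))
  }
  if (length(term_indices) == 0) {
    return(list(statistic = 0, df = 0L, p_value = 1))
  }
  stopifnot(all(term_indices >= 1), all(term_indices <= length(fit$coefficients)))
  b <- fit$coefficients[term_indices]
  V <- fit$vcov[term_indices, term_indices, drop = FALSE]
  Vinv <- tryCatch(solve(V), error = function(e) {
    stop("singular covariance for the requested terms", call. = FALSE)
  })
  stat <- drop(t(b) %*% Vinv %*% b)
  df <- length(term_indices)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Exponentiated effects on the relative-difficulty scale
#'
#' Reports `exp(beta)` with 95% Wald intervals per covariate. Categorical
#' dummies are the ratio of treatment difficulty between each level and
#' the reference; binary flags between presence and absence; linear terms
#' per unit increase. For spline-coded covariates a single number is
#' undefined, so the effect is the inter-quartile contrast — the modeled
#' difficulty ratio between the covariate's 75th and 25th percentile —
#' with a delta-method interval and the joint Wald p-value of the block.
#'
#' @param fit a `poisson_offset_fit` carrying `blocks`.
#' @param design the `d2t_design` that produced the fit (supplies spline
#'   knots and observed quartiles).
#' @return data frame: `covariate`, `term`, `estimate` (log scale), `se`,
#'   `effect`, `ci_low`, `ci_high`, `p_value`, `contrast`.
#' @export
relative_difficulty <- function(fit, design) {
  stopifnot(inherits(fit, "poisson_offset_fit"), !is.null(fit$blocks))
  z <- qnorm(0.975)
  rows <- list()
  for (nm in names(fit$blocks)) {
    idx <- fit$blocks[[nm]]
    type <- design$info[[nm]]$type
    if (type == "rcs") {
      qs <- design$info[[nm]]$quartiles
      knots <- design$info[[nm]]$knots
      basis_at <- function(v) drop(rcs_basis(v, knots))
      cvec <- basis_at(qs[2]) - basis_at(qs[1])
      b <- sum(cvec * fit$coefficients[idx])
      se <- sqrt(drop(t(cvec) %*% fit$vcov[idx, idx] %*% cvec))
      p <- wald_test(fit, idx)$p_value
      rows[[length(rows) + 1]] <- data.frame(
        covariate = nm, term = paste0(nm, " [Q3 vs Q1]"),
        estimate = b, se = se, effect = exp(b),
        ci_low = exp(b - z * se), ci_high = exp(b + z * se),
        p_value = p,
        contrast = sprintf("Q3 (%.3g) vs Q1 (%.3g)", qs[2], qs[1]))
    } else {
      for (j in idx) {
        b <- fit$coefficients[j]
        se <- sqrt(fit$vcov[j, j])
        rows[[length(rows) + 1]] <- data.frame(
          covariate = nm, term = names(fit$coefficients)[j],
          estimate = unname(b), se = se, effect = exp(unname(b)),
          ci_low = exp(unname(b) - z * se),
          ci_high = exp(unname(b) + z * se),
          p_value = wald_test(fit, j)$p_value,
          contrast = switch(type,
            binary = "present vs absent",
            factor = "level vs reference",
            linear = "per unit"))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
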