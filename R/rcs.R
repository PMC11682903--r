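# Restricted (natural) cubic spline basis, truncated-power parameterization.

#' Default restricted-cubic-spline knot locations
#'
#' Quantile-based knot placement following the usual clinical-modelling
#' convention: 3 knots at the 10th/50th/90th percentiles, 4 at
#' 5/35/65/95, 5 at 5/27.5/50/72.5/95.
#'
#' @param x numeric vector.
#' @param n_knots number of knots (3-7).
#' @return numeric vector of strictly increasing knots.
#' @export
rcs_knots <- function(x, n_knots = 3) {
  probs <- switch(as.character(n_knots),
    "3" = c(0.10, 0.50, 0.90),
    "4" = c(0.05, 0.35, 0.65, 0.95),
    "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
    "6" = c(0.05, 0.23, 0.41, 0.59, 0.77, 0.95),
    "7" = c(0.025, 0.1833, 0.3417, 0.50, 0.6583, 0.8167, 0.975),
    stop("n_knots must be between 3 and 7", call. = FALSE))
  x <- x[!is.na(x)]
  if (length(unique(x)) < n_knots) {
    stop("fewer than ", n_knots,
         " distinct values; use a linear term instead", call. = FALSE)
  }
  k <- quantile(x, probs, type = 7, names = FALSE)
  if (any(diff(k) <= 0)) {
    stop("quantile-based knots are not distinct (heavy ties); ",
         "use a linear term or explicit knots", call. = FALSE)
  }
  k
}

#' Restricted cubic spline basis
#'
#' Truncated-power natural cubic spline basis with `k` knots: the first
#' column is `x` itself and the `k - 2` nonlinear columns are cubic
#' between the boundary knots and exactly linear outside them (twice
#' continuously differentiable at interior knots). Nonlinear columns are
#' normalized by the squared boundary-knot span so their scale is
#' comparable to `x`.
#'
#' @param x numeric vector.
#' @param knots strictly increasing knot vector of length >= 3, or a
#'   single integer giving the knot count for [rcs_knots()] placement.
#' @return matrix with `length(knots) - 1` columns; attribute `"knots"`
#'   carries the knots used.
#' @export
#' @examples
#' b <- rcs_basis(seq(0, 10, 0.5), knots = c(2, 5, 8))
#' ncol(b) # k - 1 = 2
rcs_basis <- function(x, knots = 3) {
  if (length(knots) == 1) knots <- rcs_knots(x, knots)
  k <- length(knots)
  stopifnot(k >= 3, all(diff(knots) > 0))
  cub <- function(u) pmax(u, 0)^3
  norm <- (knots[k] - knots[1])^2
  out <- matrix(NA_real_, length(x), k - 1)
  out[, 1] <- x
  tk <- knots[k]
  tk1 <- knots[k - 1]
  for (j in seq_len(k - 2)) {
    tj <- knots[j]
    out[, j + 1] <- (cub(x - tj) -
                       cub(x - tk1) * (tk - tj) / (tk - tk1) +
                       cub(x - tk) * (tk1 - tj) / (tk - tk1)) / norm
  }
  colnames(out) <- c("", paste0("_nl", seq_len(k - 2)))
  attr(out, "knots") <- knots
  out
}
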