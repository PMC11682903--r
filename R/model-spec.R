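# Covariate codings and design-matrix construction for the
# relative-difficulty models. Each covariate occupies a named block of
# design columns; blocks enter and leave selection together.

#' Covariate codings
#'
#' Declare how a cohort column enters the model design:
#' `cov_binary()` — a single 0/1 column from a logical or 0/1 variable;
#' `cov_factor()` — dummy columns against a named reference level;
#' `cov_linear()` — the variable as-is;
#' `cov_rcs()` — a restricted-cubic-spline block (see [rcs_basis()]).
#'
#' @param name cohort column name.
#' @param ref reference level (factor coding).
#' @param n_knots,knots knot count or explicit knots (spline coding).
#' @return a `cov_spec` object.
#' @name covariate-codings
NULL

#' @rdname covariate-codings
#' @export
cov_binary <- function(name) {
  structure(list(name = name, type = "binary"), class = "cov_spec")
}

#' @rdname covariate-codings
#' @export
cov_factor <- function(name, ref) {
  structure(list(name = name, type = "factor", ref = ref), class = "cov_spec")
}

#' @rdname covariate-codings
#' @export
cov_linear <- function(name) {
  structure(list(name = name, type = "linear"), class = "cov_spec")
}

#' @rdname covariate-codings
#' @export
cov_rcs <- function(name, n_knots = 3, knots = NULL) {
  structure(list(name = name, type = "rcs", n_knots = n_knots, knots = knots),
            class = "cov_spec")
}

cov_columns <- function(spec, x, info = NULL) {
  switch(spec$type,
    binary = {
      v <- as.numeric(x)
      if (any(!v %in% c(0, 1), na.rm = TRUE)) {
        stop("covariate '", spec$name, "' is not binary", call. = FALSE)
      }
      m <- matrix(v, ncol = 1)
      colnames(m) <- spec$name
      list(X = m, info = list(type = "binary"))
    },
    factor = {
      levels <- if (is.null(info)) {
        c(spec$ref, setdiff(sort(unique(x[!is.na(x)])), spec$ref))
      } else {
        info$levels
      }
      f <- factor(x, levels = levels)
      if (is.null(info) && any(is.na(f) & !is.na(x))) {
        stop("covariate '", spec$name, "' has values outside its levels",
             call. = FALSE)
      }
      m <- sapply(levels[-1], function(l) as.numeric(f == l))
      m <- matrix(m, nrow = length(x))
      colnames(m) <- paste0(spec$name, "=", levels[-1])
      list(X = m, info = list(type = "factor", levels = levels))
    },
    linear = {
      m <- matrix(as.numeric(x), ncol = 1)
      colnames(m) <- spec$name
      list(X = m, info = list(type = "linear"))
    },
    rcs = {
      knots <- if (is.null(info)) {
        if (is.null(spec$knots)) rcs_knots(as.numeric(x), spec$n_knots)
        else spec$knots
      } else {
        info$knots
      }
      qs <- if (is.null(info)) {
        quantile(as.numeric(x), c(0.25, 0.75), na.rm = TRUE,
                 type = 7, names = FALSE)
      } else {
        info$quartiles
      }
      b <- rcs_basis(as.numeric(x), knots)
      colnames(b) <- paste0(spec$name, colnames(b))
      list(X = unclass(b)[, , drop = FALSE],
           info = list(type = "rcs", knots = knots, quartiles = qs))
    }
  )
}

#' Build a model design from covariate codings
#'
#' Constructs the design matrix (leading intercept column) and records
#' per-covariate column blocks plus the data-dependent coding state
#' (factor levels, spline knots, observed quartiles) so the identical
#' design can be applied to new data with [apply_design()].
#'
#' @param data cohort data frame.
#' @param covariates list of `cov_spec` codings (see
#'   [covariate-codings]).
#' @return object of class `d2t_design` with elements `X` (matrix),
#'   `blocks` (named list of column indices, intercept excluded),
#'   `covariates` and `info`.
#' @export
prepare_design <- function(data, covariates) {
  stopifnot(length(covariates) > 0)
  names(covariates) <- vapply(covariates, `[[`, "", "name")
  X <- matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
  blocks <- list()
  info <- list()
  for (spec in covariates) {
    if (is.null(data[[spec$name]])) {
      stop("covariate '", spec$name, "' not found in data", call. = FALSE)
    }
    built <- cov_columns(spec, data[[spec$name]])
    blocks[[spec$name]] <- ncol(X) + seq_len(ncol(built$X))
    info[[spec$name]] <- built$info
    X <- cbind(X, built$X)
  }
  structure(list(X = X, blocks = blocks, covariates = covariates,
                 info = info),
            class = "d2t_design")
}

#' @rdname prepare_design
#' @param design a `d2t_design` from `prepare_design()`.
#' @param newdata data frame with the same covariate columns.
#' @return `apply_design()` returns the design matrix for `newdata`
#'   under the stored coding state.
#' @export
apply_design <- function(design, newdata) {
  stopifnot(inherits(design, "d2t_design"))
  X <- matrix(1, nrow(newdata), 1, dimnames = list(NULL, "(Intercept)"))
  for (spec in design$covariates) {
    built <- cov_columns(spec, newdata[[spec$name]],
                         info = design$info[[spec$name]])
    X <- cbind(X, built$X)
  }
  colnames(X) <- colnames(design$X)
  X
}
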