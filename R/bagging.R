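# Multivariable procedure: complete-case filtering, backward-AIC block
# selection, bootstrap bagging with zero-imputed coefficient averaging,
# ratio prediction and nomogram construction.

#' Complete-case filtering
#'
#' Keeps exactly the rows with no missing value in any listed covariate
#' (index fields — counts, follow-up — are never missing by
#' construction). Retained/dropped counts are messaged.
#'
#' @param cohort cohort data frame.
#' @param covariates character vector of column names.
#' @return the filtered cohort, with attributes `n_input` and
#'   `n_dropped`.
#' @export
complete_cases <- function(cohort, covariates) {
  stopifnot(length(covariates) > 0)
  missing_cols <- setdiff(covariates, names(cohort))
  if (length(missing_cols) > 0) {
    stop("unknown covariate(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  keep <- !Reduce(`|`, lapply(cohort[covariates], is.na))
  out <- cohort[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    stop("no complete cases; reduce the covariate set", call. = FALSE)
  }
  message("complete_cases: retained ", nrow(out), " of ", nrow(cohort),
          " rows (", nrow(cohort) - nrow(out), " dropped)")
  attr(out, "n_input") <- nrow(cohort)
  attr(out, "n_dropped") <- nrow(cohort) - nrow(out)
  out
}

refit_blocks <- function(y, X, offset, blocks, keep) {
  idx <- c(1L, unlist(blocks[keep], use.names = FALSE))
  fit_poisson_offset(y, X[, idx, drop = FALSE], offset, blocks = NULL)
}

#' Backward variable selection by AIC
#'
#' Starting from the full model, iteratively removes the covariate block
#' (all dummy/spline columns of one covariate move together) whose
#' removal yields the largest AIC reduction; stops when no removal
#' reduces the AIC. The intercept and offset are never candidates. Ties
#' break deterministically towards the block earliest in the
#' specification order.
#'
#' @param y counts; `X` full design matrix with intercept; `offset`
#'   log-expected offset; `blocks` named list of covariate column
#'   blocks (indices into `X`).
#' @param X,offset,blocks see above.
#' @return list: `selected` (names of retained covariates), `dropped`
#'   (in removal order), `fit` (the final `poisson_offset_fit`),
#'   `coefficients_full` (length `ncol(X)`, zero for removed blocks),
#'   `aic_path` (AIC after each accepted step, starting at the full
#'   model).
#' @export
backward_aic <- function(y, X, offset, blocks) {
  keep <- names(blocks)
  fit <- refit_blocks(y, X, offset, blocks, keep)
  aic_path <- fit$aic
  dropped <- character(0)
  while (length(keep) > 0) {
    cand_aic <- vapply(keep, function(nm) {
      refit_blocks(y, X, offset, blocks, setdiff(keep, nm))$aic
    }, 0)
    best <- which.min(cand_aic) # first minimum = earliest in spec order
    if (cand_aic[best] < fit$aic) {
      dropped <- c(dropped, keep[best])
      keep <- setdiff(keep, keep[best])
      fit <- refit_blocks(y, X, offset, blocks, keep)
      aic_path <- c(aic_path, fit$aic)
    } else {
      break
    }
  }
  coefs <- setNames(numeric(ncol(X)), colnames(X))
  kept_idx <- c(1L, unlist(blocks[keep], use.names = FALSE))
  coefs[kept_idx] <- fit$coefficients
  list(selected = keep, dropped = dropped, fit = fit,
       coefficients_full = coefs, aic_path = aic_path)
}

#' Bootstrap-bagged backward-AIC selection
#'
#' Draws `n_resamples` bootstrap samples of the rows (with replacement),
#' runs [backward_aic()] in each, and records the retained covariate set
#' and the coefficient vector with zeros for unselected blocks. A
#' resample whose design loses full column rank (e.g. a dummy level
#' absent from the draw) is recorded as degenerate and redrawn, keeping
#' the coefficient vectors conformable; more than 20% degenerate draws
#' aborts with advice to prune the covariate set. Fully reproducible for
#' a given seed.
#'
#' @param y,X,offset,blocks as in [backward_aic()], on complete-case
#'   data.
#' @param n_resamples number of bootstrap resamples (default 1000).
#' @param seed RNG seed (default 1).
#' @param no_resample diagnostic mode: every "resample" is the original
#'   data, so the averaged coefficients must equal the single
#'   backward-AIC fit.
#' @return object of class `bagging_result`: `selection_frequency`
#'   (named, per covariate), `coefficient_draws` (`n_resamples x
#'   ncol(X)` matrix, zeros where unselected), `averaged_coefficients`,
#'   `resample_log` (data frame: resample, retained set, final AIC,
#'   steps), `n_degenerate`, `n_resamples`, `seed`.
#' @export
bootstrap_bag <- function(y, X, offset, blocks, n_resamples = 1000,
                          seed = 1, no_resample = FALSE) {
  stopifnot(n_resamples >= 1)
  set.seed(seed)
  n <- length(y)
  p <- ncol(X)
  draws <- matrix(0, n_resamples, p, dimnames = list(NULL, colnames(X)))
  selected <- matrix(FALSE, n_resamples, length(blocks),
                     dimnames = list(NULL, names(blocks)))
  log_rows <- vector("list", n_resamples)
  n_degenerate <- 0L
  max_degenerate <- ceiling(0.2 * n_resamples)
  for (b in seq_len(n_resamples)) {
    repeat {
      idx <- if (no_resample) seq_len(n) else sample.int(n, n, replace = TRUE)
      if (qr(X[idx, , drop = FALSE])$rank == p) break
      n_degenerate <- n_degenerate + 1L
      if (n_degenerate > max_degenerate) {
        stop("more than 20% of bootstrap resamples were degenerate ",
             "(rank-deficient design); prune rare covariate levels",
             call. = FALSE)
      }
    }
    bw <- backward_aic(y[idx], X[idx, , drop = FALSE], offset[idx], blocks)
    draws[b, ] <- bw$coefficients_full
    selected[b, bw$selected] <- TRUE
    log_rows[[b]] <- data.frame(
      resample = b,
      retained = paste(bw$selected, collapse = "+"),
      aic = bw$fit$aic,
      steps = length(bw$aic_path) - 1L)
  }
  structure(list(selection_frequency = colMeans(selected),
                 coefficient_draws = draws,
                 averaged_coefficients = colMeans(draws),
                 resample_log = do.call(rbind, log_rows),
                 n_degenerate = n_degenerate,
                 n_resamples = n_resamples,
                 seed = seed,
                 no_resample = no_resample),
            class = "bagging_result")
}

#' @export
print.bagging_result <- function(x, ...) {
  cat("Bagged backward-AIC selection:", x$n_resamples, "resamples",
      if (x$no_resample) "(no-resample diagnostic)" else "",
      "| degenerate redraws:", x$n_degenerate, "\n")
  print(round(sort(x$selection_frequency, decreasing = TRUE), 3))
  invisible(x)
}

#' Zero-imputed coefficient averaging
#'
#' Averages each design coefficient over all resamples with zeros for
#' resamples where its covariate was not selected; algebraically the
#' selection frequency times the mean conditional-on-selection
#' coefficient. All covariates stay in the final model — selection only
#' zeroes them per resample.
#'
#' @param result a `bagging_result`.
#' @param design the `d2t_design` the bagging ran on (stored so the
#'   model can be applied to new data).
#' @return object of class `final_model`: `coefficients` (averaged,
#'   intercept first), `selection_frequency`, `design`, `blocks`.
#' @export
average_coefficients <- function(result, design) {
  stopifnot(inherits(result, "bagging_result"))
  structure(list(coefficients = result$averaged_coefficients,
                 selection_frequency = result$selection_frequency,
                 design = design,
                 blocks = design$blocks),
            class = "final_model")
}

#' Predict the difficulty ratio and stratify patients
#'
#' The fitting construction (response = actual count, offset = log
#' expected count) makes `exp(x' beta)` the modeled actual-to-expected
#' ratio, so the final model predicts each patient's difficulty ratio
#' directly — the offset cancels. Patients are stratified at 1 and 1.5.
#' Rows missing a model covariate are skipped with a message.
#'
#' @param final a `final_model`.
#' @param newdata cohort data frame.
#' @return data frame: `patient_id`, `predicted_ratio`, `stratum`
#'   (factor `<=1`, `(1,1.5]`, `>1.5`).
#' @export
predict_and_stratify <- function(final, newdata) {
  stopifnot(inherits(final, "final_model"))
  covs <- names(final$blocks)
  complete <- !Reduce(`|`, lapply(newdata[covs], is.na))
  if (any(!complete)) {
    message("predict_and_stratify: skipped ", sum(!complete),
            " patient(s) with missing model covariates")
  }
  dat <- newdata[complete, , drop = FALSE]
  Xn <- apply_design(final$design, dat)
  ratio <- exp(drop(Xn %*% final$coefficients))
  data.frame(patient_id = dat$patient_id,
             predicted_ratio = ratio,
             stratum = cut(ratio, breaks = c(-Inf, 1, 1.5, Inf),
                           labels = c("<=1", "(1,1.5]", ">1.5"),
                           right = TRUE))
}

#' Nomogram table for the final model
#'
#' Tabular nomogram: each covariate's contribution to the linear
#' predictor over its observed range is rescaled to points so the widest
#' single-covariate range spans 100 points; the total-points axis maps
#' linearly back to the linear predictor and exponentially to the
#' predicted difficulty ratio. A covariate with zero averaged
#' coefficient gets a zero point range.
#'
#' @param final a `final_model`.
#' @param data cohort data frame supplying the observed covariate ranges
#'   (typically the complete-case fitting data).
#' @return object of class `nomogram_table`: `$table` (per covariate:
#'   `covariate`, `contrib_min`, `contrib_max`, `points_range`),
#'   `$scale` (points per linear-predictor unit), `$const` (linear
#'   predictor at zero total points).
#' @export
nomogram_table <- function(final, data) {
  stopifnot(inherits(final, "final_model"))
  X <- apply_design(final$design, data)
  beta <- final$coefficients
  contrib <- lapply(names(final$blocks), function(nm) {
    idx <- final$blocks[[nm]]
    drop(X[, idx, drop = FALSE] %*% beta[idx])
  })
  names(contrib) <- names(final$blocks)
  lo <- vapply(contrib, min, 0)
  hi <- vapply(contrib, max, 0)
  width <- hi - lo
  if (max(width) <= 0) {
    stop("all averaged coefficients are zero; no nomogram", call. = FALSE)
  }
  scale <- 100 / max(width)
  tab <- data.frame(covariate = names(contrib),
                    contrib_min = lo, contrib_max = hi,
                    points_range = width * scale,
                    row.names = NULL)
  structure(list(table = tab, scale = scale,
                 const = unname(beta[1]) + sum(lo),
                 final = final),
            class = "nomogram_table")
}

#' @rdname nomogram_table
#' @param nomo a `nomogram_table`.
#' @param newdata cohort rows to score.
#' @return `total_points()` returns each patient's total points;
#'   `predict_from_points()` maps total points back to the predicted
#'   ratio (`exp(points / scale + const)`).
#' @export
total_points <- function(nomo, newdata) {
  stopifnot(inherits(nomo, "nomogram_table"))
  final <- nomo$final
  X <- apply_design(final$design, newdata)
  pts <- 0
  for (i in seq_along(final$blocks)) {
    idx <- final$blocks[[i]]
    contrib <- drop(X[, idx, drop = FALSE] %*% final$coefficients[idx])
    pts <- pts + (contrib - nomo$table$contrib_min[i]) * nomo$scale
  }
  pts
}

#' @rdname nomogram_table
#' @param points numeric vector of total points.
#' @export
predict_from_points <- function(nomo, points) {
  stopifnot(inherits(nomo, "nomogram_table"))
  exp(points / nomo$scale + nomo$const)
}
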