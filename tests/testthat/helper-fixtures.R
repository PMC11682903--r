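# Shared fixtures: small cohorts and count data generated in code.

# minimal hand-built cohort with fully controlled fields
tiny_cohort <- function() {
  data.frame(
    patient_id = 1:4,
    sex = c("M", "F", "F", "M"),
    dapsa = c(2, 22, 30, NA),
    n_prev_btsdmards = c(0L, 3L, 2L, 5L),
    months_since_diagnosis = c(24, 120, 60, 200),
    management_problematic = c(FALSE, TRUE, FALSE, TRUE),
    fibromyalgia = c(FALSE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

# Poisson counts with exposure offset and binary covariates:
# y_i ~ Poisson(E_i * exp(b0 + x_i' beta)), offset = log E_i
make_count_data <- function(n, beta, prev = NULL, b0 = 0, seed = 1,
                            exposure = NULL) {
  set.seed(seed)
  k <- length(beta)
  if (is.null(prev)) prev <- rep(0.5, k)
  X <- sapply(seq_len(k), function(j) rbinom(n, 1, prev[j]))
  X <- matrix(X, nrow = n)
  colnames(X) <- names(beta) %||% paste0("x", seq_len(k))
  if (is.null(exposure)) exposure <- runif(n, 0.5, 2)
  mu <- exposure * exp(b0 + drop(X %*% beta))
  list(y = rpois(n, mu),
       X = cbind("(Intercept)" = 1, X),
       offset = log(exposure),
       blocks = setNames(as.list(seq_len(k) + 1L), colnames(X)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent closed-form oracle for the 2x2 Firth slope:
# log odds ratio after adding 0.5 to every cell
firth_2x2_oracle <- function(tab) {
  log((tab[2, 2] + 0.5) * (tab[1, 1] + 0.5) /
        ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5)))
}

# expand a 2x2 table (rows x = 0/1, cols y = 0/1) to patient-level data
expand_2x2 <- function(tab) {
  x <- rep(c(0, 0, 1, 1), times = c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
  y <- rep(c(0, 1, 0, 1), times = c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
  data.frame(x = x, y = y)
}
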