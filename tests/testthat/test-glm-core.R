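test_that("restricted cubic spline basis has the natural-spline shape", {
  knots <- c(2, 4, 6, 8)
  x <- seq(0, 10, by = 0.01)
  b <- rcs_basis(x, knots)
  expect_equal(ncol(b), 3) # k - 1 columns
  expect_equal(b[, 1], x)  # first column is x itself
  # below the first knot every nonlinear column is exactly 0
  expect_true(all(b[x < 2, -1] == 0))
  # numerical second derivative vanishes beyond the boundary knots
  h <- 0.01
  right <- seq(8.5, 9.5, by = h)
  br <- rcs_basis(right, knots)
  d2 <- diff(br[, 2], differences = 2) / h^2
  expect_lt(max(abs(d2)), 1e-8)
  # 3 knots -> exactly 2 columns
  expect_equal(ncol(rcs_basis(x, c(2, 5, 8))), 2)
  # continuity and smoothness at an interior knot
  eps <- 1e-6
  at <- rcs_basis(c(4 - eps, 4, 4 + eps), knots)
  expect_lt(max(abs(diff(at[, 2]))), 1e-5)
})

test_that("quantile knot placement rejects degenerate inputs", {
  expect_error(rcs_knots(c(1, 1, 1, 2), 3), "linear")
  expect_error(rcs_knots(runif(100), 8), "between 3 and 7")
  expect_error(rcs_knots(c(rep(0, 60), runif(40)), 3), "linear|ties")
  k <- rcs_knots(1:100, 3)
  expect_equal(k, quantile(1:100, c(0.1, 0.5, 0.9), names = FALSE))
})

test_that("intercept-only Poisson-offset fit equals the closed-form rate MLE", {
  set.seed(10)
  n <- 200
  expected <- sample(1:6, n, replace = TRUE)
  y <- rpois(n, expected * 0.8)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- fit_poisson_offset(y, X, log(expected))
  expect_equal(exp(unname(fit$coefficients)), sum(y) / sum(expected),
               tolerance = 1e-10)
  # AIC consistent with its own log-likelihood
  expect_equal(fit$aic, -2 * fit$loglik + 2)
})

test_that("single binary covariate recovers the stratified rate ratio exactly", {
  set.seed(11)
  n <- 300
  g <- rbinom(n, 1, 0.4)
  expected <- runif(n, 1, 5)
  y <- rpois(n, expected * exp(-0.2 + 0.7 * g))
  X <- cbind("(Intercept)" = 1, g = g)
  fit <- fit_poisson_offset(y, X, log(expected))
  oracle <- (sum(y[g == 1]) / sum(expected[g == 1])) /
    (sum(y[g == 0]) / sum(expected[g == 0]))
  expect_equal(exp(unname(fit$coefficients["g"])), oracle, tolerance = 1e-8)
  # score equations X'(y - mu) = 0 at convergence
  expect_lt(max(abs(crossprod(fit$X, fit$y - fit$fitted))), 1e-6)
})

test_that("offset behaves as exposure: coefficients invariant, means scale", {
  d <- make_count_data(400, c(a = 0.5, b = -0.3), seed = 12)
  fit <- fit_poisson_offset(d$y, d$X, d$offset)
  # same fit expressed with a shifted offset: slopes unchanged
  fit2 <- fit_poisson_offset(d$y, d$X, d$offset + log(2))
  expect_equal(fit$coefficients[-1], fit2$coefficients[-1], tolerance = 1e-10)
  expect_equal(unname(fit$coefficients[1] - fit2$coefficients[1]), log(2),
               tolerance = 1e-10)
  expect_equal(fit$fitted, fit2$fitted, tolerance = 1e-8)
})

test_that("rank-deficient designs fail loudly, naming aliased columns", {
  d <- make_count_data(100, c(a = 0.2), seed = 13)
  X <- cbind(d$X, a_copy = d$X[, "a"])
  expect_error(fit_poisson_offset(d$y, X, d$offset), "a_copy")
  expect_error(fit_poisson_offset(c(-1, d$y[-1]), d$X, d$offset),
               "nonnegative")
  expect_error(fit_poisson_offset(d$y, d$X, rep(Inf, 100)), "finite")
})

test_that("a pure-noise column cannot decrease the maximized log-likelihood", {
  d <- make_count_data(300, c(a = 0.4), seed = 14)
  fit <- fit_poisson_offset(d$y, d$X, d$offset)
  set.seed(15)
  X2 <- cbind(d$X, noise = rnorm(300))
  fit2 <- fit_poisson_offset(d$y, X2, d$offset)
  expect_gte(fit2$loglik, fit$loglik - 1e-10)
})

test_that("Wald test identities hold", {
  d <- make_count_data(500, c(a = 0.6, b = 0), seed = 16)
  fit <- fit_poisson_offset(d$y, d$X, d$offset, blocks = d$blocks)
  # 1-df Wald equals (beta / se)^2
  w <- wald_test(fit, 2)
  expect_equal(w$statistic,
               (fit$coefficients[[2]] / sqrt(fit$vcov[2, 2]))^2,
               tolerance = 1e-10)
  # empty set: statistic 0, p = 1
  w0 <- wald_test(fit, integer(0))
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p_value, 1)
  # p decreasing in the statistic at fixed df
  expect_gt(wald_test(fit, 3)$p_value, w$p_value)
})

test_that("relative_difficulty reports exponentiated effects with 95% CIs", {
  set.seed(17)
  n <- 4000
  dat <- data.frame(fibromyalgia = rbinom(n, 1, 0.3) == 1,
                    age = runif(n, 30, 70))
  expected <- runif(n, 1, 4)
  y <- rpois(n, expected * exp(-0.1 + log(2) * dat$fibromyalgia +
                                 0.005 * dat$age))
  des <- prepare_design(dat, list(cov_binary("fibromyalgia"),
                                  cov_rcs("age", n_knots = 3)))
  fit <- fit_poisson_offset(y, des$X, log(expected), blocks = des$blocks)
  eff <- relative_difficulty(fit, des)
  fib <- eff[eff$covariate == "fibromyalgia", ]
  expect_equal(fib$effect, 2.0, tolerance = 0.1)
  expect_true(fib$ci_low <= fib$effect && fib$effect <= fib$ci_high)
  # spline covariate reported as a single inter-quartile contrast
  age <- eff[eff$covariate == "age", ]
  expect_equal(nrow(age), 1)
  qs <- des$info$age$quartiles
  expect_equal(age$effect, exp(0.005 * (qs[2] - qs[1])), tolerance = 0.05)
})

test_that("RCS fit reproduces a linear truth without spurious curvature", {
  set.seed(18)
  n <- 2000
  x <- runif(n, 0, 10)
  y <- rpois(n, exp(0.1 + 0.15 * x))
  dat <- data.frame(x = x)
  des <- prepare_design(dat, list(cov_rcs("x", n_knots = 3)))
  fit <- fit_poisson_offset(y, des$X, rep(0, n), blocks = des$blocks)
  nl <- wald_test(fit, des$blocks$x[-1])
  # nonlinear term should not be significant under a linear truth
  expect_gt(nl$p_value, 0.001)
  # fitted log-means close to the generating line
  expect_lt(mean(abs(log(fit$fitted) - (0.1 + 0.15 * x))), 0.05)
})
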