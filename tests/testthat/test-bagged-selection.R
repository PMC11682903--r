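test_that("complete_cases keeps exactly the fully observed rows", {
  cohort <- tiny_cohort()
  expect_message(out <- complete_cases(cohort, c("dapsa", "sex")),
                 "retained 3 of 4")
  expect_equal(out$patient_id, 1:3) # only row 4 misses dapsa
  expect_equal(attr(out, "n_dropped"), 1)
  # no missingness: identity
  full <- complete_cases(cohort, "sex")
  expect_equal(full$patient_id, cohort$patient_id)
  expect_error(complete_cases(cohort, "nope"), "unknown")
  all_na <- cohort
  all_na$dapsa <- NA_real_
  expect_error(suppressMessages(complete_cases(all_na, "dapsa")),
               "no complete cases")
})

test_that("backward AIC drops noise, keeps signal, and its path decreases", {
  d <- make_count_data(1000, c(strong = log(3), n1 = 0, n2 = 0, n3 = 0),
                       seed = 21)
  bw <- backward_aic(d$y, d$X, d$offset, d$blocks)
  expect_true("strong" %in% bw$selected)
  expect_true(all(diff(bw$aic_path) < 0))
  # zero-imputed full-length coefficients, conformable with the design
  expect_equal(length(bw$coefficients_full), ncol(d$X))
  dropped_cols <- unlist(d$blocks[bw$dropped])
  expect_true(all(bw$coefficients_full[dropped_cols] == 0))
  kept_cols <- unlist(d$blocks[bw$selected])
  expect_equal(unname(bw$coefficients_full[kept_cols]),
               unname(bw$fit$coefficients[-1]))
})

test_that("a strong single-covariate truth is selected essentially always", {
  hits <- 0
  for (seed in 1:30) {
    d <- make_count_data(1000, c(strong = log(3), n1 = 0, n2 = 0),
                         seed = 100 + seed)
    bw <- backward_aic(d$y, d$X, d$offset, d$blocks)
    hits <- hits + ("strong" %in% bw$selected)
  }
  expect_gte(hits / 30, 0.99)
})

test_that("factor and spline columns move as one block", {
  set.seed(23)
  n <- 500
  dat <- data.frame(grp = sample(c("a", "b", "c"), n, replace = TRUE),
                    z = runif(n, 0, 5))
  y <- rpois(n, exp(0.2)) # neither covariate matters
  des <- prepare_design(dat, list(cov_factor("grp", ref = "a"),
                                  cov_rcs("z", n_knots = 3)))
  bw <- backward_aic(y, des$X, rep(0, n), des$blocks)
  for (nm in bw$dropped) {
    expect_true(all(bw$coefficients_full[des$blocks[[nm]]] == 0))
  }
  # both blocks should go under a null truth here (AIC penalty 2/col)
  expect_true(length(bw$selected) <= 1)
})

test_that("no-resample diagnostic equals the single backward-AIC fit exactly", {
  d <- make_count_data(300, c(a = 0.8, b = 0, c = 0), seed = 24)
  bag <- bootstrap_bag(d$y, d$X, d$offset, d$blocks, n_resamples = 5,
                       seed = 1, no_resample = TRUE)
  bw <- backward_aic(d$y, d$X, d$offset, d$blocks)
  expect_identical(bag$averaged_coefficients, bw$coefficients_full)
  expect_true(all(bag$selection_frequency %in% c(0, 1)))
})

test_that("bagging is byte-identical under a fixed seed", {
  d <- make_count_data(200, c(a = 0.7, b = 0), seed = 25)
  b1 <- bootstrap_bag(d$y, d$X, d$offset, d$blocks, n_resamples = 40, seed = 9)
  b2 <- bootstrap_bag(d$y, d$X, d$offset, d$blocks, n_resamples = 40, seed = 9)
  expect_identical(b1, b2)
  b3 <- bootstrap_bag(d$y, d$X, d$offset, d$blocks, n_resamples = 40, seed = 10)
  expect_false(identical(b1$coefficient_draws, b3$coefficient_draws))
})

test_that("averaging identity: mean draw = frequency x conditional mean", {
  d <- make_count_data(250, c(a = 0.6, b = 0.2, c = 0), seed = 26)
  bag <- bootstrap_bag(d$y, d$X, d$offset, d$blocks, n_resamples = 60, seed = 2)
  for (nm in names(d$blocks)) {
    col <- d$blocks[[nm]]
    draws <- bag$coefficient_draws[, col]
    freq <- bag$selection_frequency[[nm]]
    cond_mean <- if (freq > 0) mean(draws[draws != 0]) else 0
    expect_equal(mean(draws), freq * cond_mean, tolerance = 1e-12)
    # shrinkage towards zero whenever not always selected
    if (freq < 1 && freq > 0) {
      expect_lte(abs(mean(draws)), abs(cond_mean) + 1e-12)
    }
  }
})

test_that("selection frequency orders with planted effect strength", {
  d <- make_count_data(500, c(strong = log(2), weak = log(1.3), null = 0),
                       seed = 27)
  bag <- bootstrap_bag(d$y, d$X, d$offset, d$blocks, n_resamples = 100,
                       seed = 3)
  f <- bag$selection_frequency
  expect_gt(f[["strong"]], f[["weak"]])
  expect_gt(f[["weak"]], f[["null"]])
})

test_that("degenerate resamples are redrawn and excessive degeneracy errors", {
  set.seed(28)
  n <- 60
  # one carrier only: ~37% of resamples lose the column entirely
  x <- c(1, rep(0, n - 1))
  X <- cbind("(Intercept)" = 1, rare = x)
  y <- rpois(n, 1)
  expect_error(
    bootstrap_bag(y, X, rep(0, n), list(rare = 2L), n_resamples = 100,
                  seed = 4),
    "degenerate")
  # with a common covariate no redraws are needed
  d <- make_count_data(200, c(a = 0.5), seed = 29)
  bag <- bootstrap_bag(d$y, d$X, d$offset, d$blocks, n_resamples = 30, seed = 5)
  expect_equal(bag$n_degenerate, 0)
})

test_that("predict_and_stratify maps the linear predictor to ratio strata", {
  dat <- data.frame(patient_id = 1:3, flag = c(FALSE, TRUE, FALSE))
  des <- prepare_design(dat, list(cov_binary("flag")))
  # hand-built final model: intercept log(2), flag coefficient 0
  final <- structure(list(coefficients = c("(Intercept)" = log(2), flag = 0),
                          selection_frequency = c(flag = 0),
                          design = des, blocks = des$blocks),
                     class = "final_model")
  pr <- predict_and_stratify(final, dat)
  expect_equal(pr$predicted_ratio, rep(2, 3))
  expect_true(all(pr$stratum == ">1.5"))
  final$coefficients[1] <- 0
  pr0 <- predict_and_stratify(final, dat)
  expect_equal(pr0$predicted_ratio, rep(1, 3))
  expect_true(all(pr0$stratum == "<=1"))
  # rows with missing covariates are skipped with a message
  dat$flag[2] <- NA
  expect_message(pr2 <- predict_and_stratify(final, dat), "skipped 1")
  expect_equal(pr2$patient_id, c(1, 3))
})

test_that("predicted >1 fraction shrinks relative to the observed fraction", {
  cohort <- generate_cohort(cohort_config(n_patients = 500, seed = 30,
                                          missingness = numeric(0)))
  idx <- difficulty_index(cohort)
  cohort$actual_count <- idx$table$actual_count
  cohort$log_expected <- log(idx$table$expected_count)
  covs <- list(cov_binary("fibromyalgia"), cov_binary("steroid_use"),
               cov_binary("pso_nail"), cov_binary("smoker"))
  des <- prepare_design(cohort, covs)
  bag <- bootstrap_bag(cohort$actual_count, des$X, cohort$log_expected,
                       des$blocks, n_resamples = 60, seed = 6)
  final <- average_coefficients(bag, des)
  pr <- predict_and_stratify(final, cohort)
  expect_lte(mean(pr$predicted_ratio > 1),
             mean(idx$table$ratio > 1) + 0.1)
})

test_that("nomogram normalizes the widest contribution to 100 points and inverts", {
  set.seed(31)
  dat <- data.frame(patient_id = 1:100,
                    a = rbinom(100, 1, 0.5) == 1,
                    z = runif(100, 0, 10))
  des <- prepare_design(dat, list(cov_binary("a"), cov_linear("z")))
  final <- structure(list(coefficients = c("(Intercept)" = -0.5,
                                           a = 0.4, z = 0.1),
                          selection_frequency = c(a = 1, z = 1),
                          design = des, blocks = des$blocks),
                     class = "final_model")
  nomo <- nomogram_table(final, dat)
  expect_equal(max(nomo$table$points_range), 100)
  # doubling a coefficient doubles its pre-scaling contribution range
  final2 <- final
  final2$coefficients["a"] <- 0.8
  nomo2 <- nomogram_table(final2, dat)
  w1 <- with(nomo$table, contrib_max - contrib_min)
  w2 <- with(nomo2$table, contrib_max - contrib_min)
  expect_equal(w2[1], 2 * w1[1])
  # round-trip: points -> predicted ratio matches the direct prediction
  pts <- total_points(nomo, dat)
  direct <- predict_and_stratify(final, dat)$predicted_ratio
  expect_equal(predict_from_points(nomo, pts), direct, tolerance = 1e-8)
  # single-covariate model: that covariate spans the full 100 points
  des1 <- prepare_design(dat, list(cov_binary("a")))
  final1 <- structure(list(coefficients = c("(Intercept)" = 0, a = 0.3),
                           selection_frequency = c(a = 1),
                           design = des1, blocks = des1$blocks),
                      class = "final_model")
  nomo1 <- nomogram_table(final1, dat)
  expect_equal(nomo1$table$points_range, 100)
  # all-zero model errors
  final0 <- final1
  final0$coefficients[] <- 0
  expect_error(nomogram_table(final0, dat), "zero")
})
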