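test_that("generate_cohort returns the configured number of records, deterministically", {
  cfg <- cohort_config(n_patients = 267, seed = 11)
  cohort <- generate_cohort(cfg)
  expect_equal(nrow(cohort), 267)
  expect_identical(cohort, generate_cohort(cfg))
  # different seed changes the draw
  cfg2 <- cohort_config(n_patients = 267, seed = 12)
  expect_false(identical(cohort, generate_cohort(cfg2)))
})

test_that("invalid configurations are rejected naming the offending field", {
  prev <- default_prevalences()
  prev$fibromyalgia <- 1.4
  expect_error(cohort_config(prevalences = prev), "fibromyalgia")
  prev$fibromyalgia <- 0.157
  prev$psa_subset <- c(axial = 0.5, peripheral = 0.4)
  expect_error(cohort_config(prevalences = prev), "psa_subset")
  expect_error(cohort_config(n_patients = 0), "n_patients")
  expect_error(
    cohort_config(missingness = c(dapsa = -0.1)), "dapsa")
  es <- default_effect_spec()
  es$base_rate <- -1
  expect_error(cohort_config(effect_spec = es), "base_rate")
})

test_that("binary marginals converge to configured prevalences (99% binomial bands)", {
  n <- 10000
  cohort <- generate_cohort(cohort_config(
    n_patients = n, seed = 21, missingness = numeric(0)))
  prev <- default_prevalences()
  for (nm in c("fibromyalgia", "steroid_use", "osteoarthritis", "smoker")) {
    band <- qbinom(c(0.005, 0.995), n, prev[[nm]]) / n
    emp <- mean(cohort[[nm]])
    expect_gte(emp, band[1])
    expect_lte(emp, band[2])
  }
  # subset probabilities after renormalization
  band <- qbinom(c(0.005, 0.995), n, prev$psa_subset[["peripheral"]]) / n
  expect_gte(mean(cohort$psa_subset == "peripheral"), band[1])
  expect_lte(mean(cohort$psa_subset == "peripheral"), band[2])
  # invariant: a psoriasis subtype implies psoriasis
  expect_true(all(!cohort$pso_nail | cohort$has_psoriasis))
  # follow-up truncated at 3 months
  expect_true(all(cohort$months_since_diagnosis >= 3))
})

test_that("zero missingness leaves the cohort complete", {
  cohort <- generate_cohort(cohort_config(
    n_patients = 300, seed = 3, missingness = numeric(0)))
  expect_false(anyNA(cohort))
})

test_that("simulate_drug_counts matches its Poisson generative model", {
  n <- 50000
  base <- data.frame(patient_id = seq_len(n),
                     months_since_diagnosis = rep(100, n),
                     fibromyalgia = rep(c(FALSE, TRUE), length.out = n))
  # zero rate: every patient has exactly the current therapy
  out0 <- simulate_drug_counts(
    base, list(base_rate = 0, coefficients = numeric(0)), seed = 1)
  expect_true(all(out0$n_prev_btsdmards == 0))
  # null effects, rate 0.02/month, T = 100: mean extra count = 2.0
  out <- simulate_drug_counts(
    base, list(base_rate = 0.02, coefficients = c(fibromyalgia = 0)), seed = 2)
  expect_equal(mean(out$n_prev_btsdmards), 2.0, tolerance = 0.01)
  # planted log(2) on fibromyalgia: rate ratio of extra counts ~ 2
  out2 <- simulate_drug_counts(
    base, list(base_rate = 0.02, coefficients = c(fibromyalgia = log(2))),
    seed = 3)
  ratio <- mean(out2$n_prev_btsdmards[out2$fibromyalgia]) /
    mean(out2$n_prev_btsdmards[!out2$fibromyalgia])
  expect_equal(ratio, 2.0, tolerance = 0.05)
  expect_error(
    simulate_drug_counts(base, list(base_rate = -1, coefficients = numeric(0))),
    "base_rate")
})

test_that("MCAR missingness hits the configured rates and protected fields never", {
  n <- 10000
  cfg <- cohort_config(n_patients = n, seed = 31, missingness = numeric(0))
  cohort <- generate_cohort(cfg)
  # rate 1 boundary: everything missing
  all_gone <- apply_missingness(cohort, c(dapsa = 1), seed = 1)
  expect_true(all(is.na(all_gone$dapsa)))
  # complete-case fraction ~ product of retentions: 5 fields at the rate
  # solving (1 - r)^5 = 177/267
  r <- 1 - (177 / 267)^(1 / 5)
  fields <- c("dapsa", "phga", "haq", "obesity", "smoker")
  holed <- apply_missingness(cohort, setNames(rep(r, 5), fields), seed = 2)
  frac <- mean(!Reduce(`|`, lapply(holed[fields], is.na)))
  band <- qbinom(c(0.005, 0.995), n, 177 / 267) / n
  expect_gte(frac, band[1])
  expect_lte(frac, band[2])
  # drug counts and follow-up are never eligible
  expect_error(apply_missingness(cohort, c(n_prev_btsdmards = 0.5)),
               "may not be set missing")
  expect_error(apply_missingness(cohort, c(dapsa = 1.2)), "dapsa")
})

test_that("a written cohort round-trips through the reader without loss", {
  cohort <- generate_cohort(cohort_config(n_patients = 80, seed = 9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_equal(back, cohort)
})

test_that("the planted coefficients are recovered by the Poisson-offset fit", {
  # generative consistency: response = extra count, offset = log months
  cfg <- cohort_config(n_patients = 8000, seed = 41, missingness = numeric(0))
  cohort <- generate_cohort(cfg)
  des <- prepare_design(cohort, list(cov_binary("fibromyalgia"),
                                     cov_binary("steroid_use"),
                                     cov_binary("pso_nail")))
  fit <- fit_poisson_offset(cohort$n_prev_btsdmards, des$X,
                            log(cohort$months_since_diagnosis),
                            blocks = des$blocks)
  truth <- c(log(cfg$effect_spec$base_rate), log(2), log(1.5), log(1.4))
  se <- sqrt(diag(fit$vcov))
  expect_true(all(abs(fit$coefficients - truth) < 3 * se))
})
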