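#!/usr/bin/env Rscript
# Stage 4 — univariate Poisson-offset screen of the relative treatment
# difficulty: one model per covariate, response = actual b/tsDMARD
# count, offset = log expected count, so exp(beta) is the ratio between
# the treatment difficulty of a category (or per-unit / inter-quartile
# increase) and its reference. Continuous covariates get restricted
# cubic splines with a Wald test of the nonlinear terms.

library(psad2t)

cohort <- read_cohort("results/cohort.csv")
idx <- difficulty_index(cohort)
cohort$actual_count <- idx$table$actual_count
cohort$log_expected <- log(idx$table$expected_count)

rows <- list()
nl <- list()
for (spec in default_model_covariates()) {
  sub <- cohort[!is.na(cohort[[spec$name]]), , drop = FALSE]
  des <- prepare_design(sub, list(spec))
  fit <- fit_poisson_offset(sub$actual_count, des$X, sub$log_expected,
                            blocks = des$blocks)
  rows[[spec$name]] <- relative_difficulty(fit, des)
  if (spec$type == "rcs") {
    w <- wald_test(fit, des$blocks[[spec$name]][-1])
    nl[[spec$name]] <- data.frame(covariate = spec$name,
                                  statistic = w$statistic, df = w$df,
                                  p_value = w$p_value)
  }
}
uni <- do.call(rbind, rows)
rownames(uni) <- NULL
write.csv(uni, "results/univariate_effects.csv", row.names = FALSE)
write.csv(do.call(rbind, nl), "results/nonlinearity_wald.csv",
          row.names = FALSE)

sig <- uni[uni$p_value < 0.05, ]
message("Unadjusted effects with p < 0.05:")
for (i in seq_len(nrow(sig))) {
  message(sprintf("  %-28s %.2f [%.2f, %.2f]", sig$term[i], sig$effect[i],
                  sig$ci_low[i], sig$ci_high[i]))
}
message("Wrote results/univariate_effects.csv and results/nonlinearity_wald.csv")
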