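#!/usr/bin/env Rscript
# Stage 5 — multivariable model with bootstrap-bagged backward-AIC
# selection: complete-case filtering, full Poisson-offset model, 1000
# resamples with replacement, backward-AIC selection in each, selection
# frequencies and zero-imputed averaged coefficients for the final model.

library(psad2t)

seed <- 1
cohort <- read_cohort("results/cohort.csv")
idx <- difficulty_index(cohort)
cohort$actual_count <- idx$table$actual_count
cohort$log_expected <- log(idx$table$expected_count)

covs <- default_model_covariates()
cov_names <- vapply(covs, `[[`, "", "name")
complete <- complete_cases(cohort, cov_names)
message("Complete cases: ", nrow(complete), " of ", nrow(cohort))

design <- prepare_design(complete, covs)
full <- fit_poisson_offset(complete$actual_count, design$X,
                           complete$log_expected, blocks = design$blocks)
adj <- relative_difficulty(full, design)
write.csv(adj, "results/adjusted_effects.csv", row.names = FALSE)

bw <- backward_aic(complete$actual_count, design$X, complete$log_expected,
                   design$blocks)
message("Single backward-AIC pass retained: ",
        paste(bw$selected, collapse = ", "))

bag <- bootstrap_bag(complete$actual_count, design$X, complete$log_expected,
                     design$blocks, n_resamples = 1000, seed = seed)
write.csv(data.frame(covariate = names(bag$selection_frequency),
                     frequency = unname(bag$selection_frequency)),
          "results/selection_frequency.csv", row.names = FALSE)
write.csv(bag$resample_log, "results/resample_log.csv", row.names = FALSE)

# coefficient-draw histograms as binned tables (one per design column)
bins <- do.call(rbind, lapply(colnames(bag$coefficient_draws), function(cl) {
  h <- hist(bag$coefficient_draws[, cl], breaks = 30, plot = FALSE)
  data.frame(term = cl, bin_low = h$breaks[-length(h$breaks)],
             bin_high = h$breaks[-1], count = h$counts)
}))
write.csv(bins, "results/coefficient_histograms.csv", row.names = FALSE)

final <- average_coefficients(bag, design)
write.csv(data.frame(term = names(final$coefficients),
                     coefficient = unname(final$coefficients)),
          "results/final_coefficients.csv", row.names = FALSE)

top <- sort(bag$selection_frequency, decreasing = TRUE)[1:5]
message("Most frequently selected over ", bag$n_resamples, " resamples:")
for (nm in names(top)) message(sprintf("  %-20s %.1f%%", nm, 100 * top[nm]))
message("Degenerate resamples redrawn: ", bag$n_degenerate)
message("Wrote adjusted effects, selection frequencies, coefficient ",
        "histograms and final averaged coefficients under results/")
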