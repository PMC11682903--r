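#!/usr/bin/env Rscript
# Stage 3 — the observed-vs-expected treatment-difficulty index.
#
# Per patient: actual count = previous b/tsDMARDs + 1 (current therapy
# included); rate of failure = actual / months of follow-up; the cohort
# 75th percentile of that rate calibrates the expected count
# ceiling(rate75 x months); the ratio actual/expected proxies treatment
# difficulty (> 1 potential D2T, > 1.5 highly potential).

library(psad2t)

cohort <- read_cohort("results/cohort.csv")
idx <- difficulty_index(cohort)
write.csv(idx$table, "results/difficulty_index.csv", row.names = FALSE)

s <- idx$summary
message(sprintf("Cut-off rate75 = %.4f b/tsDMARDs per month", s$rate75))
message("Observed ratio > 1: ", s$n_ratio_gt1, " of ", s$n,
        " (", pct(s$n_ratio_gt1, s$n), "%) | > 1.5: ", s$n_ratio_gt1.5)
message("Ratio median [Q1, Q3]: ",
        paste(round(quantile(idx$table$ratio, c(0.5, 0.25, 0.75)), 2)[c(1, 2, 3)],
              collapse = " / "))
message("Wrote results/difficulty_index.csv")
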