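# psad2t — treatment-difficulty indexing for psoriatic arthritis cohorts

Psoriatic arthritis (PsA) patients who cycle through many biological or
targeted-synthetic DMARDs (b/tsDMARDs) without durable disease control
are *difficult to treat* (D2T). Definitions adapted from rheumatoid
arthritis count failed therapies and current activity but ignore how
fast the failures accrued. `psad2t` is for rheumatology researchers and
biostatisticians who want to:

* apply the preliminary **three-criterion D2T rule** (≥ 2 failed
  b/tsDMARDs, at-least-moderate activity by DAPSA, problematic
  management) and screen associations with **Firth-penalized logistic
  regression**, which stays finite when only a handful of patients are
  D2T;
* compute a **continuous treatment-difficulty index**: with actual count
  `A = previous b/tsDMARDs + 1`, failure rate `ROF = A / months`, and
  cohort cut-off `r75` (75th percentile of ROF), the expected count is
  `E = ceiling(r75 × months)` and the index is the ratio `A / E` —
  above 1 flags potential D2T, above 1.5 highly potential;
* model the **relative treatment difficulty** with a Poisson GLM, log
  link, offset `log E` (so `exp(β)` is a difficulty ratio), restricted
  cubic splines for continuous covariates and Wald tests for
  non-linearity;
* run **bootstrap-bagged backward-AIC selection** (1000 resamples,
  covariate blocks move as units, selection frequencies, zero-imputed
  averaged coefficients), predict each patient's ratio
  `exp(x'β̄)` with >1 / >1.5 strata, and emit a points-based
  **nomogram table**.

Because registry data of this kind are rarely deposited, a synthetic
cohort generator emulates the published marginal structure of a
267-patient b/tsDMARD-treated PsA cohort and plants known effect sizes
(fibromyalgia ×2, steroid use ×1.5, nail psoriasis ×1.4 on the
drug-switch rate), so every stage is testable end to end. See the
methods vignette (`vignettes/treatment-difficulty-methods.Rmd`) for the
model details and design choices.

## Worked example

```r
library(psad2t)

cohort <- generate_cohort(cohort_config(n_patients = 267, seed = 1))
idx <- difficulty_index(cohort)
print(idx)
#> Treatment-difficulty index: n = 267 | rate75 = 0.01501 (cohort quantile)
#> ratio > 1: 15 (5.6%) | ratio > 1.5: 9

st <- classify_d2t(cohort)
#> classify_d2t: 24 patient(s) indeterminate (missing criterion fields), not counted as D2T
sum(st$is_d2t)
#> [1] 2

firth_univariate(cohort, st$is_d2t, "fibromyalgia")
#>      covariate   n events       beta       se odds_ratio     ci_low  ci_high
#> 1 fibromyalgia 267      2 0.02272825 1.573637   1.022989 0.04681533 22.35391
```

Reading: the cohort's 75th-percentile failure rate is 0.015 drugs per
month; 15 of 267 patients (5.6%) used more b/tsDMARDs than expected at
that rate over their own follow-up, 9 of them more than 1.5× as many.
Only 2 patients meet the strict three-criterion definition, so the
Firth odds ratio for fibromyalgia is estimated from 2 events — finite
(that is the point of the penalty) but with a wide interval.

The full analysis — simulation, classification, index, univariate
Poisson screen, 1000-resample bagging, prediction, nomogram — runs as
numbered scripts:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_classify_d2t.R
Rscript analysis/03_difficulty_index.R
Rscript analysis/04_univariate_models.R
Rscript analysis/05_multivariable_bagging.R
Rscript analysis/06_predict_report.R
```

Each writes its tables under `results/` and prints what it found; the
same stages are available programmatically via `run_pipeline()`.
On the default synthetic cohort (seed 1) the planted effects come back
as the story: the univariate screen flags nail psoriasis (1.35
[1.07, 1.70]), fibromyalgia (1.58 [1.26, 1.97]) and steroid use (1.36
[1.05, 1.76]); steroid use and fibromyalgia top the bagged selection
frequencies (91% and 84% of 1000 resamples).

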