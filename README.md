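# proteoclock

Plasma proteomic aging clocks by penalized regression — with a
synthetic-cohort simulator so the entire analysis is reproducible without
access-controlled data.

## What it does, and for whom

Large aptamer-based (SOMAscan-style) plasma proteomes show widespread
linear age trends in log10 intensity, and penalized regression on those
intensities yields accurate predictors of chronological age ("aging
clocks"). The residual — **delta age**, predicted minus chronological age —
is read as a biological-age deviation and compared between groups. The
real cohorts behind such analyses are access-controlled, which makes the
pipelines hard to test.

`proteoclock` is for biostatisticians and computational biologists who
want that pipeline as tested, reusable R code:

* **Simulation** (`cohort_spec()`, `generate_cohort()`): cohorts with a
  known fraction of age-informative analytes,
  `log10 x_ip = mu_p + beta_p (age_i − mean age) + gamma_p sex_i + eps`,
  per-year coefficients drawn log-uniformly over the published magnitude
  range (3.24e-4 to 1.64e-2), a ~76/24 increasing/decreasing split, plus
  `inject_aging_shift()` (group-level proteome aging) and
  `apply_platform_mask()` (smaller assay panels).
* **Age-association screening** (`fit_age_regression()`, `adjust_fdr()`,
  `summarize_directions()`): per-analyte OLS of log10 intensity on age,
  Benjamini–Hochberg q-values, direction counts at q < 0.05.
* **Clocks** (`train_clock()`): ridge (alpha = 0) or LASSO (alpha = 1) on
  z-scaled log10 intensities, 2/3–1/3 train/test split, penalty chosen by
  tenfold cross-validation over a 100-value lambda path (`lambda.min`),
  evaluated by Pearson r and *median* absolute error in years. The solver
  (cyclic coordinate descent on
  `(1/2n)||y − b0 − Zb||² + λ[(1−α)/2 ||b||² + α||b||₁]`) is implemented
  in the package (Rcpp) and verified against closed-form ridge, KKT
  conditions, grid search, and glmnet in the test suite.
* **Pathway screening** (`screen_pathways()`, `rank_clocks()`): a ridge
  and LASSO clock per GMT pathway with a shared split; sets with < 2
  mapped analytes excluded.
* **Transfer** (`predict(clock, cohort, features = ...)`,
  `estimate_correction()`, `apply_correction()`): apply a clock to a
  cohort measuring only a subset of its analytes without refitting, and
  correct the resulting slope attenuation with the correction coefficient
  `kappa = 1/b` estimated on a learning cohort.
* **Group comparison** (`compute_delta_age()`, `compare_groups()`):
  delta-age summaries (mean ± SD) and Wilcoxon rank-sum / signed-rank
  tests.
* **Enrichment** (`overrepresentation_test()`): hypergeometric
  upper-tail ORA with BH FDR over a pathway collection.
* **I/O**: cohorts as CSV triplets, pathway collections as GMT, fitted
  clocks as JSON (`write_clock_model()` / `read_clock_model()`).

## Worked example

```r
library(proteoclock)

spec <- cohort_spec(n_subjects = 500, n_analytes = 200, seed = 42)
g <- generate_cohort(spec)
g$cohort
#> <proteomic_cohort> 500 subjects x 200 analytes
#>   age: 18.0-75.8 years (median 45.9)

## which analytes change with age, and in which direction?
assoc <- classify_directions(fit_age_regression(g$cohort))
summarize_directions(assoc)
#> 29 of 200 analytes significant at q < 0.05
#>   increasing: 22 (75.86%)   decreasing: 7 (24.14%)

## train a ridge aging clock
clock <- train_clock(g$cohort, alpha = 0, seed = 42)
clock
#> <aging_clock> ridge over 200 analytes (200 nonzero), lambda = 1.676
#>   train: r = 0.993, MAE = 2.17 y (n = 333)
#>   test:  r = 0.987, MAE = 2.69 y (n = 167)

## a new cohort in which half the subjects are "biologically" 8 years older
g2 <- generate_cohort(cohort_spec(n_subjects = 60, n_analytes = 200,
                                  seed = 43), truth = g$truth)
older <- subject_ids(g2$cohort)[1:30]
shifted <- inject_aging_shift(g2$cohort, g$truth, older, 8)
pred <- predict(clock, shifted)
grp <- ifelse(subject_ids(shifted) %in% older, "sedentary", "trained")
delta <- compute_delta_age(pred, shifted$subjects$age, grp)
delta
#> <delta_age>
#>   sedentary (n = 30): chronological 44.22 ± 16.82, predicted 52.04 ± 14.90, delta 7.82 ± 2.84 years
#>   trained (n = 30): chronological 42.95 ± 17.17, predicted 43.55 ± 14.27, delta 0.60 ± 3.76 years
compare_groups(delta)
#> Wilcoxon rank-sum test (normal approximation): sedentary vs trained (n = 30, 30)
#>   statistic = 848, p = 4.18e-09
#>   difference of mean predicted ages = 8.48 years
```

The clock recovers chronological age from the simulated proteome (held-out
r = 0.987, median error 2.7 years), the direction split among significant
analytes matches the generating 76/24 ratio, and the injected 8-year
proteomic shift is recovered as a delta-age gap of ~7.8 years with a
highly significant group difference.

See `vignettes/proteomic-aging-clocks.Rmd` for the model, the fitting
protocol, and the reasoning behind the numerical choices.

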