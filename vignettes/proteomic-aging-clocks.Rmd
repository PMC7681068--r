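---
title: "Proteomic aging clocks: model, protocol, and design notes"
author: "proteoclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteomic aging clocks: model, protocol, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteoclock)
```

## The problem

Plasma protein levels change with age: in large SOMAscan cohorts a
substantial fraction of aptamer-measured analytes show significant linear
trends in log10 relative fluorescence units (RFU), with roughly three
quarters of the significant analytes increasing. Penalized linear
regression on the full panel yields "aging clocks" — predictors of
chronological age whose residual (the *delta age*, predicted minus
chronological) is read as a biological-age deviation; groups under a
physiological stressor (e.g. sedentary versus aerobically trained
subjects) can then be compared on delta age.

Real cohorts of this kind are access-controlled. `proteoclock` therefore
ships a synthetic-cohort generator with known ground truth, so that every
stage — association screening, clock fitting, pathway screening, transfer,
group comparison — is testable end-to-end, with parameter-recovery checks
instead of irreproducible headline numbers.

## The generative model

For subject $i$ and analyte $p$:

$$\log_{10} x_{ip} = \mu_p + \beta_p\,(a_i - \bar a) + \gamma_p s_i +
\varepsilon_{ip}, \qquad \varepsilon_{ip} \sim N(0, \sigma^2)$$

with age $a_i$, sex code $s_i \in \{0,1\}$, and intensities reported as
$10^{\log_{10}x}$ (raw RFU scale, strictly positive). The defaults in
`cohort_spec()` are the package's study conditions:

| parameter | default | why |
|---|---|---|
| `n_subjects`, `n_analytes` | 3000, 3000 | a large-donor-cohort scale (thousands of subjects and aptamers) |
| `age_range` | 18–76 years | typical blood-donor recruitment window |
| `frac_informative` | 0.15 | 450 truly age-coupled analytes out of 3000 |
| `frac_increasing` | 0.7584 | the ~76/24 increasing/decreasing split observed among significant plasma proteins |
| `beta_range` | $[3.24\times10^{-4}, 1.64\times10^{-2}]$ per year | the span of published per-year log10 age coefficients for common aging plasma proteins; magnitudes drawn log-uniformly |
| baseline $\mu_p$ | $N(3, 0.5)$ | RFUs in the hundreds-to-thousands |
| `noise_sd` ($\sigma$) | 0.05 | calibration choice: no published per-analyte residual scale exists, so $\sigma$ is set such that the full-panel clock reaches test correlation $\ge 0.9$ at the default cohort size |
| `sex_effect_sd` ($\gamma_p$ scale) | 0.02 | modest sex dimorphism, smaller than the age signal across the range; set 0 to disable |
| age sampling | uniform | maximizes identifiability of the slope; `age_dist = "triangular"` skews towards a median of 45 years to mimic a donor age pyramid |

Every stochastic operation takes an explicit seed and is bit-reproducible.
`generate_cohort(spec, truth = old_truth)` redraws *subjects* while reusing
the per-analyte parameters, which is how independent validation and
transfer cohorts from the same generative process are made.
`inject_aging_shift()` moves selected subjects along their own true
trajectories by $\beta_p \cdot \Delta$ years — the synthetic analog of a
group that is biologically older than its calendar age —
and `apply_platform_mask()` restricts the panel, emulating older assay
versions with 1305- or 1129-protein menus.

What the generator does *not* emulate: hybridization/batch structure,
plate effects, heteroscedastic or heavy-tailed noise, nonlinear
trajectories, analyte–analyte correlation beyond the shared age and sex
factors. Passing tests therefore certify the *protocol* (estimators,
selection, correction, inference), not performance on real plasma data.
With the default calibration the synthetic data are in fact considerably
cleaner than real proteomes — the full-panel clock reaches $r > 0.99$ —
so absolute accuracies should never be quoted as expectations for real
cohorts.

## Clock protocol

`train_clock()` follows the standard recipe end to end:

1. **Inputs** are z-scaled log10 RFUs. Standardization parameters are
   estimated on the *training subjects only* by default (no leakage into
   the held-out evaluation); `scaling = "global"` reproduces whole-cohort
   scaling for fidelity with published pipelines that scaled first and
   split second.
2. **Split**: a uniform random 2/3–1/3 train/test partition
   (`round(n * fraction)` training subjects), deterministic given the
   seed, reused across all clocks of a screen for comparability.
3. **Fit**: elastic-net penalized least squares
   $$\tfrac{1}{2n}\lVert y - \beta_0 - Z\beta\rVert_2^2 +
   \lambda\left[\tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2 +
   \alpha\lVert\beta\rVert_1\right]$$
   with $\alpha = 0$ (ridge) or $1$ (LASSO), solved by cyclic coordinate
   descent with warm starts along a 100-value log-spaced $\lambda$ path,
   converged when the largest coefficient change in a pass falls below
   $10^{-7}$.
4. **Penalty selection**: tenfold cross-validation, folds assigned by a
   seeded permutation; the `lambda.min` rule (path value minimizing mean
   CV squared error), with ties resolved towards the larger, more
   regularized $\lambda$ (the path is scanned in descending order, so the
   first minimum wins).
5. **Evaluation**: Pearson correlation between predicted and
   chronological age, and the *median* absolute error in years, reported
   for train and test separately.

### Numerical choices

* $\lambda_{\max}$ is $\max_j |z_j^\top y| / (n \cdot \max(\alpha,
  0.001))$ — the usual convention with the mixing parameter floored so the
  pure-ridge path is finite.
* Path floor: for $\alpha > 0$ the smallest path value is
  $\lambda_{\max}\cdot 10^{-4}$ when $n > p$ and $10^{-2}$ otherwise (the
  common default). For pure ridge the $10^{-2}$ floor is too shallow in
  *every* regime: because the floored-mixing $\lambda_{\max}$ sits three
  orders of magnitude above the lasso scale, a $10^{-2}$ ratio leaves the
  entire path heavily over-penalized — the CV curve is still decreasing at
  the boundary and predictions are visibly compressed toward the mean
  (high $r$, poor MAE). Ridge therefore uses a $10^{-4}$ floor throughout.
* Pure-ridge solves are seeded at the closed-form minimizer, obtained from
  one symmetric eigendecomposition of the smaller Gram matrix (using the
  push-through identity when $n \le p$); coordinate-descent passes then
  certify the fixed point at the stated tolerance. This keeps the deep
  ridge path affordable on a single core; $\alpha > 0$ uses warm-started
  coordinate descent with covariance updates over the active set.
* Analytes with zero training variance cannot be z-scaled and are dropped
  with a warning. A clock whose active set is empty predicts a constant;
  its correlation is reported as `NA`.
* On very clean synthetic data the CV curve can remain monotone down to
  the path floor, in which case `lambda.min` is the smallest path value;
  this is a property of the calibration, not a defect of the rule.

## Pathway screening

`screen_pathways()` builds one ridge and one LASSO clock per pathway,
restricted to the pathway's analytes, reusing a single shared split.
Pathways mapping to fewer than `min_analytes` (default 2) panel analytes
are excluded and counted. Members may be analyte ids, gene symbols, or
protein ids; a symbol covered by several analytes resolves to the first
annotation listed (deterministic), and unmapped members are dropped with a
count. Ranking is by held-out $r$ (descending) or MAE (ascending), ties
broken by fewer analytes then pathway id, so that minimalistic clocks are
preferred at equal performance.

## Transfer to restricted panels

Applying a clock to a cohort that measures only a subset of its analytes
uses the no-refit rule: missing features' terms are simply omitted —
equivalent to imputing the training mean on the z scale, and requiring no
statistics from the target cohort. Restricted predictions are attenuated
towards the training-mean age; on a learning cohort with the full panel
the attenuation is measured by regressing restricted predictions on
chronological age, $\hat y_r = a + b\,\mathrm{age}$, and the correction
coefficient $\kappa = 1/b$ is reported.

The applied transform is the full affine inversion
$\hat y_{\mathrm{corr}} = (\hat y_r - a)/b$: it is the unique line-based
transform after which corrected predictions regress on age with slope 1
and intercept 0 on the learning set. A bare-multiplier variant
($\kappa \hat y_r$) is available via `apply_correction(..., method =
"multiplier")` for fidelity with reports that quote only the single
coefficient; whether the original procedure subtracted the intercept is
not decidable from published text, and the affine form is the default
because it is the one that exactly corrects the slope offset it names.

## Delta age and group comparison

`compute_delta_age()` reports per-subject $\Delta_i = \hat y_i - a_i$ and
group mean ± SD summaries. `compare_groups()` defaults to the two-sample
Wilcoxon rank-sum test — the statistically appropriate choice for
independent groups — while the paired signed-rank test is available for
fidelity with analyses that name it (it requires equal group sizes and
pairs subjects by order; the output states which test ran). Exact
p-values are used for combined $n \le 25$ without ties; otherwise the
normal approximation with continuity correction and mid-rank ties.

## Overrepresentation analysis

`overrepresentation_test()` is a plain one-sided hypergeometric upper-tail
test per pathway with Benjamini–Hochberg FDR across pathways. The
background defaults to the measured panel (the analysis universe actually
available), not all protein-coding genes; a wider background can be passed
explicitly. No redundancy reduction between overlapping pathways is
attempted.

For the per-analyte screen, q-values default to Benjamini–Hochberg — the
reproducible, conservative choice — with a Storey-type
$\hat\pi_0 = \min(1, \overline{\mathbb{1}[p > 0.5]}/0.5)$ rescaling
behind `adjust_fdr(method = "storey")` for users who want the less
conservative estimate.

## Test problem sizes

The test suite exercises the full default scale once (3000 × 3000, the
parameter-recovery check) and otherwise uses proportionally scaled-down
cohorts chosen so each property is measured with adequate Monte-Carlo
precision: FDR control over 50 replicate cohorts of 1000 × 300;
accuracy-vs-input monotonicity over 10 replicates of 400 × 700 with
nested informative subsets of 10/50/200; transfer-slope recovery over 20
random 30% panels against independent 250-subject target cohorts;
delta-age power over 50 and size over 200 replicate 48-subject cohorts
scored by a clock trained on 500 × 300. These sizes are the package's
own choices for stable, fast checks; the properties they probe are
scale-free.

## Known limitations

* The noise model is homoscedastic Gaussian on the log10 scale with a
  single global $\sigma$; real SOMAscan residual structure is richer.
* Only linear age trends are generated and fitted; nonlinear trajectory
  modeling is out of scope.
* The signed-rank option pairs subjects by order, which is only meaningful
  if the caller's ordering encodes a real pairing.
* LASSO model selection on near-noiseless data is parsimonious by design:
  it recovers a *sufficient* predictive subset (high precision), not the
  complete set of truly informative analytes.
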