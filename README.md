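# mirecover

Simulation toolkit for quantifying how much information **multiple
imputation** recovers relative to **complete-case analysis** when data are
missing at random (MAR) in one covariate or in the exposure of interest.

Epidemiologists routinely face incomplete cohort data and reach for
multiple imputation without asking two prior questions: *is there anything
to recover for my coefficient of interest?* and *will my imputation model's
assumptions (in particular normality) hold well enough as the missing
fraction grows?* `mirecover` provides a full, reproducible laboratory for
both questions, built around a cohort-style synthetic population of
adolescent girls with a binary dieting exposure, demographic and
health-perception covariates, and a highly right-skewed emotional-distress
score bounded on (0, 3].

## What it implements

* **Synthetic population** (`population_config()`, `generate_population()`,
  `fit_truth()`): a Gaussian-copula generator calibrated so the pairwise
  Spearman correlations, the analysis-scale coefficients
  (β₁ = −0.101 for diet, β₂ ≈ 0.554 for log baseline distress,
  β₆ = 0.042 for health), the raw-scale skewness of distress (> 3) and the
  borderline significance of the diet effect at n = 1000 all hold
  simultaneously. "True" parameters are always re-estimated from the
  generated population.
* **MAR mechanisms** (`missingness_spec()`, `calibrate_intercept()`,
  `apply_missingness()`): logistic models with log-odds log(2.7) / log(1.2)
  / log(1.3) on fully observed drivers and a structurally zero coefficient
  on the target's own value; intercepts calibrated by bisection so the mean
  missingness probability hits 10/25/50/75/90% to within 1e−8.
* **MVNI engine** (`mvni_impute()`, `da_impute()`): data-augmentation MCMC
  under a uniform prior — sweep-operator conditioning per missingness
  pattern in the I-step, inverse-Wishart (n − 1 df) and normal draws in the
  P-step — with an RcppArmadillo core, EM initialisation, and
  reproducibility from R's RNG seed.
* **Transforms** (`zero_skew_shift()`, `fit_transform()`,
  `truncate_imputed()`): simple log and zero-skewness shifted log
  *u* = ln(±x − k), fitted on observed values, with truncation of
  back-transformed imputed values at the smallest observed value (zero-skew
  only) and the scale maximum.
* **Estimation and pooling** (`fit_linear()`, `fit_logistic()`,
  `rubin_pool()`): the linear and logistic analysis models (with separation
  detection for the dichotomised outcome) and Rubin's rules
  (T = W + (1 + 1/m)B, classic degrees of freedom).
* **Metrics and orchestration** (`performance_summary()`,
  `precision_gain()`, `coverage_band()`, `run_scenario()`,
  `make_report()`): bias, average SE, standardised bias, MSE, coverage,
  Monte Carlo errors, the precision gain (SE_CC/SE_MI)² − 1, and fully
  seeded scenario runs with per-replicate reproducibility.

See `vignettes/information-recovery.Rmd` for the model, the calibration and
the design decisions.

## Worked example

Generate a population, estimate the truth, and run a small version of the
continuous-outcome scenario with 50% of baseline distress missing:

```r
library(mirecover)
pcfg  <- population_config(population_size = 2e5, seed = 1)
pop   <- generate_population(pcfg)
truth <- fit_truth(pop)
cfg <- scenario_config(1, complete_fractions = 0.5, S = 50, n = 1000,
                       mvni = mvni_config(m = 10, burn_in = 100, between = 50),
                       master_seed = 42, population = pcfg)
res <- run_scenario(cfg, pop = pop, truth = truth)
print(res)
```

```
Scenario 1: 50 replicates x n = 1000, fractions 50%
 fraction     method coefficient   bias avg_se std_bias coverage excluded
      0.5        CCA        diet -0.061  0.096   -0.636    86.0%        0
      0.5        CCA     ldistW1  0.026  0.045    0.570    90.0%        0
      0.5        CCA      health -0.002  0.045   -0.047    98.0%        0
      0.5   MVNI-log        diet -0.011  0.071   -0.148    92.0%        0
      0.5   MVNI-log     ldistW1  0.026  0.041    0.647    90.0%        0
      0.5   MVNI-log      health  0.002  0.035    0.069    92.0%        0
      0.5 MVNI-skew0        diet -0.013  0.070   -0.186    94.0%        0
      0.5 MVNI-skew0     ldistW1  0.016  0.038    0.423    94.0%        0
      0.5 MVNI-skew0      health -0.001  0.035   -0.036    96.0%        0
```

Reading the rows: dropping the half-incomplete records biases the diet
coefficient (−0.061 against a truth of −0.095) and inflates its SE to
0.096, while either imputation method removes most of the bias and returns
the SE to ~0.070. The precision comparison for the diet coefficient:

```r
se_cc <- subset(res$summaries, method == "CCA"        & coefficient == "diet")$avg_se
se_mi <- subset(res$summaries, method == "MVNI-skew0" & coefficient == "diet")$avg_se
precision_gain(se_cc, se_mi)
#> SE ratio CC/MI = 1.366 (variance-scale gain 0.867)
```

i.e. at this missingness level the complete-case SE is ~37% larger, an
87% gain in effective information from imputing. (At 50 replicates the
coverage column carries a Monte Carlo band of about ±6 percentage points —
`coverage_band(50)`; the full design uses S = 1000, where the band is
93.6–96.4%.)

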