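# crrme — meta-regression on baseline risk with measurement error correction

Meta-analyses of two-arm studies often regress the treatment-arm risk on
the *baseline risk* — the event risk under the control condition — to
explain between-study heterogeneity, optionally together with additional
study-level covariates such as mean age or the percentage of males.  All
of these regressors are observed only as aggregated summaries (event
counts, trait counts, means ± SD), so they carry sampling error, and the
uncorrected regression suffers the classical errors-in-variables
attenuation: the slope on baseline risk is biased toward zero and the
residual heterogeneity is inflated.

`crrme` fits the control-risk regression

η<sub>i</sub> = β₀ + β₁ ξ<sub>i</sub> + β₂ ζ<sub>i</sub> + ε<sub>i</sub>,  ε<sub>i</sub> ~ N(0, τ²),

on the log-odds scale with a structural measurement-error correction:
latent Gaussian baseline risk ξ<sub>i</sub> ~ N(μ<sub>ξ</sub>, σ²<sub>ξ</sub>)
and latent covariate ζ<sub>i</sub> ~ N(μ<sub>ζ</sub>, σ²<sub>ζ</sub>).
It provides

* the closed-form marginal likelihood under the approximate
  (multivariate-normal) error model, and exact binomial / multinomial /
  bivariate-normal-subgroup error models evaluated by Gauss–Hermite
  quadrature;
* pseudo-likelihood variants under working independence, with sandwich
  standard errors;
* first-order Taylor within-study covariances from subgroup summary
  tables, validated by a Monte-Carlo resampling oracle;
* the uncorrected ("naive") analyses for comparison;
* a simulation engine reproducing the estimators' bias, standard error
  and Wald-coverage behaviour under three data-generating scenarios;
* a packaged 10-study meta-analysis of COVID-19 mortality in patients
  with and without schizophrenia.

## Worked example

```r
library(crrme)

records <- covid_schizophrenia()              # 10 studies, counts per arm
d <- assemble_observed(records, apply = "never")

crr_fit(d, method = "likelihood")             # corrected fit
#> likelihood fit (approximate error model), 10 studies
#>   beta0         0.146 (0.329)
#>   beta1         0.761 (0.091) *
#>   mu_xi         -2.568 (0.500) *
#>   tau2          0.028 (0.049)
#>   sigma_xi2     2.459 (1.112) *

crr_fit(d, method = "naive")                  # uncorrected baseline
#> naive analysis fit (approximate error model), 10 studies
#>   beta0         -0.080 (0.140)
#>   beta1         0.709 (0.056) *
#>   tau2          0.527 (0.211) *
```

The corrected slope on baseline risk (0.761) exceeds the uncorrected one
(0.709) — attenuation working as theory predicts — and the corrected
residual heterogeneity collapses from 0.527 to 0.028: most of the
"heterogeneity" the naive model reports is measurement error.  Adding an
error-prone covariate (here the standardized mean age, entering through a
pseudo-likelihood because within-study covariances are unavailable):

```r
da <- assemble_observed(covid_schizophrenia("age"), apply = "never",
                        standardize = TRUE)
crr_fit(da, method = "pseudo", sandwich = TRUE)
#> pseudo-likelihood fit (approximate error model), 10 studies
#>   beta0         0.883 (0.485)
#>   beta1         1.070 (0.185) *
#>   beta2         -0.558 (0.269) *
#>   ...
```

Mortality decreases with younger study populations (β₂ < 0), and
including age absorbs essentially all the residual heterogeneity.

Simulation study of estimator bias and coverage:

```r
cfg <- sim_config(scenario = 1, n_studies = 20, tau2 = 0.1, n_reps = 1000)
run_sim_study(cfg)   # bias / se / sd / convergence / coverage tables
```

Thin command-line wrappers live in `inst/scripts/` (`fit.R`,
`simulate.R`).

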