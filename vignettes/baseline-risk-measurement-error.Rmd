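---
title: "Correcting for measurement error in meta-regression on baseline risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting for measurement error in meta-regression on baseline risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crrme)
```

## The problem

A recurring question in meta-analysis of two-arm trials is whether the
treatment-arm risk depends on the *baseline risk* — the risk that subjects
would face under the control condition.  Writing \(\eta_i\) and \(\xi_i\)
for the true log odds of the event in the treatment and control arms of
study \(i\), the control-risk regression is

\[
\eta_i = \beta_0 + \beta_1 \xi_i + \beta_2 \zeta_i + \varepsilon_i,
\qquad \varepsilon_i \sim N(0, \tau^2),
\]

where \(\zeta_i\) is an optional additional study-level covariate (mean
age, the log odds of a binary trait, ...) and \(\tau^2\) is the residual
between-study heterogeneity.  Neither \(\eta_i\), \(\xi_i\) nor (usually)
\(\zeta_i\) is observed.  What *is* observed are aggregated summaries —
event counts, trait counts, means with SDs — and those summaries carry
sampling ("measurement") error.  Regressing the observed treatment log
odds on the observed control log odds without correction attenuates
\(\hat\beta_1\) toward zero and inflates \(\hat\tau^2\); this is the
classical errors-in-variables phenomenon.

`crrme` implements a structural correction: the latent quantities get a
Gaussian distribution, \(\xi_i \sim N(\mu_\xi, \sigma^2_\xi)\) and
\(\zeta_i \sim N(\mu_\zeta, \sigma^2_\zeta)\), and inference is by maximum
(pseudo-)likelihood over the full parameter vector
\(\theta = (\beta_0, \beta_1, \beta_2, \mu_\xi, \mu_\zeta, \tau^2,
\sigma^2_\xi, \sigma^2_\zeta, \sigma_{\xi\zeta})\).

## Error models

**Approximate (default).**  The observed log odds
\(\hat\eta_i = \log Y_i/(n_{iT} - Y_i)\) is treated as normal around
\(\eta_i\) with known variance \(s^2_{\eta i} = 1/Y_i + 1/(n_{iT}-Y_i)\),
and likewise for \(\hat\xi_i\) and the observed covariate \(\hat\zeta_i\).
The observed triple is then marginally trivariate normal with mean
\((\beta_0 + \beta_1\mu_\xi + \beta_2\mu_\zeta, \mu_\xi, \mu_\zeta)\) and
covariance \(\Sigma + \Gamma_i\), where \(\Sigma\) is implied by the
regression and \(\Gamma_i\) collects the within-study error variances and
covariances.  The likelihood is closed-form (`neg_loglik_approx()`).
We implement \(\Sigma\) in its internally consistent general form,
including the \(\sigma_{\xi\zeta}\) terms in the first row; it reduces to
the familiar display when \(\sigma_{\xi\zeta} = 0\).

**Exact.**  The counts themselves are modelled — binomial for the event
counts, multinomial for event-by-trait subgroup tables, bivariate normal
for subgroup means — and the latent integrals are evaluated by
tensor-product Gauss–Hermite quadrature after standardising each latent
at its conditional mean (`neg_loglik_exact_binomial()` and friends).
The default is 10 nodes per dimension; `n_nodes` is exposed because the
binomial factors sharpen as counts grow, and a non-adaptive rule then
needs more nodes (our accuracy tests use up to 160 nodes against an
adaptive-quadrature oracle; with group sizes beyond a few hundred the
approximate model is accurate anyway and is the better tool).  In the full
multinomial observation model the cell probabilities are underdetermined
by their margins; we complete them by independence of event status and
trait given the latents, the only completion that satisfies the margins
for every latent value.  Correlations between event and non-event
subgroup means (\(\rho_{iT}, \rho_{iC}\)) are treated as known inputs,
zero by default, because no functional form for them is available.

## Within-study covariances and the pseudo-likelihood

\(\hat\eta_i\) and \(\hat\zeta_i\) are computed from the same subjects, so
they co-vary within a study.  When event-by-trait subgroup tables are
available, first-order Taylor expansions give closed-form approximations
(`taylor_cov_binary()`, `taylor_cov_mean()`); a resampling oracle
(`monte_carlo_cov_oracle()`) validates them.  Assembled per-study
covariance matrices are checked for positive semidefiniteness — the
Taylor values are approximations — and, if needed, both covariances are
shrunk by the smallest common factor restoring validity, with a warning.
The covariance between \(\hat\eta_i\) and \(\hat\xi_i\) is fixed at zero:
the two arms involve distinct subjects.

When subgroup information is unavailable, the *pseudo-likelihood* simply
sets the within-study covariances to zero (working independence).  The
point estimates lose little; the price is paid in the variance, which is
why `sandwich_se()` provides the robust \(A^{-1} B A^{-1}\) covariance
from the per-study scores.  At a stationary point the delta-method
mapping between our transformed optimisation scale and the natural scale
is exact, so the reported standard errors do not depend on the
parametrization.

## The uncorrected ("naive") analysis

Two uncorrected baselines are provided.  The default, `fit_naive()`, is
the closed-form two-stage estimator: weighted least squares of
\(\hat\eta_i\) on the observed regressors (weights \(1/s^2_{\eta i}\) for
data analysis; the simulation harness uses the unweighted variant), with
dispersion-scaled coefficient standard errors, and the residual
heterogeneity estimated as \(\hat\tau^2 = \mathrm{RSS}/n\) with standard
error \(\hat\tau^2\sqrt{2(n-p)}/n\).  The alternative
(`naive_ml = TRUE`) maximises the uncorrected normal likelihood with
variance \(s^2_{\eta i} + \tau^2\); whether \(s^2_{\eta i}\) enters at all
is controlled by `include_s_eta2`.  Both are deliberately wrong — they
exist to quantify what the correction buys.

## Fitting: parametrization, starts, convergence

`crr_fit()` maximises the chosen objective with Nelder–Mead from an
ordinary-least-squares start (`ols_start()`).  Variances are optimised on
the log scale and \(\sigma_{\xi\zeta}\) through a bounded correlation
transform, which avoids the boundary and non-PSD failures that plain
raw-scale simplex search is known to produce; `parametrization =
"natural"` mirrors the raw-scale behaviour for comparison.  Two
Nelder–Mead passes with relative tolerance \(10^{-10}\) and a generous
iteration cap reproduce the application estimates to three decimals.
A replicate counts as convergent when the optimizer reports success, the
observed information is positive definite and invertible, and no variance
component sits at the numerical floor (\(10^{-10}\)); with the log-scale
parametrization the floor/flat-information cases are precisely the
boundary fits, so this rule is stricter than counting optimizer success
alone — about a tenth of small-sample replicates with small \(\tau^2\)
end there.  Summaries aggregate over convergent replicates.

\(\sigma_{\xi\zeta}\) is fixed at zero by default
(`estimate_sigma_xizeta = TRUE` frees it).  The application fits that the
package reproduces are obtained under \(\sigma_{\xi\zeta} = 0\), the
simulation scenarios generate \(\xi \perp \zeta\), and freeing the
parameter on ten studies visibly destabilises the remaining estimates.

## Covariate handling details

* Log-odds covariates come as a trait count over a denominator.  When a
  study reports only a percentage, the count is recovered by rounding
  `pct * n / 100` over the total study size — the transformation needs an
  integer count.
* Mean-value covariates reported as mean ± SD give
  \(\hat\zeta_i = \bar Z_i\), \(s^2_{\zeta i} = SD_i^2 / n_i\).
* `standardize = TRUE` centres and scales \(\hat\zeta_i\) by the
  unweighted sample mean and SD of the study values and divides
  \(s^2_{\zeta i}\) by the sample variance — exact affine error
  propagation.  (Whether weighted moments should be used instead is not
  identifiable from the application we reproduce; the unweighted choice
  reproduces it best and is the default.)
* A continuity correction of 0.5 per cell is applied only to studies with
  an empty cell by default (`apply = "only_zero"`); `"always"` and
  `"never"` are available.

## The simulation engine

`sim_config()` + `run_sim_study()` reproduce the designed operating
conditions of the estimators: group sizes integer-uniform on
\([15, 200]\), \((\beta_0,\beta_1,\beta_2) = (0, 1, 0.8)\),
\(\tau^2 \in \{0.1, 0.5, 1\}\), \(n \in \{10, 20, ...\}\) studies,
baseline risk standard normal or skew-normal \(SN(0,1,-5)\) (drawn via the
half-normal representation, `draw_skew_normal()`).  Scenario 1 attaches an
error-free covariate; scenario 2 generates event-by-trait multinomial
subgroup tables, with the free cell probability drawn uniformly on its
feasible range (the naive uniform upper bound alone can leave a negative
fourth cell, so the draw is restricted to the valid simplex); scenario 3
generates bivariate-normal subgroup means with correlations uniform on
\((-1,1)\) and unit within-study SD.  The generator applies the
Haldane–Anscombe 0.5 correction to every cell when forming observed log
odds — a convention chosen once for the whole engine so that boundary
counts at the smallest group sizes never interrupt a replicate — and
computes Taylor covariances on the same corrected margins.  One master
seed drives everything; per-replicate seeds are derived from it so any
replicate can be regenerated in isolation.

What the generator does **not** emulate: publication selection,
covariates measured in one arm only, non-constant within-study SDs,
correlated latent \(\xi\) and \(\zeta\), or risk measures other than log
odds.  Green simulation tests therefore certify the estimator under the
stated sampling models, not under arbitrary real-data violations of them.

Summaries report bias, the mean estimated standard error, the empirical
standard deviation, convergence counts, and empirical coverage of 95%
Wald intervals (Hessian and, optionally, sandwich).  At the default desk
scale (1000 replicates, \(n = 20\)) the scenario-1 run takes about a
minute and the scenario-2 pseudo-likelihood run a few minutes on one
core; the coverage checks in the test suite use 500 replicates at
\(n = 50\).

A note on the uncorrected slope in scenario 3: with the latent baseline
risk independent of the latent covariate and mean-zero within-study error
covariances, classical errors-in-variables theory says the attenuation of
\(\hat\beta_1\) depends only on the average error variance of
\(\hat\xi_i\) — which is identical across the three scenarios.  Our
simulations bear this out: the unweighted naive bias of \(\beta_1\) at
\(n = 20\), \(\tau^2 = 0.1\) sits near \(-0.06\) to \(-0.07\) in all
three scenarios.  Reference values that place scenario 3 noticeably lower
than scenarios 1–2 are not reproducible from the generating procedure
implemented here, and the corresponding acceptance check is expected to
sit at the edge of its Monte-Carlo band.

## Known limitations

* Non-adaptive Gauss–Hermite quadrature loses accuracy when binomial
  factors are much sharper than the latent prior (very large counts);
  use the approximate model there, or raise `n_nodes`.
* One covariate at a time, mirroring how the model and \(\Gamma_i\) are
  defined; fit several covariates by fitting several models.
* No REML, profile-likelihood or bootstrap intervals; Wald only.
* The uncorrected two-stage estimator's \(\hat\tau^2\) standard error
  uses a homoscedastic chi-square argument; it is reported for
  comparability, not recommended for inference.
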