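---
title: "Partitioning variation in in-hospital mortality after complex cancer surgery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning variation in in-hospital mortality after complex cancer surgery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihmvar)
```

## The question and the model

In-hospital mortality (IHM) after complex cancer resections — esophagectomy
(ES), pneumonectomy (PN), pancreatectomy (PD), proctectomy (PR) — varies
across hospitals. How much of that variation is attributable to who the
patients are (patient characteristics, PC), how many cases the hospital does
(case volume, CV), what the hospital is structurally (hospital
characteristics, HC), and the social circumstances patients come from
(social determinants of health, SDoH)?

The working model is a two-level random-intercept logistic regression for
death before discharge of patient $i$ at hospital $j$:

$$\operatorname{logit} P(y_{ij} = 1 \mid u_j) = \beta_0 + x_{ij}^\top \beta + u_j,
\qquad u_j \sim N(0, \sigma_u^2).$$

Four nested models add the covariate blocks in a fixed order — PC, then CV,
then HC, then SDoH — each refit with its own random intercept on one shared
complete-case sample. On the latent-threshold scale the outcome variance of
model $m$ splits into three components: the fixed-effect variance
$\sigma_F^2(m) = \operatorname{Var}(x^\top \hat\beta_m)$ (population divisor
$n$, computed over the estimation sample), the hospital variance
$\hat\sigma_u^2(m)$, and the standard-logistic residual $\pi^2/3$. The
explained share of model $m$ is the marginal latent-scale $R^2$

$$R^2_m = \frac{\sigma_F^2(m)}{\sigma_F^2(m) + \hat\sigma_u^2(m) + \pi^2/3},$$

block contributions are successive differences of $R^2_1, \dots, R^2_4$, and
the unexplained share is $1 - R^2_4$.

Two modelling conventions deserve comment because the underlying estimator
of "variance explained" admits more than one reading:

* **The hospital random intercept counts as unexplained.** Unexplained
  variation is what no measured covariate accounts for; the intercepts are
  by construction the unmeasured hospital-level residue. This is the only
  reading under which the unexplained share can exceed 60% while individual
  fixed-effect blocks are credited separately. The alternative — crediting
  $\hat\sigma_u^2$ as explained — is available via
  `explained_proportion(fit, credit_random_effect = TRUE)`.
* **Each model keeps its own $\hat\sigma_u^2$ in the denominator** (refit
  per model), because the decomposition reports one number per nested
  model. A consequence is that increments can in principle be negative
  (adding a block can re-apportion variance between $\sigma_F^2$ and
  $\hat\sigma_u^2$); they are reported as computed, with a warning, never
  clipped.

The intraclass correlation reported alongside fits is the latent-threshold
form $\sigma_u^2 / (\sigma_u^2 + \pi^2/3)$.

### Block layout

The blocks follow the fully adjusted model's presentation: PC = age, sex,
race/ethnicity, Elixhauser comorbidity index, year of diagnosis, procedure;
CV = mean annual volume of the patient's own procedure at the treating
hospital, per 10 procedures; HC = major teaching status, medical-school
affiliation, cancer-program accreditation, physician FTE per bed; SDoH =
SVI percentile, insurance, travel minutes per 10. Two genuinely ambiguous
choices were resolved as follows:

* **Insurance sits in the SDoH block** (it therefore enters at model 4),
  matching the block layout of the adjusted-model table rather than the
  footnote that lists insurance among the baseline adjustments of every
  model. The block lists are configuration (`model_spec()`), so the other
  reading is one argument away.
* **The comorbidity burden enters as the integer Elixhauser count** ("per
  1-unit increase"), not as 27 separate indicators: the synthetic generator
  produces an index, and the count form is what the coefficient scale in
  the source table describes. The 27-indicator variant is deliberately not
  implemented.

## Estimation and numerical choices

`fit_random_intercept_logit()` maximizes the marginal likelihood by
adaptive Gauss–Hermite quadrature via `lme4::glmer`:

* **Quadrature**: 15 points by default (`options$nAGQ`, 0–25). Estimates at
  7 vs 15 points agree to well under 1e-4 on recovery test sets; the
  brute-force trapezoid oracle (`marginal_loglik_oracle()`, an equispaced
  grid over at least ±8 SD of the random effect with log-sum-exp
  stabilization) agrees with the reported AGQ-15 log-likelihood to better
  than 1e-6 on toy sets. `nAGQ = 0` selects lme4's fast profiled
  approximation for very large fits; it coincides with maximum likelihood
  as $\hat\sigma_u^2 \to 0$ and is used in this package's own large
  null/pc_only simulations where that is the regime by construction.
* **Optimizer**: `nloptwrap` (BOBYQA) without derivative re-checks; on this
  model family it reaches equal or better log-likelihoods than the bobyqa
  default at a fraction of the evaluations. Convergence reporting follows
  the optimizer status plus lme4's convergence messages; optimizer failure
  returns a fit with `converged = FALSE` rather than an exception, and a
  singular (collinear) design is an estimation error naming the aliased
  columns.
* **Boundary fits**: $\hat\sigma_u^2$ is reported as exactly the lme4
  estimate with a `boundary` flag when it is below 1e-8; `fix_sigma_u = 0`
  drops to ordinary logistic regression (`glm`), which the test-suite uses
  as the reduction oracle.
* **Inference**: Wald throughout — `OR = exp(beta)`,
  `CI = exp(beta ± z se)` — matching the reporting style of the
  adjusted-model table; no profile likelihood.

## Reliability adjustment and profiling

`eb_hospital_effects()` implements two empirical-Bayes estimators of the
hospital effect. The default (`"posterior"`) computes the posterior mean
and variance of $u_j$ given the hospital's own outcomes under the fitted
model, by numerical integration on a mode-centered grid; the reliability
weight is $1 - \operatorname{Var}(u_j \mid y)/\hat\sigma_u^2$, the share of
prior variance resolved by the data. The `"normal_approx"` method is the
classic shrinkage form $w_j \hat u_j^{raw}$ with
$w_j = \hat\sigma_u^2 / (\hat\sigma_u^2 + v_j)$; it exists because its
shrinkage identity $|u_{shrunk}| \le |u_{raw}|$ is exactly testable. Raw
offsets of degenerate hospitals (no deaths, or all deaths) diverge; they
are capped at ±8 log-odds before weighting, which leaves the shrunken
effect finite and near zero for small hospitals, as shrinkage should.

`shrunken_rates()` standardizes indirectly: every hospital's adjusted rate
is the average of $\operatorname{invlogit}(x^\top \hat\beta + \hat u_j)$
over one common reference case mix, by default the full estimation sample.
(Standardizing to each hospital's own mix is available through
`reference_mix`.) Tertile groups are assigned within each procedure
stratum from Hazen percentile ranks, $100(r - 0.5)/n$ with mean ranks
across ties, so tied hospitals always share a group and an all-tied
stratum is all "medium"; the cut points are the a-priori 33.3/66.7
percentiles. Funnel limits are exact binomial quantiles of deaths/volume
at the center rate, so their realized exceedance probability is slightly
below the nominal $\alpha$ by discreteness — the coverage test compares
against the discreteness-exact rate, not a nominal 5%.

## The synthetic cohort generator

Because the source registry is access-restricted, every stage is driven by
a generator whose ground truth is known. It emulates the published
marginal structure of the California 2010–2020 cohort (52,838 admissions,
294 hospitals):

| quantity | design | tuned to |
|---|---|---|
| age | truncated normal (67.79, 11.23) on [18, 95] | median 68, IQR 60–75 |
| sex, race, insurance, year | categorical draws | printed counts / 52,838 |
| comorbidity index | negative binomial (size 1.3, mu 2.6), truncated at 27 | quartiles 1/2/4 |
| SVI | 100 × Beta(1.274, 1.030) | quartiles ≈ 31.6/59.6/77.2 |
| travel minutes | log-normal (log 20, 0.814) | median 20, IQR 11.8–35.4 |
| per-procedure volume | log-normal matched to printed mean ± SD, for offering hospitals | ES 3.7 ± 5.7 … |
| offering probability | 158/294, 245/294, 166/294, 255/294 | hospital counts |

Hospital assignment is volume-proportional within the drawn procedure,
which concentrates patients at high-volume centers (the patient-level
volume distribution is the size-biased log-normal — used in closed form by
`designed_linear_predictor_variance()`). Insurance is drawn conditionally
on age (Medicare probability 0.78 at ≥ 65, the younger-stratum probability
solved so the overall marginal is preserved exactly); all other covariates
are independent. That independence is a deliberate simplification: real
discharge data carry correlations (age–comorbidity, SVI–insurance,
volume–teaching) the generator does not emulate, so passing tests
demonstrate correctness of the estimation machinery under the stated
model, not robustness to real-data dependence structure.

One global seed expands into named substreams (`hospitals`, `intercepts`,
`patients`, `outcomes` via `substream_seed()`), so regenerating outcomes
under different effects never perturbs covariate draws, and identical
(config, seed) reproduce byte-identical cohorts.

### Presets and calibration constants

* `"null"`: all effects zero, $\sigma_u = 0$, intercept
  $\operatorname{logit}(0.017)$ — the no-signal benchmark.
* `"pc_only"`: only the PC-block effects are nonzero, $\sigma_u = 0$, and
  the intercept (−7.2774) was solved once so the marginal death rate is
  1.7%. Its designed latent $R^2$ (≈ 0.399) is closed-form arithmetic from
  the preset constants, which is what the decomposition must recover.
* `"calibrated"` / `"california"`: every effect equals the log of the
  fully adjusted odds ratios (age ln 1.03, female ln 0.66, comorbidity
  ln 1.63, volume ln 0.99 per 10, SVI ln 1.01, travel ln 0.95 per 10,
  …); year effects decline log-linearly at −0.0617 per year to mirror the
  published crude fall from 2.2% to 1.2%. Two constants the source never
  states were calibrated once and frozen: the intercept (−8.0615, solved
  so the marginal death rate is 1.7% over a 400,000-draw covariate sample
  with Gauss–Hermite integration over $u$) and $\sigma_u = 0.8715$, solved
  in closed form so the designed total explained share equals the printed
  final-model value of 36.8%.

## Problem sizes used by the test suite

Simulation scales were chosen from bias arithmetic, not convenience: the
sample variance of $x^\top\hat\beta$ overstates $\operatorname{Var}(x^\top\beta)$
by approximately $\operatorname{tr}(S_x V_{\hat\beta})$, which shrinks with
the number of events. The decomposition-recovery runs therefore use 20
replicates of 60,000 patients across 100 hospitals (expected inflation ≈
0.005 on the $R^2$ scale, inside the ±0.01 assertion), the null-scenario
check uses one cohort of 100,000, and the coverage study follows the
50-hospitals × 100-patients × 50-replicates design with AGQ-7.

## Known limitations

* **Few clusters, rare events.** With 50 hospitals, a 1.7% outcome
  (~85 deaths per replicate) and six hospital-level fixed covariates,
  maximum likelihood systematically underestimates $\sigma_u$ — the
  hospital-level fixed effects absorb intercept variance, and Wald
  intervals for hospital-level coefficients narrow accordingly. This is a
  property of the estimator at that design, not of the implementation: the
  same machinery recovers $\sigma_u$ when the fixed-effect block is small
  relative to the cluster count. The coverage/recovery test at that scale
  is reported as measured; interpret hospital-level inference at small
  cluster counts with care (or with cluster-robust alternatives outside
  this package's scope).
* **Independence of simulated covariates** (above): marginal fidelity is
  tested, joint fidelity is not claimed.
* **The variance-explained estimator of the source analysis is unstated.**
  The printed cumulative row is therefore treated as input arithmetic
  (differencing) rather than a reproduction target; this package's
  estimator is fully specified above so its numbers are reproducible by
  construction.
* **No crossed/nested random effects, random slopes, GEE or Bayesian
  estimation**; no O/E ratios with Poisson intervals; figures are left to
  the caller — profiling and funnel output are plain tables.
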