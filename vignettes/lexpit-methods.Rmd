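---
title: "Absolute risk regression for population-based case-control studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absolute risk regression for population-based case-control studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lexpit)
```

## The model

Logistic regression answers relative questions — odds ratios — but public
health decisions often need absolute ones: how many excess cases per 100,000
people does an exposure account for? The linear-expit (lexpit) model makes
absolute risk the estimand while still accommodating covariates whose effects
are multiplicative. The probability of disease within a fixed risk period
$\tau$, given additive covariates $x$ and multiplicative covariates $z$, is

$$R(x, z) = \beta' x + \operatorname{expit}(\gamma_0 + \gamma' z),
\qquad \operatorname{expit}(u) = \frac{e^u}{1 + e^u}.$$

Each $\beta_k$ is a risk difference in probability units per unit of $x_k$,
adjusted for everything else in the model. The intercept lives inside the
expit, so the baseline risk $R_0 = \operatorname{expit}(\gamma_0)$ needs no
constraint to stay in $[0,1]$. Each $e^{\gamma_k}$ is a *residual odds
ratio*: the odds-ratio effect of $z_k$ on the risk that remains after the
additive component $\beta'x$ is subtracted,
$(R - \beta'x)/(1 - R)$. With an empty additive block the model is exactly
logistic regression; with an empty multiplicative block it is the linear
binomial (additive risk) model. Dividing $R(x,z)$ by $\tau$ gives an average
incidence rate under the assumption of constant risk over the period
(`incidence_rate()`).

## Sampling weights and the pseudo-likelihood

In a population-based case-control study with complete case ascertainment,
all cases in the study base enter the sample, and controls are a stratified
random sample from a census frame. `cc_design()` records each stratum's
population size $N_j$ and control sample size $n_j$;
`add_sampling_weights()` gives every case weight 1 and every control in
stratum $j$ the expansion weight $w = N_j / n_j$, the inverse of its sampling
fraction. Summed control weights reconstruct the stratum populations exactly
(`expansion_totals()`), so weighted proportions of the sample are absolute
risks in the study base. Weights may instead be supplied as a column for
designs whose fractions come from elsewhere; an explicit column wins over a
design, with a warning. Cases are assumed completely ascertained; a
case-weight column can override this.

Estimation maximizes the weighted pseudo-log-likelihood

$$\ell(\beta, \gamma_0, \gamma) = \sum_{j}\sum_{i} w_{ij}
\left[ y_{ij} \log R_{ij} + (1 - y_{ij}) \log (1 - R_{ij}) \right],$$

which with unit weights is the exact Bernoulli log-likelihood of a cohort.
Because the additive part can push $R$ outside $[0,1]$, the maximization is
constrained to the feasible region: one pair of bounds
$0 \le R(x,z) \le 1$ for every *unique observed covariate pattern*
(duplicates collapsed after centering/scaling; `feasible_region()` exposes
the constraint set).

## The optimizer

`lexpit()` uses a log-barrier interior-point method written for this
problem: the objective $-\ell + \mu \sum_p [-\log R_p - \log(1 - R_p)]$ over
unique patterns $p$ is minimized by damped Newton iterations (analytic
gradient and Hessian; Levenberg ridging when curvature is indefinite;
backtracking line search that rejects infeasible points), with the barrier
weight $\mu$ reduced geometrically from $10^{-2}$ to $10^{-12}$ relative to
the likelihood scale. A final barrier-free Newton polish with a
feasibility-guarded line search removes the barrier bias whenever the
optimum is interior. The pseudo-log-likelihood itself returns $-\infty$
outside the feasible region, so no iterate can escape it.

Numerical choices that matter:

* **Starting values.** $\gamma$ from a weighted logistic fit of the
  multiplicative block (`stats::glm`, quasibinomial family so expansion
  weights are accepted) and $\beta = 0$. Logistic probabilities are strictly
  inside $(0,1)$, so the start is always feasible. If the logistic start
  fails (separation, degenerate block) the marginal weighted rate is used and
  a warning is raised.
* **Convergence.** Iterations stop on the Newton decrement
  $g' H^{-1} g / 2$, which is invariant to the weight scale; a fit is
  declared converged when the final decrement is below $10^{-9}(1 +
  |\ell|)$, or the gradient passes the analogous test, or constraints are
  active and the pseudo-log-likelihood has stabilized to $10^{-9}$ relative.
  The iteration cap is 500 (`lexpit_control()`).
* **Active constraints.** Patterns whose fitted risk is within $10^{-6}$ of
  0 or 1 are reported; Wald inference for parameters at the boundary is
  flagged as unreliable. Fitted risks are clipped to $[0,1]$ for reporting.
* **Degenerate inputs.** A covariate constant across the sample is an error
  naming the covariate; strata contributing controls but no cases (or cases
  but no controls) are allowed; a variable in both blocks triggers a
  weak-identification warning and is intended for
  `dual_scale_comparison()`.
* **Determinism.** The fit involves no randomness; identical data, terms and
  options give identical results, and results are invariant to row order and
  to rescaling all weights by a constant.

Centering and scaling (`center = c(age = 60)`, `scale = c(pack_years =
10)`) are user-specified, recorded in the fit, and applied before pattern
deduplication, so "per 10 pack-years" style effects are explicit covariate
rescalings, not automatic transforms.

## Variance estimation

The inverse observed information is not valid under expansion weighting, so
`lexpit()` uses influence-function linearization, the standard survey
approach. The influence of observation $ij$ is $d_{ij} = w_{ij} \hat
H^{-1} s_{ij}$ with $s_{ij}$ the per-observation score and $\hat H$ the
weighted observed information; influences sum to zero at an interior
optimum. The parameter covariance estimates the variance of the influence
total with two components:

* **Controls** are a stratified random sample: each sampling stratum
  contributes the centered between-unit term $\frac{n_j}{n_j-1} \sum_i
  (d_{ij} - \bar d_j)(d_{ij} - \bar d_j)'$. A finite-population factor
  $1 - n_j/N_j$ is available (`fpc = TRUE`) but off by default — census
  sampling fractions are typically well below 1%. Strata with a single
  sampled control are collapsed with the nearest stratum by label order,
  with a warning.
* **Cases** are completely ascertained, so their randomness is the Bernoulli
  outcome process of the study base, not a sampling process. The default
  (`case_component = "model"`) therefore adds their *uncentered* outer
  products $\sum_i d_i d_i'$, which estimates the outcome-model score
  variance in the rare-disease regime. The alternative `"resampling"`
  centers the cases as one stratum; that estimates the smaller variance
  *conditional on the total case count* and is the quantity a bootstrap that
  resamples a fixed number of cases estimates. The two agree when case
  counts are balanced across the additive contrasts of interest and diverge
  on baseline-risk directions; the default is the one whose intervals attain
  nominal coverage across replicate synthetic studies (see the validation
  summary below).

With no design and unit weights every observation is model-based and the
estimator reduces to the ordinary sandwich; for an intercept-only model it
reproduces the binomial variance $\hat p(1-\hat p)/n$ exactly. A stratified
bootstrap (`boot_vcov()`: cases resampled as one stratum, controls within
sampling strata) is available as a cross-check and for small-sample caution.
Wald intervals are formed on the coefficient scale; residual-odds-ratio
intervals exponentiate the endpoints, and `risk_difference_report()`
rescales additive effects to a population unit (default per 100,000 persons
per risk period).

## Diagnostics

**Weighted Hosmer-Lemeshow.** Observations ranked by fitted risk are cut
into `groups` (default 10) bins of nearly equal *total weight* — weights
span orders of magnitude between cases and controls, so equal-count deciles
would make expected counts unstable on the population scale. Per group the
weighted observed events $O_g = \sum w y$ and expected events $E_g = \sum w
\hat R$ give

$$X^2 = \sum_g \frac{(O_g - E_g)^2}{E_g\left(1 - E_g / W_g\right)}.$$

Ties in fitted risk stay in one group (grouping is over unique fitted
values), making the statistic exactly row-order invariant at the price of
slightly unequal group weights; degenerate groups ($E_g = 0$ or $W_g$) merge
with a neighbor. With unit weights the statistic is the classical one. No
p-value is attached: under expansion weighting the reference distribution is
nonstandard, and the statistic is used as in practice — to compare candidate
models for the same data, lower being better.

**Risk-exposure scatter.** `risk_exposure_scatter()` bins a continuous
exposure into equal-weight groups and plots the crude weighted risk
$\sum w y / \sum w$ per bin against the bin's weighted mean exposure. An
approximately linear trend suggests an additive effect; expit-like curvature
suggests a multiplicative one.

**Dual-scale comparison.** `dual_scale_comparison()` fits the exposure
additive-only, multiplicative-only, and on both scales jointly, reporting
coefficients, standard errors, Wald $z$ and each model's weighted
goodness-of-fit statistic. In the joint model the scale carrying the effect
tends to carry the larger $|z|$. The joint model is generally weakly
identified, so no automatic verdict is issued; if it fails, the report
degrades to the single-scale fits with a flag.

## The synthetic-study generator

`lexpit_scenario()` + `generate_population()` + `sample_case_control()`
simulate the full mechanism the estimator assumes: a finite population
partitioned into strata, covariates drawn from a configurable model,
outcomes drawn Bernoulli from a known lexpit truth (the scenario is rejected
before simulation if any true risk leaves $[0,1]$), complete case
ascertainment, and within-stratum simple random sampling of controls, with
the matching `cc_design()` emitted. The recorded population size is
configurable: the census frame convention (`frame = "population"`, default)
counts everyone including future cases, so control weights expand to the
full stratum population; `frame = "noncases"` expands to the non-case
population exactly. At realistic disease risks of a few per thousand the
difference is negligible.

`eagle_scenario()` ships a default scenario shaped like a large
population-based lung-cancer case-control study in Northern Italy: 90
strata (5 regions x 9 age bands x 2 genders) with the published control
population and sample sizes, and true effects near the published analysis —
additive 3-year risk differences of $4.6\times10^{-5}$ for female,
$52.9\times10^{-5}$ per 10 pack-years and $-39.3\times10^{-5}$ for their
interaction, a multiplicative age effect of $\log 1.12$ per year (age
centered at 60), baseline log-odds $\operatorname{logit}(6\times10^{-4})$,
$\tau = 3$ years. Covariates are simple parametric stand-ins: age uniform
within its band, smoking prevalence 0.75 (men) and 0.43 (women), pack-years
among smokers gamma with mean 35 (men) and 22 (women) capped at 120. The
generator emulates the *design*, not any real microdata: covariates are
independent within strata given gender and age, there is no interview
nonresponse, no individual matching, and no measurement error, so passing
validation here shows the estimator is correct under its stated assumptions,
not that those assumptions hold in any particular study.

Two generator options exist because of a small-sample property worth
knowing: with only 0-2 sampled controls in a stratum, the stratum's expansion
weight rides on a tiny sample and the nonlinear estimator picks up a visible
finite-sample bias. Scaling a scenario down for replicate studies should
therefore scale the *population*, not the per-stratum control counts
(`control_scale`), and `collapse_regions = TRUE` merges the five regions —
which carry no risk signal in the truth — into 18 gender-by-age strata,
removing the single-control strata of the full design.

## Validation studies shipped in the test suite

The package's claims are tested against independent oracles (closed forms,
an independently maximized weighted logistic fit, dense grid search, hand
arithmetic) and by seeded replicate studies whose sizes were chosen as a
balance of resolution and runtime:

* parameter recovery and interval calibration: 500 replicate studies of the
  gender-by-age scenario at 30% of the full study base with the published
  control counts; means over 200 replicates lie within 2 Monte-Carlo
  standard errors of the truth and 95% Wald coverage lies in 93-97% over
  all 500;
* variance validity: linearized standard errors against a 2,000-draw
  stratified bootstrap (within 20%, comparing the case-total-conditional
  variants on both sides) and against the Monte-Carlo SD of estimates over
  500 gender-only replicate studies (within 15%, using the default
  model-based case component);
* goodness-of-fit behavior: the statistic is exactly zero for a saturated
  fit, equals the classical statistic at unit weights, and ranks a
  correctly specified additive-plus-multiplicative model below a strictly
  multiplicative logistic fit of the same variables in at least 90% of 200
  replicates of a scenario with material scale misfit.

## Limitations

* The risk period is tied to the case-ascertainment window; long-term risks
  are out of reach, and risk is assumed constant within the period.
* Validity rests on accurate sampling weights; secondary-base designs
  (hospital or registry controls) rarely support them.
* Individually matched designs, nonresponse adjustment, post-stratification
  or calibration weighting, penalized variants and alternative multiplicative
  links are out of scope.
* Wald inference is asymptotic and unreliable for parameters whose fitted
  patterns sit at the $[0,1]$ boundary (the fit warns); profile or
  small-sample intervals are not provided.
* The weighted goodness-of-fit statistic has no attached reference
  distribution; use it comparatively.
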