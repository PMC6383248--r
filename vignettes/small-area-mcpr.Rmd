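---
title: "Small-area estimation of modern contraceptive prevalence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area estimation of modern contraceptive prevalence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

National household surveys in low-income countries are powered for
national indicators. The modern contraceptive prevalence rate (mCPR) —
the share of women of reproductive age using a modern method — is needed
by health departments at the regional level, where the survey's own
sample is too small for precise direct estimation: a region is a *small
area* in the sample-size sense regardless of its geographic size. This
package implements a woman-level Bayesian hierarchical model that
borrows strength across areas, covariates and survey rounds to produce
stable subnational estimates with honest uncertainty, together with the
design-based direct estimators it should be compared against and the
diagnostics that justify trusting it.

## The model

Data are one row per woman-interview, nested in enumeration areas (EAs,
the sampling clusters), which nest in regions, observed over repeated
survey rounds. For woman $i$ in area $k$ at round $t$:

$$y_{ikt}\mid P_{ikt} \sim \mathrm{Bernoulli}(P_{ikt}),\qquad
\mathrm{logit}(P_{ikt}) = x_{ikt}'\beta + u_{kt}.$$

The design vector $x_{ikt}$ contains one indicator per round (round
specific intercepts; there is no separate global intercept) and the
encoded covariates. The area-by-round effects follow a stationary
first-order autoregression across rounds,

$$u_{k1}\sim N\!\left(0,\tfrac{\sigma^2}{1-\rho^2}\right),\qquad
u_{kt} = \rho\,u_{k,t-1} + \varepsilon_{kt},\quad
\varepsilon_{kt}\sim N(0,\sigma^2),$$

independent across areas. The AR(1) structure lets each area's
trajectory deviate smoothly from the covariate surface and makes
round-to-round change estimates respect the serial correlation of the
underlying area effects.

Whether "area" means EA or region is configurable (`area_level`); the
default is the EA, the lowest level of the sampling hierarchy, with
region-level effects available for sensitivity analysis. Aggregation
works identically under either choice.

**Covariates.** The standard set is twelve woman-level determinants of
modern contraceptive use: residence, schooling, wealth quintile, child
survival, age, cohabitation, recent sexual activity, health worker
visit, family planning message exposure, fertility intention, parity and
distance to the nearest facility. Their exact codings in the original
microdata are not public, so `default_covariates()` uses plausible kinds
(wealth quintile a five-level factor, parity a count, age standardized)
and every element is user-replaceable. Rows with a missing model
covariate are dropped with a logged count (complete-case); no imputation
is attempted.

**Priors.** The source analysis does not publish its priors, so the
defaults are weakly informative on the logit scale and configurable via
`bhm_priors()`: $\beta_j \sim N(0, 5^2)$, $\sigma \sim$ Half-Normal(1),
and $(\rho+1)/2 \sim \mathrm{Beta}(1,1)$, i.e. $\rho$ uniform on
$(-1,1)$.

**Weights.** The likelihood is the unweighted woman-level Bernoulli,
following the model statement literally; survey weights enter only when
woman-level probability draws are aggregated. This is a documented
design choice, not a claim about the original computation.

## Computation

No general-purpose MCMC backend is assumed: the sampler is built in.
Pólya-Gamma data augmentation (Polson, Scott & Windle, 2013) makes the
conditional posteriors of $\beta$ and of each area's
$T$-dimensional effect vector Gaussian — the AR(1) prior contributes a
tridiagonal precision — so both are Gibbs steps; $\rho$ and $\sigma$
move by adaptive random-walk Metropolis on the $\mathrm{atanh}$ and
$\log$ scales respectively (adaptation during warmup only, targeting a
0.44 acceptance rate). The PG(1, z) variables are drawn with the exact
alternating-series rejection sampler, driven by R's RNG so a fixed seed
yields bit-identical chains.

Defaults are 4 chains of 1000 warmup plus 1000 retained draws.
Convergence is summarized per parameter by the rank-normalized split
potential-scale-reduction factor and bulk effective sample size
(Vehtari et al., 2021), with thresholds 1.05 (warn) / 1.1 (fail) and
ESS 100; a non-converged fit warns but is not discarded. The R-hat is
floored at 1, so chains in exact agreement report exactly 1.0. The
scalar parameters $\rho$ and $\sigma$ mix more slowly than $\beta$
(they are informed only by the $K \times T$ effect field); short chains
are fine for interval-based simulation checks but production runs
should use the defaults.

## Estimands

Regional and national prevalence are computed *within each joint
posterior draw* as the weight-normalized mean of the woman-level
$P^{(s)}_{ikt}$ over the sampled women of that level and round
(`aggregate_mcpr()`, `mcpr_table()`); the point estimate is the
posterior median and the uncertainty interval the equal-tailed 2.5–97.5
percentile range. Change between rounds is the draw-wise difference
(`change_posterior()`): because differencing happens inside the joint
posterior, serial correlation is automatically respected — the interval
for the change is not the difference of interval endpoints, and the
median change need not equal the change in medians. `prob_target()`
turns any such posterior into the probability of exceeding a
programmatic target. Aggregation is over the sampled women with their
survey weights; no post-stratification to census totals is attempted.

## Direct estimators

The EA-level direct estimate is the raw ratio of users to sample size
with a Wilson score interval. Regional and national direct estimates are
weighted proportions with variance by EA-clustered Taylor
linearization and intervals formed on the logit scale (Wilson fallback
at boundary estimates, unclustered flag when a region has a single EA).
The source analysis does not state its direct-interval method; these
choices are standard, respect $[0,1]$, and are not claimed to reproduce
its printed direct intervals.

## Diagnostics

`shrinkage_table()` joins, per unit-round, the direct estimate, the
model posterior and the covariate-only prediction (all $u$ zeroed):
hierarchical shrinkage pulls small cells strongly toward the regression
surface and large cells hardly at all, and the interval-width ratio
quantifies the precision gain.

`z_values()` standardizes each cell's observed user count against its
posterior-predictive distribution. Two constructions are offered. The
*conditional* replication (`u_rep = "posterior"`) keeps each draw's
estimated area effects; because those absorb much of a cell's deviation,
its Z-values are strongly conservative (variance well below 1 even for a
correct model) and useful only for within-cell fit. The default *mixed*
replication (`u_rep = "prior"`, in the sense of Marshall &
Spiegelhalter, 2007) re-draws the whole effect field from its
stationary AR(1) prior given each draw's $(\rho, \sigma)$, which makes
the Z-values calibrated (mean ≈ 0, variance ≈ 1 under a correct model)
so extreme areas stand out. The exact Z formula used with the original
analysis is unpublished; this construction is this package's own,
chosen because its calibration is testable. Analytic moments
($\sum P$, $\sum P(1-P)$ per draw, combined by the law of total
variance) and brute-force Bernoulli simulation agree within Monte-Carlo
error and both are available.

## The synthetic-data generator

`generate_dataset()` runs the model forward as a stated world, not a
tuning dial. Defaults emulate a Ghana-like survey: 10 regions, 94 EAs,
four semi-annual rounds of 3460/3645/4251/4801 women allocated evenly
over EAs, AR(1) effects with $\rho = 0.6$, $\sigma = 0.5$ (stationary
SD ≈ 0.63 on the logit scale), and round intercepts calibrated so the
implied national mCPR tracks roughly 14→23%. Covariate distributions
are plausible defaults — binary covariates Bernoulli(0.5), wealth
quintile uniform, age uniform 15–49 (standardized), parity Poisson(2),
facility distance exponential with mean 5 km — all overridable. A
master seed spawns separate sub-streams for covariates, effects and
outcomes so components can be varied independently.

The generator emulates the *statistical* structure the model assumes:
nesting, round structure, AR(1) effects, Bernoulli outcomes. It does not
emulate informative sampling weights, nonresponse or attrition, spatial
correlation between areas, repeated interviews of the same woman, or
covariate measurement error. A green recovery test therefore
establishes that the machinery is correct under the model's own
assumptions — not that the model is right for any particular real
survey.

## Simulation evidence (computed by the test suite)

The acceptance tests recompute, at every run: exact agreement of the
likelihood and prior with brute-force oracles; AR(1) generator
calibration at 10,000 series; 95% credible-interval coverage of
$\beta$, $\rho$, $\sigma$ and of the true regional prevalences across
50 replicate surveys (20 EAs, 4 rounds, ~4000 women each, at reduced
draw counts to fit a test-time budget); shrinkage monotonicity in cell
size and interval narrowing relative to the direct estimator; Z-value
calibration; and bit-identical reproducibility under a fixed seed,
including a command-line round trip (`simulate → fit → report`). The
replicate studies use a reduced covariate set (one binary, one
three-level categorical, one continuous) purely for runtime; the
recovery target parameters are unchanged.

## Numerical and design notes

- $\rho$ is updated on the $\mathrm{atanh}$ scale (Jacobian included),
  keeping $|\rho| < 1$ without user-visible transforms; $\sigma$ on the
  log scale with its Half-Normal prior.
- Empty area-round cells are not deleted: their $u_{kt}$ exists and is
  smoothed by the AR(1) prior; prediction for areas never seen at fit
  time draws effects from the stationary prior per draw and flags the
  records as extrapolation. Rounds never seen at fit time cannot be
  predicted (their intercept does not exist).
- With a single round the AR(1) reduces to independent effects with the
  stationary variance; $\rho$ is then informed only by its prior.
- All report tables keep full precision internally and round only at
  write time.
- The covariate-selection procedure that produced the twelve-covariate
  list, choropleth mapping, and survey-frame construction are out of
  scope; so is any survey-weighted likelihood.

## References

Polson, N. G., Scott, J. G., Windle, J. (2013). Bayesian inference for
logistic models using Pólya-Gamma latent variables. *JASA* 108,
1339–1349.

Marshall, E. C., Spiegelhalter, D. J. (2007). Identifying outliers in
Bayesian hierarchical models: a simulation-based approach. *Bayesian
Analysis* 2, 409–444.

Vehtari, A., Gelman, A., Simpson, D., Carpenter, B., Bürkner, P.-C.
(2021). Rank-normalization, folding, and localization: an improved
$\widehat R$ for assessing convergence of MCMC. *Bayesian Analysis* 16,
667–718.
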