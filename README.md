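# mcprsae

Small-area estimation of the modern contraceptive prevalence rate
(mCPR) from multi-round cluster household surveys, for analysts who need
regional indicator estimates from surveys that were powered only for
national ones.

## What it does

National surveys leave first-level administrative divisions (regions,
counties) with samples too small for precise direct estimation. This
package fits a woman-level Bayesian hierarchical logistic model that
borrows strength across areas, covariates and survey rounds:

```
y_ikt | P_ikt ~ Bernoulli(P_ikt)
logit(P_ikt) = x_ikt' beta + u_kt
u_k1 ~ N(0, sigma^2 / (1 - rho^2)),  u_kt = rho u_k,t-1 + N(0, sigma^2)
```

for woman `i` in area `k` (enumeration area or region) at round `t`,
with round-specific intercepts and a standard set of twelve woman-level
covariates (residence, schooling, wealth quintile, child survival, age,
cohabitation, recent sex, health worker visit, family planning message,
fertility intention, parity, distance to facility) in `x`. The AR(1)
area-by-round effects `u_kt` capture serial correlation of area
trajectories, so round-to-round change is estimated with the right
uncertainty. Fitting is by a built-in Pólya-Gamma Gibbs sampler
(Rcpp/RcppArmadillo); no external MCMC engine is required.

Around the model the package provides:

- the data contract and readers for woman-level CSV microdata
  (`read_women()`, `profile_dataset()`, `filter_balanced_eas()`);
- a synthetic survey generator with known truth for simulation studies
  (`generate_dataset()`, `simulate_ar1()`, `true_regional_mcpr()`);
- design-based direct estimators as the comparator (`ea_direct()`,
  `region_direct()`, Wilson and EA-clustered logit intervals);
- posterior aggregation to regional/national prevalence, draw-wise
  change, and probability-of-target (`mcpr_table()`,
  `aggregate_mcpr()`, `change_posterior()`, `prob_target()`);
- shrinkage and posterior-predictive Z-value diagnostics plus
  convergence reporting (`shrinkage_table()`, `z_values()`, `rhat()`,
  `ess_bulk()`, `convergence_report()`, `report_bhm()`);
- a command-line front end
  (`inst/cli/mcpr-sae.R simulate|fit|estimate|diagnose|report`).

See `vignettes/small-area-mcpr.Rmd` for the model, priors, sampler and
design choices in full.

## Worked example

Simulate a four-round survey of 4000 women in 20 EAs across 4 regions,
fit the model, and summarize:

```r
library(mcprsae)
sim <- generate_dataset(generator_config(n_regions = 4,
  eas_per_region = 5, rounds = 4, women_per_round = 1000, seed = 1))
fit <- bhm(sim$data, chains = 2, iter = 500, warmup = 500, seed = 1)
fit
#> Bayesian hierarchical logistic model (AR(1) area-round effects)
#>   4000 women, 20 ea-level areas, 4 round(s), 20 coefficients
#>   2 chains x 500 draws (warmup 500, thin 1), seed 1
#>   rho: 0.422 [0.048, 0.768]  sigma: 0.473 [0.313, 0.637]
#>   max Rhat 1.060, min bulk ESS 40
```

(The short demo chains trigger a non-convergence warning for `sigma`;
the 4-chain, 1000-draw defaults are meant for production runs.)
National prevalence by round, posterior median with 95% interval:

```r
subset(mcpr_table(fit), region_id == "ALL")
#>  region_id round  mcpr lower upper    n
#>        ALL     1 0.136 0.116 0.158 1000
#>        ALL     2 0.152 0.131 0.174 1000
#>        ALL     3 0.191 0.167 0.215 1000
#>        ALL     4 0.265 0.242 0.291 1000
```

The generating truth rises from about 14% to 23% nationally; the
estimates track it with ±2-point intervals. Change for one region,
computed within draws so serial correlation is respected:

```r
p1 <- aggregate_mcpr(fit, "region", round = 1, region = "R01")
p4 <- aggregate_mcpr(fit, "region", round = 4, region = "R01")
change_posterior(p1, p4)
#> mCPR change, R01 rounds 1 -> 4: +15.9 points (95% UI +10.3 to +21.7)
#>   [UI excludes 0]
prob_target(p4, 0.20)   # P(region R01 above 20% by round 4)
#> [1] 1
```

Shrinkage diagnostics per EA-round — the model estimate sits between
the noisy direct ratio and the covariate-only prediction, with a
narrower interval (`width_ratio < 1`):

```r
head(shrinkage_table(fit, "ea")[, c("unit_id", "round", "n", "direct",
                                    "bhm", "reg_pred", "width_ratio")], 3)
#>     unit_id round  n direct        bhm  reg_pred width_ratio
#> 1 R01_EA001     1 50   0.18 0.14375397 0.1271193   0.7458105
#> 2 R01_EA001     2 50   0.04 0.09544344 0.1497332   0.9414831
#> 3 R01_EA001     3 50   0.14 0.13720043 0.1538699   0.6994371
```

## Acceptance script

`scripts/acceptance.R` re-runs the whole pipeline from scratch —
synthetic survey with known truth, model fit, regional/national
prevalence and change tables, shrinkage and Z-value diagnostics — and
logs a summary to stderr:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The real microdata behind the original analysis are access-restricted,
so there are no numeric reference targets; the JSON report is an empty
object and the scientific checks (oracle equivalence, AR(1) generator
calibration, parameter and estimand recovery, shrinkage behaviour,
Z-value calibration, determinism) live in the test suite, principally
`tests/testthat/test-acceptance.R`.
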