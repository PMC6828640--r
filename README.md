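# dyadicc

Dyadic agreement ICCs for skewed semicontinuous outcomes, via Bayesian
two-part (hurdle) mixed models.

## The problem

How well does a concerned significant other (CSO) — a partner, parent or
other close person — know how much money a problem gambler actually loses?
When both members of a dyad independently fill in a 30-day timeline
followback (TLFB) of money lost per day, their agreement is naturally
measured by an intraclass correlation coefficient (ICC): the share of the
outcome variance that lies *between* dyads rather than *within* them.

Gambling-loss reports, however, are heavily right-skewed and contain exact
zeros ("no losses"), so the classical Gaussian linear mixed model (LMM)
behind the usual ICC is badly misspecified. `dyadicc` instead models the
reports with a **two-part (hurdle) generalized linear mixed model**:

* a **zero part** — a logistic mixed model for whether a report is nonzero:
  `logit P(y > 0) = beta_z0[g] + delta_z * cso + u_z`,
* a **losses part** — a gamma (or lognormal) mixed model for the positive
  amounts with a log link: `log E[y | y > 0] = beta_c0[g] + delta_c * cso + u_c`,

with dyad-level random intercepts `(u_z, u_c) ~ N2(0, Sigma)` that may be
correlated (`rho`), and group-specific variances and shape parameters per
relationship type `g` (partner / parent / other). Posterior sampling is MCMC
(JAGS); estimates are posterior medians with 95% percentile intervals.

ICCs are computed **on the observed data scale** by integrating over the
random effects in every posterior draw. For one group, writing
`p(u_z)` for the nonzero probability and `m(u_c)` for the conditional mean,

```
ICC = Var_u[ E(y | u) ] / ( Var_u[ E(y | u) ] + E_u[ Var(y | u) ] )
```

evaluated by Gauss–Hermite quadrature for the logistic part and in closed
form for the lognormally distributed conditional mean. Three components are
reported: the **zero** part (agreement on reporting no losses), the
**losses** part (agreement on the positive amounts, closed form
`(e^{sigma_c^2}-1) / ((e^{sigma_c^2}-1) + e^{sigma_c^2}/alpha)` for the
gamma family), and the **overall** semicontinuous outcome. Group contrasts
(e.g. partner − parent), marginal means and zero-proportion contrasts by
rater role, posterior predictive checks, 10-fold cross-validated model
comparison, and a full Monte Carlo validation harness (relative bias,
interval coverage, power) are included.

## Worked example

```r
library(dyadicc)

# a TLFB-like synthetic dataset: 73 partner, 50 parent, 10 other dyads,
# right-skewed positive losses with a minority of exact zeros
scenario <- paper_like_scenario(seed = 2)
dyads <- draw_dyads(scenario)

fit <- fit_two_part(dyads, fit_config("gamma", correlated = FALSE,
                                      chains = 2, iter = 1000, seed = 1))

posterior_icc(fit, "losses", "partner")
#> losses [partner]: 0.671, 95% CI (0.554, 0.752)  [good]
posterior_icc(fit, "losses", "parent")
#> losses [parent]: 0.420, 95% CI (0.189, 0.576)  [fair]
icc_difference(fit, "losses", "partner", "parent")
#> losses difference [partner - parent]: 0.250, 95% CI (0.059, 0.490)
```

The partner dyads agree better on the amounts than the parent dyads
(posterior median difference 0.25, interval excluding zero), recovering the
generating preset in which the true losses ICCs are 0.65 and 0.45. The
`[fair]`/`[good]` tags are conventional verbal anchors, reported as
annotations only.

A Gaussian LMM on the same data gives a much higher, unreliable ICC —
compare the models predictively:

```r
cv <- kfold_compare(dyads,
                    fit_config("gaussian"), fit_config("gamma"),
                    K = 10, seed = 1)
#> 10-fold CV: gaussian versus gamma (indep)
#> elpd_diff = -317.3 (SE 41.7)
```

The negative difference (many standard errors from zero) says the gamma
hurdle model predicts held-out dyads far better than the Gaussian LMM.

## Command line

A thin CLI over the same functions is installed under `inst/cli/dyadicc`:

```sh
dyadicc simulate --preset paper-like --seed 1 --out run1
dyadicc describe --data run1/data.csv --out run1
dyadicc icc --data run1/data.csv --component losses --by-group --out run1
dyadicc cv --data run1/data.csv --family-a gaussian --family-b gamma --out run1
```

Each subcommand writes its result tables plus a `manifest.json` recording
inputs, seeds, filters and the package version.
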