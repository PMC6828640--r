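---
title: "Measuring dyadic agreement on skewed semicontinuous outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring dyadic agreement on skewed semicontinuous outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dyadicc)
```

## The model

Each dyad consists of a problem gambler and a concerned significant other
(CSO) who both report the same quantity: average money lost to gambling per
day over the last 30 days, from a timeline-followback (TLFB) calendar.
Reports are non-negative, heavily right-skewed, and a minority are exactly
zero. The package models a report $y_{ij}$ (dyad $i$, rater $j$) with a
two-part (hurdle) GLMM:

* **Zero part.** $z_{ij} = 1\{y_{ij} > 0\}$ follows a logistic mixed model,
  $\mathrm{logit}\, p_{ij} = \beta_{z0}[g_i] + \delta_z\,\mathrm{cso}_j + u_{zi}$.
* **Losses part.** Given $z_{ij} = 1$, the amount follows a gamma
  distribution with shape $\alpha[g_i]$ and mean
  $m_{ij} = \exp(\beta_{c0}[g_i] + \delta_c\,\mathrm{cso}_j + u_{ci})$
  (log link), or alternatively a lognormal distribution with log-scale
  variance $s^2[g_i]$, parameterized through its conditional mean for all
  moment computations so the two families share one contract.
* **Random effects.** $(u_{zi}, u_{ci}) \sim N_2(0, \Sigma[g_i])$ with SDs
  $\sigma_z, \sigma_c$ and correlation $\rho$; $\rho \equiv 0$ gives the
  independent variant. A positive $\rho$ encodes that dyads with larger
  losses are less likely to report zeros.
* **Groups.** All variance, shape and intercept parameters may differ by
  the CSO's relationship to the gambler (partner / parent / other); the
  rater-role effects $\delta_z, \delta_c$ (CSO minus gambler) are shared
  across groups because ten "other" dyads cannot identify separate role
  contrasts. The gambler is the reference role.

The comparison model is the classical Gaussian two-level LMM on the raw
outcome, zeros included.

## ICCs on the data scale

Variance components from a GLMM live on the link scale; agreement in the
actual reports is a data-scale question. For each posterior draw the
package computes, per group,

$$\mathrm{ICC} \;=\;
\frac{\mathrm{Var}_u\,[\,\mathbb{E}(y \mid u)\,]}
     {\mathrm{Var}_u\,[\,\mathbb{E}(y \mid u)\,] + \mathbb{E}_u\,[\,\mathrm{Var}(y \mid u)\,]}$$

by integrating over the random effects: Gauss–Hermite quadrature for the
logistic-normal zero part (64 nodes; 32 per axis for the 2-D correlated
case, both validated against node doubling and large-sample Monte Carlo),
closed forms for the lognormally distributed conditional mean of the
positive part. Three components are reported:

* **zero**: $p(u) = \mathrm{logit}^{-1}(\bar\eta_z + u)$ with
  $v_b = \mathrm{Var}[p(u)]$, $v_w = \mathbb{E}[p(u)(1 - p(u))]$; the two
  always sum to the marginal Bernoulli variance.
* **losses**: closed form, for the gamma family
  $(e^{\sigma_c^2} - 1)\,/\,((e^{\sigma_c^2} - 1) + e^{\sigma_c^2}/\alpha)$,
  free of intercepts and hence invariant to currency rescaling.
* **overall**: the hurdle outcome $y = z \cdot w$ with conditional mean
  $p\,m$ and conditional variance $p\,m^2(1 + 1/\alpha) - (p\,m)^2$.

Summaries are posterior medians with 95% percentile intervals, and group
contrasts (e.g. partner − parent) are formed draw by draw.

**Role effects and the agreement convention.** The raters of a dyad differ
by role, so a systematic CSO-vs-gambler shift is genuine within-dyad
disagreement. The default (*absolute agreement*) therefore adds the
squared role gap to the within-dyad variance; `role_handling =
"consistency"` marginalizes the role difference out of both variances
instead, which makes the losses-part ICC equal the intercept-free closed
form exactly. Systematic differences themselves are reported separately by
`role_marginals()` (marginal means, zero proportions, and their
CSO-gambler contrasts, dyad-count-weighted across groups).

Whole-sample ("overall sample") ICCs come from a pooled fit
(`group_specific = FALSE`); per-type ICCs from the group-specific fit.
Both are available because the two answer different questions.

## Priors, sampling, and numerical choices

Priors are weakly informative and configurable: half-Student-t(3, 2.5) on
all random-effect SDs, Student-t(3, 0, 5) on intercepts, normal(0, 2.5) on
role effects, uniform(−1, 1) on $\rho$, and normal(0, sd 2) on
$\log \alpha$ — a lognormal prior on the shape that, unlike a half-normal
on the log, does not exclude the heavy-tailed $\alpha < 1$ regime. For the
Gaussian model the location/scale priors scale with the outcome SD so raw
currency units need no rescaling. Random effects use a non-centered
parameterization (the ten-dyad "other" group produces funnel geometry
otherwise). Sampling is MCMC via JAGS with per-chain seeded RNG, so refits
are reproducible draw for draw; convergence is summarized by
potential-scale-reduction (threshold 1.05, flagged with a warning, never
silently) and effective sample size. A dataset that is all zeros stops with
an error (the positive part is unidentifiable); an all-positive dataset
simply pushes the hurdle intercept to large values and reduces to the pure
gamma GLMM.

Degenerate inputs in the ICC engine are handled explicitly: $\sigma^2 = 0$
gives ICC 0; $p \equiv 1$ makes the overall ICC collapse to the losses
ICC; the $\rho = 0$ two-dimensional quadrature agrees with the factorized
path to $10^{-8}$ and the node counts are fixed (reproducibility over
adaptivity), with a node-doubling check and a Monte Carlo fallback for the
zero part.

## What the synthetic generator emulates

No raw dyadic TLFB data ship with the package, so every downstream stage
is exercised on synthetic data. The preset
(`paper_like_scenario()`) emulates the descriptive profile of a
treatment-seeking sample of 133 dyads: 73 partner, 50 parent and 10 other
dyads; about 13% of CSOs and 5% of gamblers reporting no losses (partner
dyads the most); right-skewed positive amounts with group mean levels near
1650/1050/1500 currency units per day; losses-part ICCs of 0.65 (partner),
0.45 (parent) and 0.46 (other) with gamma shapes 3/2/2; zero-part ICCs of
0.5/0.3/0.3; and a small negative CSO role effect on amounts
($\delta_c = -0.03$). Hurdle intercepts, role effect $\delta_z$ and
random-intercept SDs are derived from those targets by deterministic
numerical inversion of the ICC and marginal-rate formulas at construction
time, and recorded in the scenario label.

Two calibration tensions are worth knowing. First, an observed
mean-to-median ratio near 3 in the positive amounts is not reachable
jointly with a losses ICC of 0.65, because that ICC requires a gamma shape
of at least $r/(1-r) \approx 1.9$; the preset prioritizes the ICC targets
and group means, landing the marginal median near 650–700 rather than 500.
Second, matching both a 7% gambler zero rate and a 0.5 zero-part ICC
forces a large $\sigma_z$ (≈ 3.7); this is faithful to how rare zeros
coexist with strong dyadic clustering, but it makes the zero part weakly
identified at n = 133 dyads — short chains then flag imperfect mixing for
the hurdle intercepts, which leaves the a-posteriori-independent losses
part untouched when $\rho = 0$.

The generator does *not* emulate: day-level TLFB autocorrelation (only the
30-day mean is generated), recall-error mechanisms, covariates beyond role
and group, or missingness. Passing tests therefore demonstrate internal
validity of the estimator under the stated generating process, not
robustness to misspecified response distributions.

## The validation harness

`run_study()` replicates the model-validation design: draw a dataset,
fit each candidate model, record posterior medians and intervals per
estimand, and aggregate relative bias (mean of posterior medians versus
truth), 95%-interval coverage, and power — defined as the 95% percentile
interval of the partner−parent ICC difference excluding zero, matching the
interval-based inference style of the rest of the package. Replication
seeds derive deterministically from the study seed; failed fits are logged
and excluded with a reported count; per-replication rows can be persisted
to make long studies resumable. The harness arithmetic is unit-tested to
exactness with stub fitters.

The shipped checks use a reduced design chosen to keep a full run on one
CPU within minutes: 100 replications for the headline coverage check
(binomial 3-SE band ±6.5 points around 95%), 20 replications for the
three-model qualitative comparison (correlated truth, $\rho = 0.5$), 15
replications at 300 dyads for correlated-model parameter recovery, and 2
chains of 600–700 retained iterations per fit. The full-scale design
(thousands of replications) is a configuration value, not a code change.
Under the reduced design the qualitative findings are stable: Gaussian-LMM
intervals undercover the true data-scale ICC of skewed outcomes while
two-part losses inference stays calibrated (with or without the
random-effect correlation modelled), ignoring a true correlation degrades
the overall-ICC estimates, and the two-part model's power to detect the
partner−parent difference is at least the Gaussian model's.

## Model comparison and checking

`kfold_compare()` scores held-out observations by their log predictive
density with the held-out dyad's random effects integrated out (new-dyad
prediction — dyads, not observations, are the exchangeable unit), refitting
per fold on a dyad-level partition that never splits a dyad;
`elpd_diff` and its SE follow the usual pointwise construction.
`posterior_predictive()` replicates datasets from posterior draws with
fresh random effects and compares zero fraction, median, 90th/99th
percentiles and maximum — the summaries that expose a Gaussian model's
negative predictions and missing right tail. Importance-sampling LOO is
deliberately out of scope; k-fold refitting is the implemented path.

## Known limitations

* The zero part is weakly identified when zeros are rare (by design of the
  data); its ICC carries wide intervals and some bias, though with
  adequate interval coverage.
* ICC estimands assume exactly two raters per dyad and a single outcome;
  counts, more raters, or chance-corrected categorical agreement are out
  of scope.
* The CLI is a thin convenience layer; programmatic use is the primary
  interface.
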