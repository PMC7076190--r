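---
title: "Polya-Gamma Gibbs sampling for the DINA model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polya-Gamma Gibbs sampling for the DINA model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dinapg)
```

## The model

The DINA (deterministic inputs, noisy "and" gate) model classifies `N`
examinees over `K` binary skills ("attributes") from their 0/1 answers to
`J` test items. A `J x K` Q-matrix records which attributes each item
requires. The examinee's latent attribute pattern `alpha_i` lies in one of
`C = 2^K` classes; the *ideal response* `eta_ij` is 1 exactly when examinee
`i` masters every attribute item `j` requires. Conditional on `eta`,
responses are noisy:

\[
P(Y_{ij}=1) = g_j + (1 - s_j - g_j)\,\eta_{ij},
\]

with guessing probability `g_j` and slipping probability `s_j`. On the
logit scale this is a logistic model in `eta`:

\[
\mathrm{logit}\,P(Y_{ij}=1) = \zeta_j + \beta_j \eta_{ij},
\qquad \zeta_j = \mathrm{logit}(g_j),\quad
\beta_j = \mathrm{logit}(1-s_j)-\mathrm{logit}(g_j),
\]

and the restriction `beta_j > 0` (a positive item discrimination index
`1 - s_j - g_j`) identifies the direction of mastery. Class membership
probabilities `pi` over the `2^K` patterns complete the model; patterns are
ordered canonically with the first attribute as the most significant bit,
and that order indexes `pi` everywhere in the package.

## The sampler

The logistic likelihood admits exact Gaussian conditionals after
Polya-Gamma augmentation: with `W_ij ~ PG(1, |zeta_j + beta_j eta_ij|)`,
each `zeta_j` has a normal full conditional with variance
`V = (1/var_zeta + sum_i W_ij)^{-1}` and mean
`V (mu_zeta/var_zeta + sum_i (Y_ij - 1/2 - W_ij beta_j eta_ij))`, and each
`beta_j` a positive-truncated normal analogue restricted to the masters
(`eta = 1`, and `eta^2 = eta` for binary `eta`). One iteration performs, in
order: (1) refresh all `W`; (2) draw all intercepts; (3) draw all
interactions; (4) draw each examinee's class from a multinomial whose log
weight for class `c` reduces to
`log pi_c + sum_j [(Y_ij - 1/2) z_jc - W_ij z_jc^2/2]` with
`z_jc = zeta_j + beta_j eta_cj` (the PG base density cancels in
normalization, and `e^{yz}/(1+e^z) \cosh(z/2) = e^{(y-1/2)z}/2`; the test
suite verifies this identity against direct evaluation); (5) draw `pi` from
its Dirichlet conditional. Every conditional is sampled exactly, so there
are no proposal scales to tune and no rejected moves.

PG(1, z) variates are generated exactly by the alternating-series rejection
sampler on the Jacobi density (inverse-Gaussian and exponential proposal
mixture), not by truncating the defining infinite sum of gamma variates;
the truncated sum survives only as an independent oracle in the tests.
Because one sweep draws `N` auxiliaries per item at only two distinct
tilts, the proposal constants are precomputed per item, which is where the
sampler's speed comes from.

The Metropolis-Hastings baseline replaces steps (2)-(3) with item-wise
random walks: `zeta` from `N(current, var_zeta_prop)` and `beta` from a
positive-truncated `N(current, var_beta_prop)` whose Hastings ratio carries
the `Phi(current/sd)/Phi(proposal/sd)` correction. The proposal scales 0.1
and 1 are *variances*; that reading matters because the comparison between
them is precisely the point of the baseline. Classes and `pi` are updated
as in the Gibbs sampler, with the marginal Bernoulli class weights (no `W`
term).

## Priors, parameter bounds, and a reproducibility caveat

Defaults are non-informative: `N(mu, 1e5)` on `zeta` and (truncated) on
`beta`, `Dirichlet(1)` on `pi`. `dina_prior()` additionally supports
interval truncation of the parameter space, and the packaged simulation
studies run on the box `zeta in [-2.5, -1]`, `beta in [2.5, 4.5]`
(`study_bounds()`), which brackets the true values of all four study noise
levels.

The box deserves an honest explanation. With unbounded non-informative
priors, the average mean-squared errors of the item parameters in the
30-item, 5-attribute, `N = 1000` design are pinned near the Fisher
information of the design — about 0.017 for `zeta` and 0.045 for `beta` at
the low-noise level, because an item requiring three attributes is mastered
by only about `N/8` examinees. Published analyses of this design report
substantially smaller MSEs, and their interval summaries show posterior
draws confined to exactly this box (HPDI endpoints pinned at -2.5, -1.0,
2.5 and 4.5). The package therefore treats the bounded space as part of
the study configuration, while the estimation functions default to the
unbounded space. Even on the box, the low-noise MSEs obtained here remain
roughly twice the smallest published figures; the information bound says
they cannot be smaller, so the package reports what it computes. The
high-noise intercept MSE and the downward bias of `beta` near the upper
bound are reproduced quantitatively.

## Classification rules

Three attribute point-estimation rules are available. `"map"` takes each
examinee's modal posterior class; it maximizes the exact-pattern rate
(CPCR) and is the package default for point estimation. `"marginal"`
thresholds each attribute's posterior mastery probability at 0.5, the
AAMA-optimal rule. The studies tabulate a third, stochastic rule
(`sampled_classification_metrics()`): the match rate of a pattern *drawn*
from the posterior, i.e. the mean posterior probability of the true class
(CPCR) and of each true attribute entry (AAMA). The published accuracy
tables are only attainable by the sampled rule — the MAP rule exceeds them
by construction (by about +0.11 CPCR under high noise) — so study 4 and
the acceptance script report the sampled rule.

## Identifiability checks

Estimation is preceded by the sufficient-and-necessary Q-matrix conditions:
completeness (the Q-matrix contains the `K x K` identity up to row
permutation), each attribute required by at least three items, and pairwise
distinct columns of the submatrix left after removing one identity row per
attribute. A failing design produces a warning, not an error: practitioners
analyze incomplete designs (the classic 15-item fraction-subtraction
Q-matrix fails completeness — attributes 2, 4 and 5 never occur alone), and
the checker reports rather than refuses. When several unit rows exist for
an attribute the lowest item index is reported, for deterministic output.

## Convergence diagnostics and summaries

`psrf()` implements the Brooks-Gelman corrected potential scale reduction
factor; chains are used whole (the studies monitor across separate chains),
with split-chain halving available but off. `psrf_trace()` uses the
cumulative convention — the statistic over the first `g` iterations — on a
default grid of 20 checkpoints, since the published trace grids are not
stated. PSRF for the simplex `pi` is per coordinate. Posterior summaries
are EAP (mean), SD, and the highest-posterior-density interval computed as
the shortest window containing `ceiling(level * n)` sorted draws, ties
broken toward the smallest lower bound.

## The synthetic-data generator

`simulate_dina()` draws classes from `pi` (flat over the `2^K` patterns by
default, the studies' setting) and responses from the conjunctive model.
The four named noise levels fix `(s, g)` at (0.1, 0.1), (0.2, 0.2),
(0.2, 0.1) and (0.1, 0.2). The generator emulates the studies' data exactly
— binary responses, a known Q-matrix, examinees exchangeable within class —
and none of real data's complications: no missingness, no polytomous items,
no Q-matrix misspecification, no within-class dependence. Passing tests
therefore certify the estimator under the model, not robustness to model
violations.

## Numerical choices

* Log-domain likelihoods throughout, with log-sum-exp for the class
  mixture; `log(1+e^z)` switches to its asymptote beyond |z| = 35.
* Probabilities are clipped to `[1e-12, 1 - 1e-12]` before logits when
  initializing from item means.
* Initial values: `zeta` from clipped item-mean logits, `beta = 1`, classes
  uniform, `pi` uniform; with several chains, starts are overdispersed by
  `N(0, 1)` jitter (absolute value for `beta`), then clamped into the
  support. Chain `c` uses seed `seed + c`; all draws, including the
  compiled sampler's, flow from R's RNG, so runs are bit-reproducible.
* Truncated-normal draws use normal rejection near the bulk and Robert's
  translated-exponential rejection in the tails, reflected for upper
  truncation; no inverse-CDF calls that would degrade in far tails.
* All-zero Q-matrix rows are rejected at validation (the ideal response
  would be identically 1, confounding `zeta_j` and `beta_j`). Constant
  response columns are allowed; the prior dominates.

## Reduced problem sizes

The published designs use 25 replications of 20 000 iterations (10 000
burn-in) with four chains. The packaged `"reduced"` scale keeps the full
structure at desk scale: 5 replications of 4 000 iterations (2 000
burn-in). Metric runs use one chain — additional chains only serve the
PSRF, which is checked in dedicated multi-chain runs. Replication `r` of a
study derives its seed as `seed * 1000 + r`, shared across conditions
(common random numbers). The prior-sensitivity study reuses the same
simulated datasets across its four prior types so that observed spread
isolates the prior's effect. The cross-sampler agreement check runs on a
shared `N = 300`, 10-item, 2-attribute dataset rather than the cluster-
scale 25-replication comparison.

## Known limitations

Only the DINA model is implemented — no DINO, rRUM or log-linear variants,
no polytomous responses, no missing data. PG(b, z) is implemented for
`b = 1` only, which is all the binary likelihood needs. MH proposal
variances are deliberately not adaptive; the baseline exists to show the
cost of tuning them. The identifiability checker verifies the stated
conditions but does not repair deficient Q-matrices.
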