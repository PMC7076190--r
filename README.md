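# dinapg

Fully Bayesian estimation of the DINA (deterministic inputs, noisy "and"
gate) cognitive-diagnosis model with a Polya-Gamma Gibbs sampler.

Cognitive-diagnosis models classify examinees over `K` binary skills
("attributes") from their answers to `J` test items; a binary `J x K`
Q-matrix says which attributes each item requires. Under DINA, an examinee
mastering every attribute item `j` requires answers correctly with
probability `1 - s_j` (slipping `s_j`), and otherwise guesses correctly
with probability `g_j`. On the logit scale,

    logit P(Y_ij = 1) = zeta_j + beta_j * eta_ij,
    zeta_j = logit(g_j),   beta_j = logit(1 - s_j) - logit(g_j) > 0,

where `eta_ij` indicates mastery of all required attributes. Augmenting
each response with a Polya-Gamma variate `W_ij ~ PG(1, |zeta_j + beta_j
eta_ij|)` makes every full conditional exact — Gaussian for `zeta`,
truncated Gaussian for `beta`, multinomial for the latent class, Dirichlet
for the class probabilities — so the sampler needs no proposal tuning and
rejects nothing. The package is aimed at psychometricians fitting
diagnostic models and at methodologists studying samplers for latent-class
logistic models.

Included besides the Gibbs sampler (`fit_pggsa()`):

* a random-walk Metropolis-Hastings baseline (`fit_mh()`) for comparison,
  with per-item acceptance-rate tracking;
* Q-matrix identifiability checks (`check_identifiability()`):
  completeness, per-attribute item counts, distinct residual columns;
* convergence diagnostics and posterior summaries: Brooks-Gelman PSRF
  (`psrf()`, `psrf_trace()`), EAP/SD/HPDI tables (`summary()` on a fit);
* a simulation engine (`simulate_dina()`, `run_study()`) with bias/MSE and
  attribute-classification metrics (CPCR and AAMA, on three point-
  estimation rules);
* an exact PG(1, z) generator (`rpg()`) written in C++;
* a thin command-line wrapper in `inst/cli/dinapg.R` with subcommands
  `fit`, `diagnose`, `simulate`, `study` and `check-q`.

## Worked example

```r
library(dinapg)

Q <- sim_qmatrix(K = 3, J = 15)          # identity blocks + mixed items
sim <- simulate_dina(N = 500, Q, s = 0.1, g = 0.1, seed = 42)

fit <- fit_pggsa(sim$Y, Q, n_iter = 4000, burn_in = 2000,
                 n_chains = 2, seed = 42)
head(summary(fit), 3)
#>   parameter       eap        sd hpdi_lower hpdi_upper
#> 1     zeta1 -2.658326 0.3826169  -3.499265  -1.980199
#> 2     zeta2 -1.965199 0.2104740  -2.377764  -1.575418
#> 3     zeta3 -2.359168 0.2599374  -2.891479  -1.860898

max(psrf_fit(fit))                       # converged below the 1.1 threshold
#> [1] 1.011646

cm <- classification_metrics(attribute_estimates(fit), sim$alpha)
unlist(cm)
#>      cpcr      aama
#> 0.8900000 0.9573333
```

The intercept EAPs sit within two posterior SDs of the generating value
`logit(0.1) = -2.197`, every PSRF is below the 1.1 convergence threshold,
and 89% of examinees have their full 3-attribute mastery pattern recovered
exactly (95.7% of individual attribute entries).

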