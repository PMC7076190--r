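#' Metropolis-Hastings proposal specification
#'
#' Random-walk proposal variances for the item parameters. Note these are
#' variances, not standard deviations: the comparison cases of interest are
#' `N(current, 0.1)` and `N(current, 1)`.
#'
#' @param var_zeta,var_beta proposal variances for the intercept and
#'   interaction random walks, both positive.
#' @return An object of class `mh_proposal`.
#' @export
mh_proposal <- function(var_zeta = 0.1, var_beta = 0.1) {
  if (var_zeta <= 0 || var_beta <= 0) stop("proposal variances must be positive")
  structure(list(var_zeta = var_zeta, var_beta = var_beta,
                 sd_zeta = sqrt(var_zeta), sd_beta = sqrt(var_beta)),
            class = "mh_proposal")
}

#' One Metropolis-Hastings update of a single item's parameters
#'
#' Reference implementation of the item-wise random-walk update used by
#' [fit_mh()]. The intercept is proposed from `N(zeta_j, var_zeta)` and
#' accepted with the usual likelihood-times-prior ratio; the interaction is
#' proposed from `N(beta_j, var_beta)` truncated to (0, Inf), so the
#' Hastings ratio carries the correction `Phi(beta_j/sd) / Phi(beta*_j/sd)`.
#'
#' @param y,eta length-`N` response and ideal-response vectors for the item.
#' @param zeta_j,beta_j current parameter values.
#' @param prior a [dina_prior()].
#' @param prop an [mh_proposal()].
#' @return List with the new `zeta`, `beta` and logical `accepted` flags.
#' @export
mh_update_item <- function(y, eta, zeta_j, beta_j, prior, prop) {
  loglik <- function(zeta, beta) {
    z <- zeta + beta * eta
    sum(y * z - ifelse(z > 35, z, log1p(exp(pmin(z, 35)))))
  }
  acc <- c(zeta = FALSE, beta = FALSE)

  zp <- rnorm(1, zeta_j, prop$sd_zeta)
  lr <- loglik(zp, beta_j) - loglik(zeta_j, beta_j) +
    (-(zp - prior$mu_zeta)^2 + (zeta_j - prior$mu_zeta)^2) / (2 * prior$var_zeta)
  if (log(runif(1)) < lr) { zeta_j <- zp; acc["zeta"] <- TRUE }

  bp <- rtnorm_pos(1, beta_j, prop$sd_beta)
  lr <- loglik(zeta_j, bp) - loglik(zeta_j, beta_j) +
    (-(bp - prior$mu_beta)^2 + (beta_j - prior$mu_beta)^2) / (2 * prior$var_beta) +
    pnorm(beta_j / prop$sd_beta, log.p = TRUE) -
    pnorm(bp / prop$sd_beta, log.p = TRUE)
  if (log(runif(1)) < lr) { beta_j <- bp; acc["beta"] <- TRUE }

  list(zeta = zeta_j, beta = beta_j, accepted = acc)
}

#' Fit the DINA model with the random-walk Metropolis-Hastings baseline
#'
#' Item parameters are updated one at a time by random-walk proposals
#' (truncated at zero for the interactions); latent classes and the
#' class-membership probabilities are then updated exactly as in the Gibbs
#' sampler, except that the class weights use the marginal Bernoulli
#' likelihood (no Polya-Gamma term). Per-item post-burn-in acceptance rates
#' are recorded in the returned fit.
#'
#' @inheritParams fit_pggsa
#' @param prop an [mh_proposal()].
#' @return A `dina_fit` object; see [fit_pggsa()]. The extra `acceptance`
#'   field holds per-item acceptance rates for `zeta` and `beta`.
#' @export
fit_mh <- function(Y, Q, prior = dina_prior(), prop = mh_proposal(),
                   n_iter = 5000, burn_in = floor(n_iter / 2), thin = 1,
                   n_chains = 2, seed = 1, check_q = TRUE) {
  Q <- validate_qmatrix(Q)
  Y <- validate_responses(Y, Q)
  .check_mcmc_settings(n_iter, burn_in, thin, n_chains)
  if (check_q) {
    rep_q <- check_identifiability(Q)
    if (!rep_q$identifiable)
      warning("Q-matrix fails the identifiability conditions; ",
              "estimates may not be identified", call. = FALSE)
  }
  eta <- ideal_response_table(Q)
  chains <- lapply(seq_len(n_chains), function(ch) {
    set.seed(seed + ch)
    st <- .init_state(Y, nrow(eta), jitter = n_chains > 1, prior = prior)
    .mh_chain_cpp(Y, eta, prior$mu_zeta, prior$var_zeta,
                  prior$mu_beta, prior$var_beta, prior$delta0,
                  prior$zeta_bounds[1], prior$zeta_bounds[2],
                  prior$beta_bounds[1], prior$beta_bounds[2],
                  prop$sd_zeta, prop$sd_beta,
                  as.integer(n_iter), as.integer(burn_in), as.integer(thin),
                  st$zeta, st$beta, st$cls - 1L, st$pi)
  })
  settings <- list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                   n_chains = n_chains, seed = seed, prior = prior, prop = prop)
  .assemble_fit(chains, Y, Q, eta, settings, sampler = "mh")
}
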