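#' Draw Polya-Gamma PG(1, z) random variates
#'
#' Exact draws via the alternating-series rejection sampler on the Jacobi
#' density (inverse-Gaussian / exponential proposal mixture). The
#' distribution depends on `z` only through `|z|`; `E[PG(1, z)] =
#' tanh(z/2) / (2 z)`, with limit 1/4 at `z = 0`.
#'
#' @param n number of draws.
#' @param z tilting parameter(s), recycled to length `n`; must be finite.
#' @return Numeric vector of `n` strictly positive draws.
#' @examples
#' set.seed(1)
#' mean(rpg(1e4, 2))  # about tanh(1)/4 = 0.1904
#' @export
rpg <- function(n, z = 0) {
  if (any(!is.finite(z))) stop("z must be finite")
  .rpg_cpp(as.integer(n), as.numeric(z))
}

#' Draw from a normal distribution truncated to the positive half-line
#'
#' @param n number of draws.
#' @param mean,sd parameters of the untruncated normal, recycled.
#' @return Numeric vector of strictly positive draws.
#' @export
rtnorm_pos <- function(n, mean = 0, sd = 1) {
  if (any(sd <= 0)) stop("sd must be positive")
  .rtnorm_interval_cpp(as.integer(n), as.numeric(mean), as.numeric(sd), 0, Inf)
}

#' Prior specification for the reparameterized DINA model
#'
#' Normal prior on each intercept `zeta_j`, positive-truncated normal on
#' each interaction `beta_j`, and a symmetric Dirichlet(`delta0`) on the
#' class-membership probabilities. The defaults are non-informative
#' (variance 1e5, `delta0 = 1`).
#'
#' @param mu_zeta,var_zeta prior mean and variance of the intercepts.
#' @param mu_beta,var_beta prior mean and variance (before truncation) of
#'   the interactions.
#' @param delta0 Dirichlet concentration for the class probabilities.
#' @param zeta_bounds,beta_bounds support intervals for the item parameters.
#'   By default `zeta` is unrestricted and `beta` is confined to (0, Inf),
#'   the monotonicity/identification restriction. Narrower intervals
#'   restrict every conditional draw to the interval (interval-truncated
#'   normal priors); the simulation studies use such a bounded parameter
#'   space, see [run_study()].
#' @return An object of class `dina_prior`.
#' @export
dina_prior <- function(mu_zeta = 0, var_zeta = 1e5,
                       mu_beta = 0, var_beta = 1e5, delta0 = 1,
                       zeta_bounds = c(-Inf, Inf), beta_bounds = c(0, Inf)) {
  if (var_zeta <= 0 || var_beta <= 0 || delta0 <= 0)
    stop("var_zeta, var_beta and delta0 must be positive")
  if (length(zeta_bounds) != 2 || length(beta_bounds) != 2 ||
      zeta_bounds[1] >= zeta_bounds[2] || beta_bounds[1] >= beta_bounds[2])
    stop("bounds must be increasing length-2 vectors")
  if (beta_bounds[1] < 0)
    stop("beta_bounds must lie within (0, Inf): beta > 0 is the identification restriction")
  structure(list(mu_zeta = mu_zeta, var_zeta = var_zeta,
                 mu_beta = mu_beta, var_beta = var_beta, delta0 = delta0,
                 zeta_bounds = as.numeric(zeta_bounds),
                 beta_bounds = as.numeric(beta_bounds)),
            class = "dina_prior")
}

# ---- single-site reference updates -----------------------------------------
# These are the readable one-step conditionals of the Gibbs cycle, exposed
# for scrutiny and testing; the production chain runs the same updates in
# compiled code.

#' Refresh the Polya-Gamma auxiliaries
#'
#' Draws `W_ij ~ PG(1, |zeta_j + beta_j * eta_ij|)` for every cell, where
#' `eta_ij` is the current ideal response of examinee `i` to item `j`.
#'
#' @param zeta,beta item parameter vectors of length `J`.
#' @param eta `N x J` binary matrix of current ideal responses.
#' @return An `N x J` matrix of positive auxiliaries.
#' @export
update_W <- function(zeta, beta, eta) {
  N <- nrow(eta); J <- ncol(eta)
  Z <- matrix(zeta, N, J, byrow = TRUE) + matrix(beta, N, J, byrow = TRUE) * eta
  matrix(rpg(N * J, as.numeric(Z)), N, J)
}

#' Gibbs update of one item intercept
#'
#' Draws `zeta_j` from its Gaussian full conditional with variance
#' `V = 1 / (1/var_zeta + sum(w))` and mean
#' `V * (mu_zeta/var_zeta + sum(y - 1/2 - w * beta_j * eta))`.
#'
#' @param y,w,eta length-`N` response, auxiliary and ideal-response vectors
#'   for the item (may be length 0, in which case the prior is drawn from).
#' @param beta_j current interaction value.
#' @param prior a [dina_prior()].
#' @return One draw of `zeta_j`.
#' @export
update_zeta <- function(y, w, eta, beta_j, prior) {
  V <- 1 / (1 / prior$var_zeta + sum(w))
  m <- V * (prior$mu_zeta / prior$var_zeta + sum((y - 0.5) - w * beta_j * eta))
  stopifnot(V > 0)
  .rtnorm_interval_cpp(1L, m, sqrt(V), prior$zeta_bounds[1], prior$zeta_bounds[2])
}

#' Gibbs update of one item interaction
#'
#' Draws `beta_j` from its positive-truncated Gaussian full conditional with
#' variance `V = 1 / (1/var_beta + sum(eta * w))` and mean
#' `V * (mu_beta/var_beta + sum(eta * (y - 1/2 - w * zeta_j)))` (eta^2 = eta
#' since eta is binary).
#'
#' @inheritParams update_zeta
#' @param zeta_j current intercept value.
#' @return One strictly positive draw of `beta_j`.
#' @export
update_beta <- function(y, w, eta, zeta_j, prior) {
  V <- 1 / (1 / prior$var_beta + sum(eta * w))
  m <- V * (prior$mu_beta / prior$var_beta + sum(eta * ((y - 0.5) - w * zeta_j)))
  .rtnorm_interval_cpp(1L, m, sqrt(V), prior$beta_bounds[1], prior$beta_bounds[2])
}

#' Unnormalized log class weights for one examinee
#'
#' The multinomial step's weights are proportional to
#' `pi_c * p(Y_i | class c) * f(W_i | class c)`. Because the base PG(1, 0)
#' density cancels in normalization and
#' `exp(y z) / (1 + e^z) * cosh(z/2) = exp((y - 1/2) z) / 2`, the log weight
#' reduces to `log pi_c + sum_j [(y_ij - 1/2) z_jc - w_ij z_jc^2 / 2]` with
#' `z_jc = zeta_j + beta_j * eta_cj`, up to a class-independent constant.
#'
#' @param y,w length-`J` response and auxiliary vectors for the examinee.
#' @param zeta,beta item parameter vectors.
#' @param eta_table `C x J` ideal-response table from [ideal_response_table()].
#' @param pi class-membership probabilities.
#' @return Length-`C` vector of unnormalized log weights.
#' @export
class_log_weights <- function(y, w, zeta, beta, eta_table, pi) {
  Z <- matrix(zeta, nrow(eta_table), length(zeta), byrow = TRUE) +
    matrix(beta, nrow(eta_table), length(beta), byrow = TRUE) * eta_table
  log(pi) + as.numeric(Z %*% (y - 0.5)) - 0.5 * as.numeric(Z^2 %*% w)
}

#' Draw a latent class index from log weights
#'
#' @param log_weights finite (or `-Inf`) unnormalized log weights.
#' @return A single class index in `1..length(log_weights)`.
#' @export
update_alpha <- function(log_weights) {
  m <- max(log_weights)
  if (!is.finite(m)) stop("degenerate class weights: all -Inf")
  p <- exp(log_weights - m)
  sample.int(length(p), 1L, prob = p)
}

#' Dirichlet update of the class-membership probabilities
#'
#' Draws `pi ~ Dirichlet(delta0 + n_1, ..., delta0 + n_C)` where `n_c`
#' counts the examinees currently assigned to class `c`.
#'
#' @param class_index length-`N` vector of class assignments in `1..C`.
#' @param C number of latent classes.
#' @param delta0 Dirichlet prior concentration.
#' @return A probability vector of length `C`.
#' @export
update_pi <- function(class_index, C, delta0 = 1) {
  if (length(class_index) && (any(class_index < 1) || any(class_index > C)))
    stop("class_index out of range")
  n_c <- tabulate(class_index, nbins = C)
  gam <- rgamma(C, shape = delta0 + n_c, rate = 1)
  gam / sum(gam)
}

# ---- full sampler -----------------------------------------------------------

.init_state <- function(Y, C, jitter, prior) {
  N <- nrow(Y); J <- ncol(Y)
  pbar <- pmin(pmax(colMeans(Y), 1e-12), 1 - 1e-12)
  zeta <- qlogis(pmin(pmax(pbar, 0.05), 0.95))
  beta <- rep(1, J)
  if (jitter) {
    zeta <- zeta + rnorm(J)
    beta <- abs(beta + rnorm(J))
    beta <- pmax(beta, 0.05)
  }
  # keep starting values inside the parameter support
  eps <- 1e-3
  zlo <- prior$zeta_bounds[1]; zhi <- prior$zeta_bounds[2]
  blo <- prior$beta_bounds[1]; bhi <- prior$beta_bounds[2]
  zeta <- pmin(pmax(zeta, if (is.finite(zlo)) zlo + eps else zlo), 
               if (is.finite(zhi)) zhi - eps else zhi)
  beta <- pmin(pmax(beta, if (is.finite(blo)) blo + eps else eps),
               if (is.finite(bhi)) bhi - eps else bhi)
  list(zeta = zeta, beta = beta,
       cls = sample.int(C, N, replace = TRUE),
       pi = rep(1 / C, C))
}

.assemble_fit <- function(chains, Y, Q, eta, settings, sampler) {
  N <- nrow(Y); C <- nrow(eta)
  counts <- Reduce(`+`, lapply(chains, `[[`, "class_counts"))
  class_probs <- counts / rowSums(counts)
  patterns <- attribute_patterns(ncol(Q))
  colnames(class_probs) <- apply(patterns, 1, paste, collapse = "")
  draws <- lapply(chains, function(ch) {
    colnames(ch$zeta) <- paste0("zeta", seq_len(ncol(ch$zeta)))
    colnames(ch$beta) <- paste0("beta", seq_len(ncol(ch$beta)))
    colnames(ch$pi) <- paste0("pi", seq_len(ncol(ch$pi)))
    ch[c("zeta", "beta", "pi")]
  })
  out <- list(draws = draws, class_probs = class_probs, Q = Q,
              patterns = patterns, settings = settings, sampler = sampler)
  if (!is.null(chains[[1]]$accept_zeta)) {
    acc <- function(field)
      rowMeans(matrix(vapply(chains, `[[`, numeric(ncol(Y)), field),
                      nrow = ncol(Y)))
    out$acceptance <- list(zeta = acc("accept_zeta"), beta = acc("accept_beta"))
  }
  class(out) <- "dina_fit"
  out
}

.check_mcmc_settings <- function(n_iter, burn_in, thin, n_chains) {
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in")
  if (thin < 1 || (n_iter - burn_in) < thin) stop("invalid thinning interval")
  if (n_chains < 1) stop("n_chains must be at least 1")
}

#' Fit the DINA model with the Polya-Gamma Gibbs sampler
#'
#' Each iteration performs, in order: (1) a fresh Polya-Gamma auxiliary
#' `W_ij ~ PG(1, |zeta_j + beta_j eta_ij|)` for every cell; (2) a Gaussian
#' draw of every intercept `zeta_j`; (3) a positive-truncated Gaussian draw
#' of every interaction `beta_j`; (4) a multinomial draw of every examinee's
#' latent attribute class; (5) a Dirichlet draw of the class-membership
#' probabilities `pi`. Every conditional is sampled exactly, so no proposal
#' tuning is needed. Chains start from overdispersed values (item-mean logit
#' intercepts and unit interactions, jittered across chains) and chain `c`
#' uses RNG seed `seed + c`.
#'
#' @param Y binary response matrix, `N` examinees by `J` items.
#' @param Q binary `J x K` Q-matrix. If it fails the identifiability
#'   conditions a warning is issued and estimation proceeds.
#' @param prior a [dina_prior()].
#' @param n_iter total iterations per chain.
#' @param burn_in iterations discarded from the start of each chain.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param n_chains number of independent chains.
#' @param seed integer seed; all randomness derives from it.
#' @param check_q set `FALSE` to skip the identifiability warning.
#' @return A `dina_fit` object: per-chain draws of `zeta`, `beta` and `pi`,
#'   a pooled `N x C` posterior class-membership matrix (`class_probs`), the
#'   Q-matrix, pattern table and settings.
#' @examples
#' sim <- simulate_dina(N = 150, Q = sim_qmatrix(K = 2, J = 6), s = 0.1, g = 0.1,
#'                      seed = 7)
#' fit <- fit_pggsa(sim$Y, sim$Q, n_iter = 400, burn_in = 200, seed = 7)
#' head(summary(fit))
#' @export
fit_pggsa <- function(Y, Q, prior = dina_prior(), n_iter = 5000,
                      burn_in = floor(n_iter / 2), thin = 1, n_chains = 2,
                      seed = 1, check_q = TRUE) {
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
    .pggsa_chain_cpp(Y, eta, prior$mu_zeta, prior$var_zeta,
                     prior$mu_beta, prior$var_beta, prior$delta0,
                     prior$zeta_bounds[1], prior$zeta_bounds[2],
                     prior$beta_bounds[1], prior$beta_bounds[2],
                     as.integer(n_iter), as.integer(burn_in), as.integer(thin),
                     st$zeta, st$beta, st$cls - 1L, st$pi)
  })
  settings <- list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                   n_chains = n_chains, seed = seed, prior = prior)
  .assemble_fit(chains, Y, Q, eta, settings, sampler = "pggsa")
}

#' @export
print.dina_fit <- function(x, ...) {
  s <- x$settings
  cat("DINA model fit (", if (x$sampler == "pggsa") "Polya-Gamma Gibbs"
      else "Metropolis-Hastings", ")\n", sep = "")
  cat("  items: ", nrow(x$Q), "  attributes: ", ncol(x$Q),
      "  classes: ", nrow(x$patterns), "\n", sep = "")
  cat("  chains: ", s$n_chains, "  iterations: ", s$n_iter,
      " (burn-in ", s$burn_in, ", thin ", s$thin, ")\n", sep = "")
  if (!is.null(x$acceptance))
    cat("  mean acceptance: zeta ", round(mean(x$acceptance$zeta), 3),
        ", beta ", round(mean(x$acceptance$beta), 3), "\n", sep = "")
  invisible(x)
}
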