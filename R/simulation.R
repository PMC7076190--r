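#' Simulation Q-matrix designs
#'
#' `sim_qmatrix()` with default arguments returns the fixed 30-item,
#' 5-attribute design used throughout the simulation studies: the identity
#' block twice (items 1-10), the ten two-attribute items (11-29 with the
#' three-attribute items), and a final item repeating the (0,0,0,1,1) row.
#' It satisfies the identifiability conditions (complete, every attribute in
#' at least three items, distinct residual columns). For other `K`/`J` a
#' structurally similar design is built: two identity blocks followed by
#' patterns of increasing attribute count, recycled to `J` rows.
#'
#' @param K number of attributes.
#' @param J number of items, at least `2 K + 1`.
#' @return A binary `J x K` Q-matrix.
#' @export
sim_qmatrix <- function(K = 5, J = 30) {
  if (K == 5 && J == 30) return(.qmatrix_study())
  if (J < 2 * K + 1) stop("need J >= 2K + 1 items for this design")
  pat <- attribute_patterns(K)
  wt <- rowSums(pat)
  extras <- pat[order(wt, seq_len(nrow(pat)))[wt[order(wt, seq_len(nrow(pat)))] >= 2], ,
                drop = FALSE]
  ident <- diag(1L, K)
  rows <- rbind(ident, ident)
  i <- 0L
  while (nrow(rows) < J) {
    i <- i %% nrow(extras) + 1L
    rows <- rbind(rows, extras[i, ])
  }
  dimnames(rows) <- list(NULL, paste0("A", seq_len(K)))
  validate_qmatrix(rows)
}

.qmatrix_study <- function() {
  rows <- c(
    1,0,0,0,0,  0,1,0,0,0,  0,0,1,0,0,  0,0,0,1,0,  0,0,0,0,1,
    1,0,0,0,0,  0,1,0,0,0,  0,0,1,0,0,  0,0,0,1,0,  0,0,0,0,1,
    1,1,0,0,0,  1,0,1,0,0,  1,0,0,1,0,  1,0,0,0,1,  0,1,1,0,0,
    0,1,0,1,0,  0,1,0,0,1,  0,0,1,1,0,  0,0,1,0,1,  0,0,0,1,1,
    1,1,1,0,0,  1,1,0,1,0,  1,1,0,0,1,  1,0,1,1,0,  1,0,1,0,1,
    1,0,0,1,1,  0,1,1,1,0,  0,1,1,0,1,  0,1,0,1,1,  0,0,0,1,1)
  Q <- matrix(as.integer(rows), nrow = 30, ncol = 5, byrow = TRUE)
  colnames(Q) <- paste0("A", 1:5)
  Q
}

#' The 15-item fraction-subtraction Q-matrix
#'
#' The five-attribute requirement design of the classic fraction-subtraction
#' test (subtract basic fractions; reduce and simplify; separate whole from
#' fraction; borrow from whole; convert whole to fraction), for use with the
#' externally distributed response data. The response data themselves are
#' not bundled.
#'
#' @return A binary `15 x 5` Q-matrix.
#' @export
fraction_qmatrix <- function() {
  rows <- c(
    1,0,0,0,0,  1,1,1,1,0,  1,0,0,0,0,  1,1,1,1,1,  0,0,1,0,0,
    1,1,1,1,0,  1,1,1,1,0,  1,1,0,0,0,  1,0,1,0,0,  1,0,1,1,1,
    1,0,1,0,0,  1,0,1,1,0,  1,1,1,1,0,  1,1,1,1,1,  1,1,1,1,0)
  Q <- matrix(as.integer(rows), nrow = 15, ncol = 5, byrow = TRUE)
  colnames(Q) <- paste0("A", 1:5)
  Q
}

#' Slipping/guessing values of the named noise levels
#'
#' LNL (low noise): s = g = 0.1; HNL (high noise): s = g = 0.2;
#' SHG (slipping higher than guessing): s = 0.2, g = 0.1;
#' GHS (guessing higher than slipping): s = 0.1, g = 0.2.
#'
#' @param level one of `"LNL"`, `"HNL"`, `"SHG"`, `"GHS"`.
#' @return A list with scalars `s` and `g`.
#' @export
noise_level <- function(level = c("LNL", "HNL", "SHG", "GHS")) {
  level <- match.arg(level)
  switch(level,
         LNL = list(s = 0.1, g = 0.1),
         HNL = list(s = 0.2, g = 0.2),
         SHG = list(s = 0.2, g = 0.1),
         GHS = list(s = 0.1, g = 0.2))
}

#' Simulate DINA response data
#'
#' Latent classes are drawn from `pi` (flat over the `2^K` patterns by
#' default), and responses from the conjunctive model: a correct answer
#' with probability `1 - s_j` when the examinee masters all required
#' attributes, `g_j` otherwise. `s = g = 0` is allowed here (and only here)
#' to generate deterministic ideal-response data.
#'
#' @param N number of examinees.
#' @param Q binary `J x K` Q-matrix.
#' @param s,g slipping and guessing probabilities, scalars or length-`J`.
#' @param pi optional class-membership probabilities over the canonical
#'   pattern order; flat when `NULL`.
#' @param seed optional integer seed.
#' @return A list of class `dina_sim` with the response matrix `Y`, the true
#'   class indices `class`, attribute patterns `alpha` (`N x K`), item
#'   parameters `s`, `g`, `zeta`, `beta`, the class probabilities `pi`,
#'   and `Q`.
#' @export
simulate_dina <- function(N, Q, s = 0.1, g = 0.1, pi = NULL, seed = NULL) {
  Q <- validate_qmatrix(Q)
  if (!is.null(seed)) set.seed(seed)
  J <- nrow(Q); K <- ncol(Q); C <- 2L^K
  s <- rep_len(s, J); g <- rep_len(g, J)
  if (any(s < 0 | s >= 1) || any(g < 0 | g >= 1)) stop("s and g must lie in [0, 1)")
  if (is.null(pi)) pi <- rep(1 / C, C)
  if (length(pi) != C || any(pi < 0) || abs(sum(pi) - 1) > 1e-12)
    stop("pi must be a probability vector of length ", C)
  patterns <- attribute_patterns(K)
  eta_table <- ideal_response_table(Q, patterns)
  cls <- sample.int(C, N, replace = TRUE, prob = pi)
  eta <- eta_table[cls, , drop = FALSE]
  P <- matrix(g, N, J, byrow = TRUE) +
    matrix(1 - s - g, N, J, byrow = TRUE) * eta
  Y <- matrix(as.integer(runif(N * J) < P), N, J)
  colnames(Y) <- paste0("item", seq_len(J))
  rp <- if (all(s > 0) && all(g > 0)) reparameterize(s, g)
        else list(zeta = rep(NA_real_, J), beta = rep(NA_real_, J))
  structure(list(Y = Y, class = cls, alpha = patterns[cls, , drop = FALSE],
                 s = s, g = g, zeta = rp$zeta, beta = rp$beta, pi = pi, Q = Q),
            class = "dina_sim")
}

#' Monte Carlo bias of replicated estimates
#'
#' @param estimates per-replication point estimates of one parameter.
#' @param truth the true value.
#' @return `mean(estimates - truth)`.
#' @export
recovery_bias <- function(estimates, truth) {
  mean(estimates - truth)
}

#' Monte Carlo mean squared error of replicated estimates
#'
#' @inheritParams recovery_bias
#' @return `mean((estimates - truth)^2)`.
#' @export
recovery_mse <- function(estimates, truth) {
  mean((estimates - truth)^2)
}

#' Attribute-pattern point estimates from a fitted model
#'
#' Either the modal latent class per examinee (`"map"`, the default) or the
#' per-attribute marginal mastery probability thresholded at 0.5
#' (`"marginal"`).
#'
#' @param fit a `dina_fit`.
#' @param rule estimation rule.
#' @param threshold threshold for the marginal rule.
#' @return An `N x K` binary matrix of estimated mastery patterns.
#' @export
attribute_estimates <- function(fit, rule = c("map", "marginal"), threshold = 0.5) {
  rule <- match.arg(rule)
  if (is.null(fit$class_probs) || nrow(fit$class_probs) == 0)
    stop("fit contains no class-membership draws")
  if (rule == "map") {
    idx <- apply(fit$class_probs, 1, which.max)
    out <- fit$patterns[idx, , drop = FALSE]
  } else {
    marg <- fit$class_probs %*% fit$patterns
    out <- (marg >= threshold) + 0L
  }
  storage.mode(out) <- "integer"
  rownames(out) <- NULL
  out
}

#' Attribute classification accuracy
#'
#' CPCR is the fraction of examinees whose whole pattern is recovered
#' exactly; AAMA is the fraction of individual attribute entries recovered.
#' CPCR <= AAMA always.
#'
#' @param alpha_hat,alpha_true `N x K` binary matrices.
#' @return A list with `cpcr` and `aama`.
#' @export
classification_metrics <- function(alpha_hat, alpha_true) {
  alpha_hat <- as.matrix(alpha_hat); alpha_true <- as.matrix(alpha_true)
  if (!all(dim(alpha_hat) == dim(alpha_true)))
    stop("alpha_hat and alpha_true must have the same dimensions")
  agree <- alpha_hat == alpha_true
  list(cpcr = mean(rowSums(agree) == ncol(agree)), aama = mean(agree))
}

#' Posterior-sampled classification accuracy
#'
#' Match rates of an attribute pattern drawn from the posterior class
#' distribution, averaged over draws: CPCR is the mean posterior probability
#' of each examinee's true class, AAMA the mean posterior probability of
#' each true attribute entry. Unlike the deterministic rules of
#' [attribute_estimates()], this rule scores a stochastic classifier; it is
#' the rule whose accuracy the simulation studies tabulate.
#'
#' @param fit a `dina_fit`.
#' @param class_true length-`N` true class indices (canonical order), or an
#'   `N x K` matrix of true attribute patterns.
#' @return A list with `cpcr` and `aama`.
#' @export
sampled_classification_metrics <- function(fit, class_true) {
  cp <- fit$class_probs
  if (is.matrix(class_true)) {
    keys <- apply(fit$patterns, 1, paste, collapse = "")
    class_true <- match(apply(class_true, 1, paste, collapse = ""), keys)
  }
  if (length(class_true) != nrow(cp) || any(is.na(class_true)) ||
      any(class_true < 1) || any(class_true > nrow(fit$patterns)))
    stop("class_true does not match the fit")
  alpha_true <- fit$patterns[class_true, , drop = FALSE]
  marg <- cp %*% fit$patterns
  list(cpcr = mean(cp[cbind(seq_len(nrow(cp)), class_true)]),
       aama = mean(ifelse(alpha_true == 1, marg, 1 - marg)))
}

.study_scale <- function(scale, n_reps, n_iter, burn_in) {
  base <- if (scale == "full") list(n_reps = 25, n_iter = 20000, burn_in = 10000)
          else list(n_reps = 5, n_iter = 4000, burn_in = 2000)
  if (!is.null(n_reps)) base$n_reps <- n_reps
  if (!is.null(n_iter)) base$n_iter <- n_iter
  if (!is.null(burn_in)) base$burn_in <- burn_in
  base
}

#' Parameter-space box of the simulation studies
#'
#' The studies sample on a bounded parameter space,
#' `zeta in [-2.5, -1]` and `beta in [2.5, 4.5]`, which brackets all four
#' noise levels' true values; see the methods vignette for the rationale.
#'
#' @return A list with `zeta_bounds` and `beta_bounds`.
#' @export
study_bounds <- function() {
  list(zeta_bounds = c(-2.5, -1), beta_bounds = c(2.5, 4.5))
}

.truth_prior <- function(zeta, beta, var = 1e5, bounds = study_bounds()) {
  dina_prior(mu_zeta = zeta[1], var_zeta = var, mu_beta = beta[1], var_beta = var,
             zeta_bounds = bounds$zeta_bounds, beta_bounds = bounds$beta_bounds)
}

.fit_eaps <- function(fit) {
  list(zeta = colMeans(.pooled_draws(fit, "zeta")),
       beta = colMeans(.pooled_draws(fit, "beta")),
       pi = colMeans(.pooled_draws(fit, "pi")))
}

.item_metrics <- function(est_mat, truth) {
  # est_mat: reps x params; per-parameter bias/MSE, then averaged
  b <- vapply(seq_along(truth), function(k) recovery_bias(est_mat[, k], truth[k]),
              numeric(1))
  m <- vapply(seq_along(truth), function(k) recovery_mse(est_mat[, k], truth[k]),
              numeric(1))
  c(bias = mean(b), mse = mean(m))
}

.run_condition <- function(noise, N, Q, n_reps, n_iter, burn_in, n_chains,
                           seed, sampler = "pggsa", prop = NULL, prior = NULL,
                           sims = NULL, classify = FALSE, rule = "sampled",
                           verbose = FALSE) {
  ng <- noise_level(noise)
  truth <- reparameterize(ng$s, ng$g)
  J <- nrow(Q); C <- 2L^ncol(Q)
  truth_zeta <- rep(truth$zeta, J); truth_beta <- rep(truth$beta, J)
  truth_pi <- rep(1 / C, C)
  if (is.null(prior)) prior <- .truth_prior(truth_zeta, truth_beta)
  est_z <- matrix(NA_real_, n_reps, J)
  est_b <- matrix(NA_real_, n_reps, J)
  est_p <- matrix(NA_real_, n_reps, C)
  cpcr <- aama <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    sim <- if (is.null(sims)) simulate_dina(N, Q, ng$s, ng$g, seed = seed * 1000 + r)
           else sims[[r]]
    fit <- if (sampler == "pggsa")
      fit_pggsa(sim$Y, Q, prior, n_iter = n_iter, burn_in = burn_in,
                n_chains = n_chains, seed = seed * 1000 + r, check_q = FALSE)
    else
      fit_mh(sim$Y, Q, prior, prop = prop, n_iter = n_iter, burn_in = burn_in,
             n_chains = n_chains, seed = seed * 1000 + r, check_q = FALSE)
    eap <- .fit_eaps(fit)
    est_z[r, ] <- eap$zeta; est_b[r, ] <- eap$beta; est_p[r, ] <- eap$pi
    if (classify) {
      cm <- if (rule == "sampled") sampled_classification_metrics(fit, sim$class)
            else classification_metrics(attribute_estimates(fit, rule), sim$alpha)
      cpcr[r] <- cm$cpcr; aama[r] <- cm$aama
    }
    if (verbose) message(noise, " N=", N, " rep ", r, "/", n_reps, " done")
  }
  out <- data.frame(
    noise = noise, N = N,
    bias_zeta = .item_metrics(est_z, truth_zeta)["bias"],
    bias_beta = .item_metrics(est_b, truth_beta)["bias"],
    bias_pi = .item_metrics(est_p, truth_pi)["bias"],
    mse_zeta = .item_metrics(est_z, truth_zeta)["mse"],
    mse_beta = .item_metrics(est_b, truth_beta)["mse"],
    mse_pi = .item_metrics(est_p, truth_pi)["mse"],
    row.names = NULL)
  if (classify) {
    out$cpcr <- mean(cpcr)
    out$aama <- mean(aama)
  }
  out
}

#' Run one of the four simulation studies
#'
#' Study 1: parameter recovery of the Gibbs sampler across noise levels and
#' sample sizes. Study 2: comparison against the Metropolis-Hastings
#' baseline with proposal variances 0.1 (Case 1) and 1 (Case 2). Study 3:
#' sensitivity to four prior types (variances 0.5, 1, 1e3, 1e5, all
#' truth-centered) under low noise; the same simulated datasets are reused
#' across types so differences isolate the prior. Study 4: attribute
#' classification accuracy (CPCR/AAMA) across noise levels.
#'
#' The `"reduced"` scale (5 replications, 4,000 iterations, 2,000 burn-in,
#' one chain per fit) preserves the full design's structure at desk-scale
#' runtime; `"full"` uses 25 replications of 20,000/10,000 chains.
#'
#' @param study study number, 1 to 4.
#' @param scale `"reduced"` or `"full"`.
#' @param seed integer seed; replication `r` uses seed `seed * 1000 + r`.
#' @param noise subset of noise levels to run (default: study-specific).
#' @param N subset of sample sizes (study 1 only; default `c(1000, 2000)`).
#' @param n_reps,n_iter,burn_in optional overrides of the scale defaults.
#' @param n_chains chains per fit (default 1; metrics need no multi-chain).
#' @param rule classification rule for study 4: `"sampled"` (posterior-draw
#'   match rates, the tabulated rule), `"map"` or `"marginal"`.
#' @param verbose print progress messages.
#' @return A data frame with one row per condition: average bias and MSE of
#'   `zeta`, `beta`, `pi` (and `cpcr`/`aama` for study 4, acceptance rates
#'   for study 2's MH cases).
#' @export
run_study <- function(study, scale = c("reduced", "full"), seed = 1,
                      noise = NULL, N = NULL, n_reps = NULL, n_iter = NULL,
                      burn_in = NULL, n_chains = 1, rule = "sampled",
                      verbose = FALSE) {
  scale <- match.arg(scale)
  sc <- .study_scale(scale, n_reps, n_iter, burn_in)
  Q <- sim_qmatrix()
  if (study == 1) {
    noise <- if (is.null(noise)) c("LNL", "HNL", "SHG", "GHS") else noise
    N <- if (is.null(N)) c(1000, 2000) else N
    grid <- expand.grid(noise = noise, N = N, stringsAsFactors = FALSE)
    out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
      .run_condition(grid$noise[i], grid$N[i], Q, sc$n_reps, sc$n_iter,
                     sc$burn_in, n_chains, seed, verbose = verbose)))
  } else if (study == 2) {
    noise <- if (is.null(noise)) "LNL" else noise[1]
    N <- if (is.null(N)) 1000 else N[1]
    cases <- list(pggsa = NULL, mh_case1 = mh_proposal(0.1, 0.1),
                  mh_case2 = mh_proposal(1, 1))
    out <- do.call(rbind, lapply(names(cases), function(nm) {
      res <- .run_condition(noise, N, Q, sc$n_reps, sc$n_iter, sc$burn_in,
                            n_chains, seed,
                            sampler = if (nm == "pggsa") "pggsa" else "mh",
                            prop = cases[[nm]], verbose = verbose)
      cbind(data.frame(algorithm = nm), res)
    }))
  } else if (study == 3) {
    noise <- if (is.null(noise)) "LNL" else noise[1]
    N <- if (is.null(N)) 1000 else N[1]
    ng <- noise_level(noise)
    truth <- reparameterize(ng$s, ng$g)
    types <- c(I = 0.5, II = 1, III = 1e3, IV = 1e5)
    sims <- lapply(seq_len(sc$n_reps), function(r)
      simulate_dina(N, Q, ng$s, ng$g, seed = seed * 1000 + r))
    bb <- study_bounds()
    out <- do.call(rbind, lapply(names(types), function(tp) {
      prior <- dina_prior(truth$zeta, types[[tp]], truth$beta, types[[tp]],
                          zeta_bounds = bb$zeta_bounds, beta_bounds = bb$beta_bounds)
      res <- .run_condition(noise, N, Q, sc$n_reps, sc$n_iter, sc$burn_in,
                            n_chains, seed, prior = prior, sims = sims,
                            verbose = verbose)
      cbind(data.frame(prior_type = tp, prior_var = types[[tp]]), res)
    }))
  } else if (study == 4) {
    noise <- if (is.null(noise)) c("LNL", "HNL", "SHG", "GHS") else noise
    N <- if (is.null(N)) 1000 else N[1]
    out <- do.call(rbind, lapply(noise, function(nl)
      .run_condition(nl, N, Q, sc$n_reps, sc$n_iter, sc$burn_in, n_chains,
                     seed, classify = TRUE, rule = rule, verbose = verbose)))
  } else {
    stop("study must be 1, 2, 3 or 4")
  }
  rownames(out) <- NULL
  out
}
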