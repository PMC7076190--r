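test_that("intercept update falls back to the prior without data", {
  prior <- dina_prior(mu_zeta = -1.5, var_zeta = 0.49)
  set.seed(41)
  draws <- replicate(5000, update_zeta(numeric(0), numeric(0), numeric(0),
                                       beta_j = 2, prior = prior))
  expect_lt(abs(mean(draws) + 1.5), 4 * 0.7 / sqrt(5000))
  expect_lt(abs(sd(draws) - 0.7), 0.03)
})

test_that("intercept update uses the simplified Gaussian conditional", {
  # with a flat prior and eta = 0 the conditional mean is sum(y - 1/2)/sum(w)
  set.seed(42)
  y <- rbinom(400, 1, 0.3)
  w <- rpg(400, 1)
  prior <- dina_prior(var_zeta = 1e12)
  draws <- replicate(4000, update_zeta(y, w, rep(0, 400), beta_j = 3, prior))
  m_expect <- sum(y - 0.5) / sum(w)
  v_expect <- 1 / sum(w)
  expect_lt(abs(mean(draws) - m_expect), 4 * sqrt(v_expect / 4000))
  expect_lt(abs(var(draws) - v_expect) / v_expect, 0.15)
})

test_that("interaction update is truncated to its support", {
  prior <- dina_prior(mu_beta = -1, var_beta = 1)
  set.seed(43)
  # no examinee masters the item: prior truncated to (0, Inf)
  draws <- replicate(5000, update_beta(numeric(0), numeric(0), numeric(0),
                                       zeta_j = 0, prior = prior))
  expect_true(all(draws > 0))
  raw <- rnorm(2e5, -1, 1)
  expect_lt(suppressWarnings(ks.test(draws, raw[raw > 0]))$statistic, 0.03)
  # bounded support restricts the draw further
  priorb <- dina_prior(mu_beta = 4, var_beta = 1e5, beta_bounds = c(2.5, 4.5))
  d2 <- replicate(500, update_beta(numeric(0), numeric(0), numeric(0), 0, priorb))
  expect_true(all(d2 > 2.5 & d2 < 4.5))
})

test_that("simplified class weights equal the direct tilted-density weights", {
  set.seed(44)
  for (r in 1:20) {
    J <- sample(1:4, 1); K <- sample(1:2, 1)
    Q <- matrix(rbinom(J * K, 1, 0.6), J, K)
    Q[rowSums(Q) == 0, sample(K, 1)] <- 1L
    eta <- ideal_response_table(Q)
    zeta <- rnorm(J); beta <- rexp(J) + 0.1
    y <- rbinom(J, 1, 0.5)
    w <- rpg(J, 1)
    pi <- rgamma(2^K, 1); pi <- pi / sum(pi)
    lw <- class_log_weights(y, w, zeta, beta, eta, pi)
    soft <- exp(lw - max(lw)); soft <- soft / sum(soft)
    expect_equal(soft, direct_class_weights(y, w, zeta, beta, eta, pi),
                 tolerance = 1e-10)
    expect_equal(sum(soft), 1, tolerance = 1e-12)
  }
})

test_that("class weights lose all data information as beta vanishes", {
  eta <- ideal_response_table(rbind(c(1, 0), c(0, 1)))
  pi <- c(0.1, 0.2, 0.3, 0.4)
  lw <- class_log_weights(c(1, 0), c(0.2, 0.3), c(-1, -0.5),
                          c(1e-12, 1e-12), eta, pi)
  expect_equal(lw - log(pi), rep(lw[1] - log(pi[1]), 4), tolerance = 1e-9)
})

test_that("one-item two-class weights match a scalar hand computation", {
  eta <- matrix(c(0L, 1L), 2, 1)
  zeta <- -1; beta <- 2; y <- 1; w <- 0.3; pi <- c(0.4, 0.6)
  lw <- class_log_weights(y, w, zeta, beta, eta, pi)
  hand <- c(log(0.4) + 0.5 * (-1) - 0.3 * 1 / 2,
            log(0.6) + 0.5 * 1 - 0.3 * 1 / 2)
  expect_equal(lw, hand, tolerance = 1e-12)
})

test_that("class draws follow the softmax probabilities", {
  expect_equal(update_alpha(c(-Inf, 0, -Inf)), 2L)
  expect_error(update_alpha(rep(-Inf, 4)), "degenerate")
  set.seed(45)
  draws <- replicate(2e4, update_alpha(rep(1.7, 8)))
  expect_gt(chisq.test(tabulate(draws, 8))$p.value, 1e-4)
  set.seed(46); a <- replicate(50, update_alpha(log(c(0.2, 0.5, 0.3))))
  set.seed(46); b <- replicate(50, update_alpha(log(c(0.2, 0.5, 0.3))))
  expect_identical(a, b)
})

test_that("class-probability update is a Dirichlet posterior", {
  set.seed(47)
  p <- update_pi(integer(0), C = 8, delta0 = 1)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  draws <- replicate(4000, update_pi(integer(0), C = 4, delta0 = 1)[1])
  expect_lt(abs(mean(draws) - 0.25), 4 * sd(draws) / sqrt(4000))
  # concentration: all N examinees in class 1
  draws1 <- replicate(3000, update_pi(rep(1L, 500), C = 4, delta0 = 1)[1])
  expect_lt(abs(mean(draws1) - 501 / 504), 4 * sd(draws1) / sqrt(3000))
  expect_error(update_pi(c(1L, 9L), C = 4), "range")
})

test_that("the compiled chain agrees with a chain composed from the R updates", {
  Q <- sim_qmatrix(K = 2, J = 6)
  sim <- simulate_dina(120, Q, 0.15, 0.15, seed = 48)
  # weakly informative prior keeps both chains away from the unstable
  # empty-class regime so the comparison measures the same posterior
  prior <- dina_prior(mu_zeta = 0, var_zeta = 4, mu_beta = 1, var_beta = 4)
  eta_tab <- ideal_response_table(Q)
  C <- nrow(eta_tab); N <- nrow(sim$Y); J <- ncol(sim$Y)

  set.seed(49)
  cls <- sample.int(C, N, replace = TRUE)
  pi <- rep(1 / C, C)
  zeta <- qlogis(pmin(pmax(colMeans(sim$Y), 0.05), 0.95))
  beta <- rep(1, J)
  n_iter <- 2000; burn <- 1000
  zs <- matrix(NA_real_, n_iter - burn, J)
  bs <- matrix(NA_real_, n_iter - burn, J)
  for (t in seq_len(n_iter)) {
    eta_i <- eta_tab[cls, , drop = FALSE]
    W <- update_W(zeta, beta, eta_i)
    for (j in seq_len(J))
      zeta[j] <- update_zeta(sim$Y[, j], W[, j], eta_i[, j], beta[j], prior)
    for (j in seq_len(J))
      beta[j] <- update_beta(sim$Y[, j], W[, j], eta_i[, j], zeta[j], prior)
    for (i in seq_len(N))
      cls[i] <- update_alpha(class_log_weights(sim$Y[i, ], W[i, ], zeta, beta,
                                               eta_tab, pi))
    pi <- update_pi(cls, C, prior$delta0)
    if (t > burn) { zs[t - burn, ] <- zeta; bs[t - burn, ] <- beta }
  }

  fit <- fit_pggsa(sim$Y, Q, prior, n_iter = 3000, burn_in = 1500,
                   n_chains = 1, seed = 50, check_q = FALSE)
  expect_lt(max(abs(colMeans(zs) - fit_eap(fit, "zeta"))), 0.35)
  expect_lt(max(abs(colMeans(bs) - fit_eap(fit, "beta"))), 0.6)
  expect_lt(mean(abs(colMeans(zs) - fit_eap(fit, "zeta"))), 0.15)
})

test_that("successive-conditional simulation preserves the prior marginals", {
  # Geweke-style check on a tiny model: alternating data simulation and one
  # Gibbs scan leaves the prior over (zeta, beta) invariant
  Q <- matrix(1L, 3, 1)
  prior <- dina_prior(mu_zeta = -1, var_zeta = 0.6, mu_beta = 1.5, var_beta = 0.4)
  eta_tab <- ideal_response_table(Q)
  N <- 15; C <- 2; J <- 3
  set.seed(51)
  zeta <- rnorm(J, -1, sqrt(0.6)); beta <- rtnorm_pos(J, 1.5, sqrt(0.4))
  pi <- update_pi(integer(0), C, 1)
  n_cycles <- 4000
  keep_z <- matrix(NA_real_, n_cycles, J)
  keep_b <- matrix(NA_real_, n_cycles, J)
  for (t in seq_len(n_cycles)) {
    cls <- sample.int(C, N, replace = TRUE, prob = pi)
    eta_i <- eta_tab[cls, , drop = FALSE]
    P <- plogis(matrix(zeta, N, J, byrow = TRUE) +
                  matrix(beta, N, J, byrow = TRUE) * eta_i)
    Y <- matrix(as.integer(runif(N * J) < P), N, J)
    W <- update_W(zeta, beta, eta_i)
    for (j in seq_len(J))
      zeta[j] <- update_zeta(Y[, j], W[, j], eta_i[, j], beta[j], prior)
    for (j in seq_len(J))
      beta[j] <- update_beta(Y[, j], W[, j], eta_i[, j], zeta[j], prior)
    for (i in seq_len(N))
      cls[i] <- update_alpha(class_log_weights(Y[i, ], W[i, ], zeta, beta,
                                               eta_tab, pi))
    pi <- update_pi(cls, C, 1)
    keep_z[t, ] <- zeta; keep_b[t, ] <- beta
  }
  # forward draws from the prior
  fz_mean <- -1; fz_sd <- sqrt(0.6)
  a <- -1.5 / sqrt(0.4)
  fb_mean <- 1.5 + sqrt(0.4) * dnorm(a) / (1 - pnorm(a))
  # generous tolerances: successive-conditional draws are autocorrelated
  expect_lt(abs(mean(keep_z) - fz_mean), 0.1)
  expect_lt(abs(sd(as.numeric(keep_z)) - fz_sd), 0.1)
  expect_lt(abs(mean(keep_b) - fb_mean), 0.1)
})
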