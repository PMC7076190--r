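# Independent oracles used across the test files. These deliberately avoid
# the package's own computational paths.

# PG(1, z) by truncating the defining infinite sum of gamma variates:
# W = (1/(2 pi^2)) sum_k T_k / ((k - 1/2)^2 + z^2 / (4 pi^2)), T_k ~ Exp(1).
rpg_series <- function(n, z, terms = 250) {
  k <- seq_len(terms)
  denom <- (k - 0.5)^2 + z^2 / (4 * pi^2)
  vapply(seq_len(n),
         function(i) sum(rgamma(terms, shape = 1, rate = 1) / denom),
         numeric(1)) / (2 * pi^2)
}

# mean of the truncated tail of the series, used to de-bias comparisons
rpg_series_tail_mean <- function(z, terms = 250) {
  k <- seq((terms + 1), terms + 200000)
  sum(1 / ((k - 0.5)^2 + z^2 / (4 * pi^2))) / (2 * pi^2)
}

# Direct evaluation of the multinomial class weights:
# lambda_c proportional to pi_c * prod_j [ Bern(y; logistic(z)) * cosh(z/2)
#   * exp(-w z^2 / 2) ], the tilted PG density with the PG(1,0) base factor
# dropped (it is class-independent and cancels in normalization).
direct_class_weights <- function(y, w, zeta, beta, eta_table, pi) {
  C <- nrow(eta_table)
  wts <- numeric(C)
  for (c in seq_len(C)) {
    z <- zeta + beta * eta_table[c, ]
    p <- plogis(z)
    wts[c] <- pi[c] * prod(p^y * (1 - p)^(1 - y) * cosh(z / 2) *
                             exp(-w * z^2 / 2))
  }
  wts / sum(wts)
}

# Naive double-loop marginal likelihood over all latent classes
brute_marginal_loglik <- function(Y, zeta, beta, pi, Q) {
  patterns <- attribute_patterns(ncol(Q))
  total <- 0
  for (i in seq_len(nrow(Y))) {
    acc <- 0
    for (c in seq_len(nrow(patterns))) {
      pr <- 1
      for (j in seq_len(nrow(Q))) {
        eta <- as.integer(all(patterns[c, Q[j, ] == 1] == 1))
        p <- plogis(zeta[j] + beta[j] * eta)
        pr <- pr * p^Y[i, j] * (1 - p)^(1 - Y[i, j])
      }
      acc <- acc + pi[c] * pr
    }
    total <- total + log(acc)
  }
  total
}

# pooled EAPs of a fit, for cross-sampler comparisons
fit_eap <- function(fit, block) {
  colMeans(do.call(rbind, lapply(fit$draws, `[[`, block)))
}
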