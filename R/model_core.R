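#' Reparameterize slipping/guessing probabilities to the logit scale
#'
#' The DINA model gives a correct response with probability `1 - s` when the
#' examinee masters every attribute the item requires (ideal response
#' `eta = 1`) and `g` otherwise. On the logit scale the same model is a
#' logistic regression on `eta` with intercept `zeta = logit(g)` and
#' interaction `beta = logit(1 - s) - logit(g)`. `beta > 0` whenever
#' `1 - s > g`, i.e. whenever the item discriminates (IDI = `1 - s - g` > 0).
#'
#' @param s slipping probability (or vector), strictly inside (0, 1).
#' @param g guessing probability (or vector), strictly inside (0, 1).
#' @return A list with numeric components `zeta` and `beta`.
#' @seealso [deparameterize()]
#' @examples
#' reparameterize(s = 0.1, g = 0.1)  # zeta = -2.1972, beta = 4.3945
#' @export
reparameterize <- function(s, g) {
  if (!is.numeric(s) || !is.numeric(g) || any(!is.finite(s)) || any(!is.finite(g)))
    stop("s and g must be finite numeric values")
  if (any(s <= 0 | s >= 1) || any(g <= 0 | g >= 1))
    stop("s and g must lie strictly inside (0, 1)")
  list(zeta = qlogis(g), beta = qlogis(1 - s) - qlogis(g))
}

#' Map intercept/interaction parameters back to the probability scale
#'
#' Inverse of [reparameterize()]: `g = plogis(zeta)` and
#' `s = 1 - plogis(zeta + beta)`.
#'
#' @param zeta item intercept (logit of guessing), finite numeric.
#' @param beta item interaction (logit difference), finite numeric.
#' @return A list with numeric components `s` and `g`.
#' @export
deparameterize <- function(zeta, beta) {
  if (!is.numeric(zeta) || !is.numeric(beta) ||
      any(!is.finite(zeta)) || any(!is.finite(beta)))
    stop("zeta and beta must be finite numeric values")
  list(s = 1 - plogis(zeta + beta), g = plogis(zeta))
}

#' Enumerate the latent attribute-pattern space
#'
#' All `C = 2^K` mastery patterns over `K` attributes, one per row, in the
#' canonical order where the first attribute is the most significant bit:
#' class `c` (1-based) has pattern equal to the binary expansion of `c - 1`.
#' This fixed order is what indexes `pi` throughout the package.
#'
#' @param K number of attributes (positive integer).
#' @return A `2^K x K` binary matrix with columns `A1..AK`.
#' @examples
#' attribute_patterns(2)  # rows: 00, 01, 10, 11
#' @export
attribute_patterns <- function(K) {
  if (!is.numeric(K) || length(K) != 1L || K < 1 || K != round(K))
    stop("K must be a positive integer")
  C <- 2L^K
  pat <- matrix(0L, C, K)
  for (k in seq_len(K)) {
    pat[, k] <- rep(rep(0:1, each = 2L^(K - k)), length.out = C)
  }
  colnames(pat) <- paste0("A", seq_len(K))
  pat
}

#' Ideal response of one attribute pattern to one item
#'
#' Returns 1 iff the pattern masters every attribute the item requires
#' (conjunctive "and" gate); an item requiring nothing would give 1 by the
#' empty-product convention, but such rows are rejected at Q-matrix
#' validation because they leave the item parameters unidentified.
#'
#' @param alpha binary mastery vector of length `K`.
#' @param q_row binary requirement vector of length `K`.
#' @return Integer 0 or 1.
#' @export
ideal_response <- function(alpha, q_row) {
  if (length(alpha) != length(q_row))
    stop("alpha and q_row must have the same length")
  as.integer(all(alpha[q_row == 1] == 1))
}

#' Ideal responses of every latent class to every item
#'
#' @param Q a validated binary Q-matrix (`J x K`), see [validate_qmatrix()].
#' @param patterns optional pattern matrix from [attribute_patterns()];
#'   derived from `ncol(Q)` when missing.
#' @return A `C x J` binary matrix; entry (c, j) is 1 iff class `c` masters
#'   all attributes required by item `j`.
#' @export
ideal_response_table <- function(Q, patterns = NULL) {
  Q <- validate_qmatrix(Q)
  if (is.null(patterns)) patterns <- attribute_patterns(ncol(Q))
  if (ncol(patterns) != ncol(Q))
    stop("patterns and Q disagree on the number of attributes")
  # eta = 1 iff the pattern covers the item's requirements:
  # count of required-and-mastered equals count of required
  eta <- (patterns %*% t(Q)) == matrix(rowSums(Q), nrow(patterns), nrow(Q),
                                       byrow = TRUE)
  storage.mode(eta) <- "integer"
  eta
}

#' Correct-response probability of the reparameterized DINA model
#'
#' `plogis(zeta + beta * eta)`, which equals `g + (1 - s - g) * eta` on the
#' probability scale. Vectorized over all arguments.
#'
#' @param zeta item intercept(s).
#' @param beta item interaction(s).
#' @param eta ideal response(s), 0 or 1.
#' @return Probability of a correct response.
#' @export
response_prob <- function(zeta, beta, eta) {
  if (any(!is.finite(zeta)) || any(!is.finite(beta)))
    stop("zeta and beta must be finite")
  plogis(zeta + beta * eta)
}

#' Bernoulli log-likelihood of one response vector under one latent class
#'
#' @param y binary response vector of length `J`.
#' @param eta_row ideal responses of the class to the `J` items.
#' @param zeta,beta item parameter vectors of length `J`.
#' @return The log-probability of `y` under the class.
#' @export
class_loglik <- function(y, eta_row, zeta, beta) {
  J <- length(y)
  if (length(eta_row) != J || length(zeta) != J || length(beta) != J)
    stop("y, eta_row, zeta and beta must all have length J")
  z <- zeta + beta * eta_row
  # y*z - log(1 + e^z), stable for large |z|
  sum(y * z - ifelse(z > 35, z, log1p(exp(pmin(z, 35)))))
}

#' Marginal log-likelihood over the latent classes
#'
#' Sums, per examinee, the class-mixture likelihood
#' `sum_c pi_c p(Y_i | class c)` in the log domain via log-sum-exp.
#'
#' @param Y binary response matrix (`N x J`).
#' @param zeta,beta item parameter vectors of length `J`.
#' @param pi class-membership probabilities over the `2^K` classes, in the
#'   canonical [attribute_patterns()] order.
#' @param Q binary Q-matrix (`J x K`).
#' @return The total log-likelihood (scalar).
#' @export
marginal_loglik <- function(Y, zeta, beta, pi, Q) {
  Q <- validate_qmatrix(Q)
  Y <- validate_responses(Y, Q)
  C <- 2L^ncol(Q)
  if (length(pi) != C || any(pi < 0) || abs(sum(pi) - 1) > 1e-12)
    stop("pi must be a probability vector over the ", C, " latent classes")
  eta <- ideal_response_table(Q)
  Zmat <- t(matrix(zeta, nrow(Q), C) + t(eta) * matrix(beta, nrow(Q), C)) # C x J
  # log p(Y_i | c) = sum_j [y z - log(1+e^z)]
  l1p <- ifelse(Zmat > 35, Zmat, log1p(exp(pmin(Zmat, 35))))
  ll_ic <- Y %*% t(Zmat) - matrix(rowSums(l1p), nrow(Y), C, byrow = TRUE)
  lw <- sweep(ll_ic, 2, log(pi), "+")
  m <- apply(lw, 1, max)
  sum(m + log(rowSums(exp(lw - m))))
}

#' Validate a Q-matrix
#'
#' Checks that the object is a binary `J x K` matrix whose rows each require
#' at least one attribute. All-zero rows are rejected: for such an item the
#' ideal response is identically 1 and `zeta`, `beta` are confounded.
#'
#' @param Q matrix or data frame of 0/1 entries.
#' @return The validated Q-matrix with integer storage.
#' @export
validate_qmatrix <- function(Q) {
  Q <- as.matrix(Q)
  if (nrow(Q) < 1 || ncol(Q) < 1) stop("Q must have at least one row and column")
  if (!all(Q %in% c(0, 1))) {
    bad <- which(rowSums(!(Q == 0 | Q == 1)) > 0)[1]
    stop("Q-matrix entries must be 0 or 1 (first offending item row: ", bad, ")")
  }
  zero <- which(rowSums(Q) == 0)
  if (length(zero))
    stop("Q-matrix rows must require at least one attribute (item rows: ",
         paste(zero, collapse = ", "), ")")
  storage.mode(Q) <- "integer"
  Q
}

#' Validate a response matrix against a Q-matrix
#'
#' @param Y matrix or data frame of 0/1 responses, examinees in rows.
#' @param Q optional Q-matrix; when supplied, `ncol(Y)` must equal `nrow(Q)`.
#' @return The validated response matrix with integer storage.
#' @export
validate_responses <- function(Y, Q = NULL) {
  Y <- as.matrix(Y)
  if (!all(Y %in% c(0, 1))) {
    bad <- which(rowSums(!(Y == 0 | Y == 1)) > 0)[1]
    stop("responses must be 0 or 1 (first offending examinee row: ", bad, ")")
  }
  if (!is.null(Q) && ncol(Y) != nrow(Q))
    stop("Y has ", ncol(Y), " items but Q has ", nrow(Q), " rows")
  storage.mode(Y) <- "integer"
  Y
}
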