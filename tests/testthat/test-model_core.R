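test_that("reparameterization reproduces the standard logit constants", {
  cases <- list(
    list(s = 0.1, g = 0.1, zeta = -2.1972, beta = 4.3945),
    list(s = 0.2, g = 0.2, zeta = -1.3863, beta = 2.7726),
    list(s = 0.2, g = 0.1, zeta = -2.1972, beta = 3.5835),
    list(s = 0.1, g = 0.2, zeta = -1.3863, beta = 3.5835))
  for (cs in cases) {
    rp <- reparameterize(cs$s, cs$g)
    expect_equal(rp$zeta, cs$zeta, tolerance = 1e-4)
    expect_equal(rp$beta, cs$beta, tolerance = 1e-4)
  }
  expect_equal(reparameterize(0.5, 0.5), list(zeta = 0, beta = 0))
})

test_that("reparameterize and deparameterize are mutual inverses on a grid", {
  grid <- expand.grid(s = seq(0.02, 0.9, by = 0.08),
                      g = seq(0.02, 0.9, by = 0.08))
  rp <- reparameterize(grid$s, grid$g)
  back <- deparameterize(rp$zeta, rp$beta)
  expect_equal(back$s, grid$s, tolerance = 1e-12)
  expect_equal(back$g, grid$g, tolerance = 1e-12)
  dp <- deparameterize(0, 0)
  expect_equal(dp, list(s = 0.5, g = 0.5))
  dp <- deparameterize(-1.3863, 2.7726)
  expect_equal(round(dp$s, 4), 0.2)
  expect_equal(round(dp$g, 4), 0.2)
})

test_that("reparameterization rejects out-of-domain inputs", {
  expect_error(reparameterize(0, 0.5), "inside")
  expect_error(reparameterize(0.5, 1), "inside")
  expect_error(deparameterize(Inf, 1), "finite")
})

test_that("ideal responses implement the conjunctive gate", {
  expect_equal(ideal_response(c(1, 1, 0, 0, 0), c(1, 1, 0, 0, 0)), 1L)
  expect_equal(ideal_response(c(1, 0, 0, 0, 0), c(1, 1, 0, 0, 0)), 0L)
  expect_equal(ideal_response(c(0, 0, 0, 0, 0), c(1, 0, 0, 0, 0)), 0L)
  expect_error(ideal_response(c(1, 0), c(1, 0, 0)), "length")
})

test_that("the ideal-response table matches per-pattern evaluation", {
  expect_equal(unname(ideal_response_table(matrix(1, 1, 1))),
               matrix(c(0L, 1L), 2, 1))
  Q <- rbind(c(1, 0), c(1, 1))
  eta <- ideal_response_table(Q)
  pats <- attribute_patterns(2)
  # enumerate by hand: patterns 00, 01, 10, 11
  expect_equal(unname(eta), rbind(c(0L, 0L), c(0L, 0L), c(1L, 0L), c(1L, 1L)))
  expect_equal(eta[nrow(eta), ], setNames(rep(1L, 2), NULL), ignore_attr = TRUE)
  # cross-check every cell against the scalar operation
  for (c in seq_len(nrow(pats)))
    for (j in seq_len(nrow(Q)))
      expect_equal(eta[c, j], ideal_response(pats[c, ], Q[j, ]))
})

test_that("attribute patterns enumerate all classes in canonical order", {
  pats <- attribute_patterns(3)
  expect_equal(dim(pats), c(8L, 3L))
  expect_equal(nrow(unique(pats)), 8L)
  # first attribute is the most significant bit
  expect_equal(unname(pats[1, ]), c(0L, 0L, 0L))
  expect_equal(unname(pats[2, ]), c(0L, 0L, 1L))
  expect_equal(unname(pats[5, ]), c(1L, 0L, 0L))
  idx <- 1 + pats %*% 2^((3 - 1):0)
  expect_equal(as.numeric(idx), 1:8)
})

test_that("response probabilities agree between the logit and s/g forms", {
  expect_equal(response_prob(qlogis(0.2), 3.7, 0), 0.2)
  expect_equal(round(response_prob(-2.1972, 4.3945, 1), 4), 0.9)
  grid <- expand.grid(s = c(0.05, 0.2, 0.4), g = c(0.05, 0.2, 0.4), eta = 0:1)
  rp <- reparameterize(grid$s, grid$g)
  expect_equal(response_prob(rp$zeta, rp$beta, grid$eta),
               grid$g + (1 - grid$s - grid$g) * grid$eta, tolerance = 1e-12)
})

test_that("response probability is monotone in beta only when eta = 1", {
  b <- seq(0.1, 5, by = 0.3)
  p1 <- response_prob(-1, b, 1)
  expect_true(all(diff(p1) > 0))
  expect_equal(response_prob(-1, b, 0), rep(plogis(-1), length(b)))
  # positive interaction implies positive discrimination index
  rp <- reparameterize(0.15, 0.25)
  expect_gt(rp$beta, 0)
  expect_equal(response_prob(rp$zeta, rp$beta, 1) -
                 response_prob(rp$zeta, rp$beta, 0), 1 - 0.15 - 0.25)
})

test_that("class log-likelihood matches hand computations", {
  rp <- reparameterize(0.1, 0.1)
  expect_equal(class_loglik(1, 1, rp$zeta, rp$beta), log(0.9), tolerance = 1e-12)
  # two items with p = (0.9, 0.2) and responses (1, 0)
  z <- c(qlogis(0.9), qlogis(0.2))
  ll <- class_loglik(c(1, 0), c(0, 0), z, c(1, 1))
  expect_equal(ll, log(0.9) + log(0.8), tolerance = 1e-12)
  expect_true(exp(ll) > 0 && exp(ll) <= 1)
  expect_error(class_loglik(c(1, 0), 1, z, c(1, 1)), "length")
})

test_that("marginal log-likelihood matches the brute-force class sum", {
  Q <- rbind(c(1, 0), c(0, 1), c(1, 1))
  zeta <- c(-2, -1.5, -1)
  beta <- c(3, 2.5, 2)
  set.seed(11)
  for (rep in 1:5) {
    Y <- matrix(rbinom(9, 1, 0.5), 3, 3)
    pi <- rgamma(4, 1); pi <- pi / sum(pi)
    expect_equal(marginal_loglik(Y, zeta, beta, pi, Q),
                 brute_marginal_loglik(Y, zeta, beta, pi, Q),
                 tolerance = 1e-10)
  }
  # degenerate single-class mixture reduces to the class log-likelihood
  Q1 <- matrix(1, 2, 1)
  Y1 <- matrix(c(1L, 0L), 1, 2)
  eta1 <- ideal_response_table(Q1)
  ll <- marginal_loglik(Y1, c(-1, -1), c(2, 2), c(0, 1), Q1)
  expect_equal(ll, class_loglik(Y1[1, ], eta1[2, ], c(-1, -1), c(2, 2)))
  expect_error(marginal_loglik(Y1, c(-1, -1), c(2, 2), c(0.7, 0.7), Q1), "simplex|probability")
})

test_that("Q-matrix validation rejects malformed input", {
  expect_error(validate_qmatrix(rbind(c(1, 2))), "0 or 1")
  expect_error(validate_qmatrix(rbind(c(1, 0), c(0, 0))), "at least one attribute")
  expect_error(validate_responses(matrix(0.5, 1, 1)), "0 or 1")
  expect_error(validate_responses(matrix(1L, 2, 3), matrix(1L, 2, 1)), "items")
})

test_that("CSV round-trips preserve matrices and report bad lines", {
  Q <- sim_qmatrix(K = 2, J = 6)
  f <- tempfile(fileext = ".csv")
  write_binary_csv(Q, f)
  expect_equal(unname(read_qmatrix(f)), unname(Q))

  Y <- simulate_dina(20, Q, 0.1, 0.1, seed = 3)$Y
  fy <- tempfile(fileext = ".csv")
  write_binary_csv(Y, fy)
  expect_equal(unname(read_responses(fy, Q)), unname(Y))

  writeLines(c("A1,A2", "1,0", "1,2"), f)
  expect_error(read_qmatrix(f), "line 3")
  writeLines(c("A1,A2", "0,0"), f)
  expect_error(read_qmatrix(f), "line")
  expect_error(read_qmatrix(tempfile()), "not found")
})
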