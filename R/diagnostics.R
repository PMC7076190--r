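.as_chain_matrix <- function(chains) {
  if (is.list(chains)) {
    n <- unique(lengths(chains))
    if (length(n) != 1) stop("all chains must have the same length")
    chains <- do.call(cbind, chains)
  }
  chains <- as.matrix(chains)
  if (ncol(chains) < 2) stop("at least two chains are required")
  if (nrow(chains) < 4) stop("chains must have at least four iterations")
  chains
}

#' Potential scale reduction factor
#'
#' The Brooks-Gelman corrected PSRF for one scalar parameter monitored over
#' `m` chains of length `n` (columns of a matrix, or a list of equal-length
#' vectors): with within-chain variance `W` (mean of the per-chain sample
#' variances) and between-chain variance `B = n * var(chain means)`,
#' \deqn{\hat R = \sqrt{\Big(\frac{(n-1)/n\,W + B/n}{W}\Big)\frac{m+1}{m}
#'   - \frac{n-1}{mn}}.}
#' Chains are used whole; set `split = TRUE` to halve each chain first.
#' Values near 1 indicate convergence; above 1.1 is the usual alarm.
#'
#' @param chains `n x m` matrix or list of `m` numeric vectors.
#' @param split halve each chain before computing (off by default).
#' @return The PSRF (scalar); `+Inf` with a warning when the within-chain
#'   variance is zero.
#' @export
psrf <- function(chains, split = FALSE) {
  x <- .as_chain_matrix(chains)
  if (split) {
    half <- floor(nrow(x) / 2)
    x <- cbind(x[seq_len(half), , drop = FALSE],
               x[(nrow(x) - half + 1):nrow(x), , drop = FALSE])
  }
  n <- nrow(x); m <- ncol(x)
  W <- mean(apply(x, 2, var))
  B <- n * var(colMeans(x))
  if (W == 0) {
    warning("zero within-chain variance; PSRF undefined")
    return(Inf)
  }
  sqrt((((n - 1) / n * W + B / n) / W) * (m + 1) / m - (n - 1) / (m * n))
}

#' Cumulative PSRF trace
#'
#' PSRF computed on the first `g` iterations of every chain for each grid
#' point `g`, the cumulative convention used for convergence trace plots.
#'
#' @inheritParams psrf
#' @param grid increasing iteration checkpoints; defaults to 20 evenly
#'   spaced points over the chain length.
#' @return An object of class `psrf_trace`: a data frame with columns
#'   `iteration` and `psrf`.
#' @export
psrf_trace <- function(chains, grid = NULL) {
  x <- .as_chain_matrix(chains)
  n <- nrow(x)
  if (is.null(grid)) grid <- unique(round(seq(max(4, n / 20), n, length.out = 20)))
  grid <- sort(unique(as.integer(grid)))
  if (any(grid < 4) || any(grid > n)) stop("grid points must lie in [4, chain length]")
  vals <- vapply(grid, function(g) psrf(x[seq_len(g), , drop = FALSE]), numeric(1))
  structure(data.frame(iteration = grid, psrf = vals),
            class = c("psrf_trace", "data.frame"))
}

#' @export
plot.psrf_trace <- function(x, threshold = 1.1, ...) {
  plot(x$iteration, x$psrf, type = "b", xlab = "iteration", ylab = "PSRF", ...)
  abline(h = threshold, lty = 2)
  invisible(x)
}

#' Highest posterior density interval
#'
#' Shortest interval containing `ceiling(level * n)` of the sorted draws;
#' ties in width are broken toward the smallest lower bound.
#'
#' @param draws numeric vector of posterior draws.
#' @param level credibility level.
#' @return Numeric vector `c(lower, upper)`.
#' @export
hpdi <- function(draws, level = 0.95) {
  x <- sort(draws)
  n <- length(x)
  keep <- ceiling(level * n)
  if (keep >= n) return(c(x[1], x[n]))
  widths <- x[(keep + 1):n] - x[1:(n - keep)]
  i <- which.min(widths)  # which.min returns the first (smallest lower bound)
  c(x[i], x[i + keep])
}

#' Posterior summary of a single parameter
#'
#' EAP (posterior mean), posterior SD and the highest posterior density
#' interval of a vector of draws.
#'
#' @param draws numeric vector with at least 10 draws.
#' @param level credibility level for the HPDI.
#' @return A one-row data frame with columns `eap`, `sd`, `hpdi_lower`,
#'   `hpdi_upper`.
#' @export
summarize_draws <- function(draws, level = 0.95) {
  if (length(draws) < 10) stop("need at least 10 draws to summarize")
  h <- hpdi(draws, level)
  data.frame(eap = mean(draws), sd = sd(draws),
             hpdi_lower = h[1], hpdi_upper = h[2])
}

.pooled_draws <- function(fit, block) {
  do.call(rbind, lapply(fit$draws, `[[`, block))
}

#' Posterior summary table of a fitted DINA model
#'
#' One row per monitored parameter (all intercepts, interactions and class
#' probabilities), pooling post-burn-in draws across chains.
#'
#' @param object a `dina_fit` from [fit_pggsa()] or [fit_mh()].
#' @param level credibility level for the HPDIs.
#' @param ... unused.
#' @return A data frame with columns `parameter`, `eap`, `sd`,
#'   `hpdi_lower`, `hpdi_upper`.
#' @export
summary.dina_fit <- function(object, level = 0.95, ...) {
  blocks <- lapply(c("zeta", "beta", "pi"), function(b) .pooled_draws(object, b))
  draws <- do.call(cbind, blocks)
  out <- do.call(rbind, lapply(seq_len(ncol(draws)), function(k)
    summarize_draws(draws[, k], level)))
  data.frame(parameter = colnames(draws), out, row.names = NULL)
}

#' PSRF of every monitored parameter of a fit
#'
#' Requires at least two chains. Class probabilities (a simplex) are
#' monitored per coordinate.
#'
#' @param fit a `dina_fit` with `n_chains >= 2`.
#' @return Named numeric vector of PSRF values.
#' @export
psrf_fit <- function(fit) {
  if (length(fit$draws) < 2) stop("PSRF needs at least two chains")
  params <- c(colnames(fit$draws[[1]]$zeta), colnames(fit$draws[[1]]$beta),
              colnames(fit$draws[[1]]$pi))
  full <- lapply(fit$draws, function(ch) cbind(ch$zeta, ch$beta, ch$pi))
  vals <- vapply(seq_along(params), function(k)
    psrf(vapply(full, function(m) m[, k], numeric(nrow(full[[1]])))),
    numeric(1))
  names(vals) <- params
  vals
}
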