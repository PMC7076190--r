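// Full MCMC sweeps for the reparameterized DINA model: the Polya-Gamma
// Gibbs chain and the random-walk Metropolis-Hastings baseline. Both update,
// per iteration, the item intercepts (zeta) and interactions (beta), then
// every examinee's latent attribute class, then the class-membership
// probabilities pi ~ Dirichlet. Classes are indexed 0-based internally.
#include <Rcpp.h>
#include <vector>
#include "samplers.h"

using namespace Rcpp;

// log(1 + exp(x)) without overflow
static inline double log1pexp_(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// per-class list of items whose required attributes the class masters
static std::vector<std::vector<int>> ones_by_class(const IntegerMatrix& eta) {
  int C = eta.nrow(), J = eta.ncol();
  std::vector<std::vector<int>> ones(C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < J; ++j)
      if (eta(c, j) == 1) ones[c].push_back(j);
  return ones;
}

// draw one categorical index from unnormalized log weights
static int sample_class(const std::vector<double>& logw) {
  int C = (int)logw.size();
  double mx = logw[0];
  for (int c = 1; c < C; ++c) if (logw[c] > mx) mx = logw[c];
  if (!R_finite(mx)) stop("degenerate class weights: all -Inf");
  double tot = 0.0;
  std::vector<double> w(C);
  for (int c = 0; c < C; ++c) { w[c] = std::exp(logw[c] - mx); tot += w[c]; }
  double u = unif_rand() * tot, acc = 0.0;
  for (int c = 0; c < C; ++c) { acc += w[c]; if (u <= acc) return c; }
  return C - 1;
}

static void update_pi_(std::vector<double>& pi, const IntegerVector& cls,
                       double delta0, int C) {
  std::vector<double> shape(C, delta0);
  for (int i = 0; i < cls.size(); ++i) shape[cls[i]] += 1.0;
  double tot = 0.0;
  for (int c = 0; c < C; ++c) { pi[c] = R::rgamma(shape[c], 1.0); tot += pi[c]; }
  for (int c = 0; c < C; ++c) pi[c] /= tot;
}

// [[Rcpp::export(name = ".pggsa_chain_cpp")]]
List pggsa_chain_cpp(const IntegerMatrix& Y, const IntegerMatrix& eta,
                     double mu_zeta, double var_zeta,
                     double mu_beta, double var_beta, double delta0,
                     double zeta_lo, double zeta_hi,
                     double beta_lo, double beta_hi,
                     int n_iter, int burn_in, int thin,
                     NumericVector zeta0, NumericVector beta0,
                     IntegerVector cls0, NumericVector pi0) {
  int N = Y.nrow(), J = Y.ncol(), C = eta.nrow();
  int S = (n_iter - burn_in) / thin;
  std::vector<double> zeta(zeta0.begin(), zeta0.end());
  std::vector<double> beta(beta0.begin(), beta0.end());
  std::vector<double> pi(pi0.begin(), pi0.end());
  IntegerVector cls = clone(cls0);
  NumericMatrix W(N, J);
  NumericMatrix zeta_draws(S, J), beta_draws(S, J), pi_draws(S, C);
  IntegerMatrix class_counts(N, C);
  std::vector<std::vector<int>> ones = ones_by_class(eta);
  std::vector<double> d(N * J);  // per-cell class-weight increments
  std::vector<double> logw(C);
  int s = 0;

  for (int t = 1; t <= n_iter; ++t) {
    if (t % 200 == 0) Rcpp::checkUserInterrupt();

    // Step 1: Polya-Gamma auxiliaries W_ij ~ PG(1, |zeta_j + beta_j eta_ij|).
    // Each item has only two distinct tilts, so the proposal constants are
    // set up once per item and reused across examinees.
    for (int j = 0; j < J; ++j) {
      PGParams p0, p1;
      pg_setup(zeta[j], p0);
      pg_setup(zeta[j] + beta[j], p1);
      for (int i = 0; i < N; ++i) {
        W(i, j) = rpg1_draw(eta(cls[i], j) ? p1 : p0);
      }
    }

    // Step 2: intercepts from Gaussian conditionals
    for (int j = 0; j < J; ++j) {
      double sw = 0.0, sk = 0.0;
      for (int i = 0; i < N; ++i) {
        double w = W(i, j);
        sw += w;
        sk += (Y(i, j) - 0.5) - w * beta[j] * eta(cls[i], j);
      }
      double V = 1.0 / (1.0 / var_zeta + sw);
      double m = V * (mu_zeta / var_zeta + sk);
      zeta[j] = rtnorm_ab(m, std::sqrt(V), zeta_lo, zeta_hi);
    }

    // Step 3: interactions from positive-truncated Gaussian conditionals
    for (int j = 0; j < J; ++j) {
      double swe = 0.0, ske = 0.0;
      for (int i = 0; i < N; ++i) {
        if (eta(cls[i], j)) {
          double w = W(i, j);
          swe += w;
          ske += (Y(i, j) - 0.5) - w * zeta[j];
        }
      }
      double V = 1.0 / (1.0 / var_beta + swe);
      double m = V * (mu_beta / var_beta + ske);
      beta[j] = rtnorm_ab(m, std::sqrt(V), beta_lo, beta_hi);
    }

    // Step 4: latent classes. Weight increment of mastering item j for
    // examinee i is d_ij = k_ij*(z1-z0) - W_ij*(z1^2 - z0^2)/2, on top of
    // the class-independent baseline (which cancels in normalization).
    for (int j = 0; j < J; ++j) {
      double z0 = zeta[j], z1 = zeta[j] + beta[j];
      double dz = z1 - z0, dz2 = 0.5 * (z1 * z1 - z0 * z0);
      for (int i = 0; i < N; ++i) {
        d[(size_t)j * N + i] = (Y(i, j) - 0.5) * dz - W(i, j) * dz2;
      }
    }
    for (int i = 0; i < N; ++i) {
      for (int c = 0; c < C; ++c) {
        double acc = std::log(pi[c]);
        for (int j : ones[c]) acc += d[(size_t)j * N + i];
        logw[c] = acc;
      }
      cls[i] = sample_class(logw);
    }

    // Step 5: class-membership probabilities
    update_pi_(pi, cls, delta0, C);

    if (t > burn_in && (t - burn_in) % thin == 0) {
      for (int j = 0; j < J; ++j) { zeta_draws(s, j) = zeta[j]; beta_draws(s, j) = beta[j]; }
      for (int c = 0; c < C; ++c) pi_draws(s, c) = pi[c];
      for (int i = 0; i < N; ++i) class_counts(i, cls[i]) += 1;
      ++s;
    }
  }
  return List::create(_["zeta"] = zeta_draws, _["beta"] = beta_draws,
                      _["pi"] = pi_draws, _["class_counts"] = class_counts);
}

// [[Rcpp::export(name = ".mh_chain_cpp")]]
List mh_chain_cpp(const IntegerMatrix& Y, const IntegerMatrix& eta,
                  double mu_zeta, double var_zeta,
                  double mu_beta, double var_beta, double delta0,
                  double zeta_lo, double zeta_hi,
                  double beta_lo, double beta_hi,
                  double sd_zeta, double sd_beta,
                  int n_iter, int burn_in, int thin,
                  NumericVector zeta0, NumericVector beta0,
                  IntegerVector cls0, NumericVector pi0) {
  int N = Y.nrow(), J = Y.ncol(), C = eta.nrow();
  int S = (n_iter - burn_in) / thin;
  std::vector<double> zeta(zeta0.begin(), zeta0.end());
  std::vector<double> beta(beta0.begin(), beta0.end());
  std::vector<double> pi(pi0.begin(), pi0.end());
  IntegerVector cls = clone(cls0);
  NumericMatrix zeta_draws(S, J), beta_draws(S, J), pi_draws(S, C);
  IntegerMatrix class_counts(N, C);
  IntegerVector acc_zeta(J), acc_beta(J);
  std::vector<std::vector<int>> ones = ones_by_class(eta);
  std::vector<double> d(N * J);
  std::vector<double> logw(C);
  int s = 0;

  // Bernoulli log-likelihood of item j given sufficient counts:
  // n1/s1 = examinees (and their correct answers) with eta = 1, n0/s0 rest
  auto item_loglik = [](double z0, double z1, double n0, double s0,
                        double n1, double s1) {
    return s1 * z1 - n1 * log1pexp_(z1) + s0 * z0 - n0 * log1pexp_(z0);
  };

  for (int t = 1; t <= n_iter; ++t) {
    if (t % 200 == 0) Rcpp::checkUserInterrupt();

    // per-item sufficient counts under the current class assignment
    for (int j = 0; j < J; ++j) {
      double n1 = 0, s1 = 0, s0 = 0;
      for (int i = 0; i < N; ++i) {
        if (eta(cls[i], j)) { n1 += 1.0; s1 += Y(i, j); } else { s0 += Y(i, j); }
      }
      double n0 = N - n1;

      // zeta: symmetric random-walk proposal; out-of-support proposals
      // (zero prior density) are rejected outright
      double zp = zeta[j] + sd_zeta * norm_rand();
      if (zp > zeta_lo && zp < zeta_hi) {
        double lr = item_loglik(zp, zp + beta[j], n0, s0, n1, s1) -
                    item_loglik(zeta[j], zeta[j] + beta[j], n0, s0, n1, s1) +
                    (-0.5 * (zp - mu_zeta) * (zp - mu_zeta) +
                      0.5 * (zeta[j] - mu_zeta) * (zeta[j] - mu_zeta)) / var_zeta;
        if (std::log(unif_rand()) < lr) { zeta[j] = zp; if (t > burn_in) acc_zeta[j] += 1; }
      }

      // beta: positive-truncated random-walk proposal with Hastings correction
      double bp = rtnorm_pos(beta[j], sd_beta);
      if (bp > beta_lo && bp < beta_hi) {
        double lr = item_loglik(zeta[j], zeta[j] + bp, n0, s0, n1, s1) -
                    item_loglik(zeta[j], zeta[j] + beta[j], n0, s0, n1, s1) +
                    (-0.5 * (bp - mu_beta) * (bp - mu_beta) +
                      0.5 * (beta[j] - mu_beta) * (beta[j] - mu_beta)) / var_beta +
                    R::pnorm(beta[j] / sd_beta, 0.0, 1.0, 1, 1) -
                    R::pnorm(bp / sd_beta, 0.0, 1.0, 1, 1);
        if (std::log(unif_rand()) < lr) { beta[j] = bp; if (t > burn_in) acc_beta[j] += 1; }
      }
    }

    // latent classes from the marginal (no-W) weights:
    // increment of mastering item j is Y_ij*(z1-z0) - [log1pexp(z1)-log1pexp(z0)]
    for (int j = 0; j < J; ++j) {
      double z0 = zeta[j], z1 = zeta[j] + beta[j];
      double dz = z1 - z0, dl = log1pexp_(z1) - log1pexp_(z0);
      for (int i = 0; i < N; ++i) d[(size_t)j * N + i] = Y(i, j) * dz - dl;
    }
    for (int i = 0; i < N; ++i) {
      for (int c = 0; c < C; ++c) {
        double acc = std::log(pi[c]);
        for (int j : ones[c]) acc += d[(size_t)j * N + i];
        logw[c] = acc;
      }
      cls[i] = sample_class(logw);
    }

    update_pi_(pi, cls, delta0, C);

    if (t > burn_in && (t - burn_in) % thin == 0) {
      for (int j = 0; j < J; ++j) { zeta_draws(s, j) = zeta[j]; beta_draws(s, j) = beta[j]; }
      for (int c = 0; c < C; ++c) pi_draws(s, c) = pi[c];
      for (int i = 0; i < N; ++i) class_counts(i, cls[i]) += 1;
      ++s;
    }
  }
  NumericVector rate_zeta(J), rate_beta(J);
  for (int j = 0; j < J; ++j) {
    rate_zeta[j] = acc_zeta[j] / (double)(n_iter - burn_in);
    rate_beta[j] = acc_beta[j] / (double)(n_iter - burn_in);
  }
  return List::create(_["zeta"] = zeta_draws, _["beta"] = beta_draws,
                      _["pi"] = pi_draws, _["class_counts"] = class_counts,
                      _["accept_zeta"] = rate_zeta, _["accept_beta"] = rate_beta);
}
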