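// Exact Polya-Gamma PG(1, z) variates via the alternating-series rejection
// sampler on the Jacobi J*(1, z/2) density (Devroye-type), plus robust
// truncated-normal samplers. All randomness comes from R's RNG so draws are
// reproducible under set.seed(). The proposal constants depend on z only,
// so they are precomputed once (pg_setup) and reused across draws with the
// same tilt -- the Gibbs sweep draws thousands of variates per item but
// each item has only two distinct tilts.
#include <Rcpp.h>
#include "samplers.h"

using namespace Rcpp;

static const double TRUNC = 0.64;  // series switch point for the J* density

// n-th coefficient of the alternating series bounding the J*(1) density at x
static double a_coef(int n, double x) {
  double d = n + 0.5;
  if (x > TRUNC) {
    return M_PI * d * std::exp(-d * d * M_PI * M_PI * x / 2.0);
  }
  return M_PI * d * std::pow(2.0 / (M_PI * x), 1.5) * std::exp(-2.0 * d * d / x);
}

// CDF at x of the inverse-Gaussian(mu = 1/z, lambda = 1); z = 0 gives the
// Levy limit 2*Phi(-1/sqrt(x)). Written to avoid overflow in exp(2z).
static double pigauss(double x, double z) {
  double rx = 1.0 / std::sqrt(x);
  double b = rx * (x * z - 1.0);
  double a = -rx * (x * z + 1.0);
  double term2 = std::exp(2.0 * z + R::pnorm(a, 0.0, 1.0, 1, 1));
  return R::pnorm(b, 0.0, 1.0, 1, 0) + term2;
}

// Inverse-Gaussian(1/z, 1) truncated to (0, t]
static double rtigauss(double z, double t) {
  double x;
  if (z < 1.0 / t) {  // mu > t: sample the z = 0 case, thin by the tilt
    for (;;) {
      double e1, e2;
      do {
        e1 = exp_rand();
        e2 = exp_rand();
      } while (e1 * e1 > 2.0 * e2 / t);
      x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      if (unif_rand() <= std::exp(-0.5 * z * z * x)) break;
    }
  } else {
    double mu = 1.0 / z;
    for (;;) {
      double y = norm_rand();
      y = y * y;
      double muy = mu * y;
      x = mu + 0.5 * mu * muy - 0.5 * mu * std::sqrt(4.0 * muy + muy * muy);
      if (unif_rand() > mu / (mu + x)) x = mu * mu / x;
      if (x <= t) break;
    }
  }
  return x;
}

void pg_setup(double z, PGParams& par) {
  par.h = std::fabs(z) * 0.5;
  par.K = M_PI * M_PI / 8.0 + 0.5 * par.h * par.h;
  double p_exp = (M_PI / (2.0 * par.K)) * std::exp(-par.K * TRUNC);
  double p_ig = 2.0 * std::exp(-par.h) * pigauss(TRUNC, par.h);
  par.r_exp = p_exp / (p_exp + p_ig);
}

double rpg1_draw(const PGParams& par) {
  for (;;) {
    double x;
    if (unif_rand() < par.r_exp) {
      x = TRUNC + exp_rand() / par.K;
    } else {
      x = rtigauss(par.h, TRUNC);
    }
    // squeeze with the partial alternating sums
    double s = a_coef(0, x);
    double y = unif_rand() * s;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (y <= s) return x / 4.0;
      } else {
        s += a_coef(n, x);
        if (y > s) break;
      }
    }
  }
}

double rpg1(double z) {
  PGParams par;
  pg_setup(z, par);
  return rpg1_draw(par);
}

// standard normal truncated to (a, Inf): normal rejection for easy cases,
// Robert's translated-exponential rejection deep in the tail
static double rtnorm_std_lower(double a) {
  double z;
  if (a < 0.45) {
    do {
      z = norm_rand();
    } while (z <= a);
  } else {
    double lambda = 0.5 * (a + std::sqrt(a * a + 4.0));
    for (;;) {
      z = a + exp_rand() / lambda;
      double d = z - lambda;
      if (unif_rand() <= std::exp(-0.5 * d * d)) break;
    }
  }
  return z;
}

double rtnorm_pos(double m, double sd) {
  return m + sd * rtnorm_std_lower(-m / sd);
}

// N(m, sd^2) truncated to (lo, hi); either bound may be infinite
double rtnorm_ab(double m, double sd, double lo, double hi) {
  double a = (lo - m) / sd, b = (hi - m) / sd;
  if (a == R_NegInf && b == R_PosInf) return m + sd * norm_rand();
  bool flip = false;
  if (b != R_PosInf && (a == R_NegInf || b < 0.0)) {
    // reflect so the near bound is the lower one
    double t = a; a = -b; b = -t;
    flip = true;
  }
  double z;
  if (b == R_PosInf) {
    z = rtnorm_std_lower(a);
  } else if (a < 0.45) {
    do {
      z = norm_rand();
    } while (z <= a || z >= b);
  } else {
    double lambda = 0.5 * (a + std::sqrt(a * a + 4.0));
    for (;;) {
      z = a + exp_rand() / lambda;
      if (z >= b) continue;
      double d = z - lambda;
      if (unif_rand() <= std::exp(-0.5 * d * d)) break;
    }
  }
  if (flip) z = -z;
  return m + sd * z;
}

// [[Rcpp::export(name = ".rpg_cpp")]]
NumericVector rpg_cpp(int n, NumericVector z) {
  NumericVector out(n);
  int nz = z.size();
  PGParams par;
  double last = R_PosInf;
  for (int i = 0; i < n; ++i) {
    double zi = z[i % nz];
    if (!R_finite(zi)) stop("non-finite tilting parameter in PG draw");
    if (zi != last) { pg_setup(zi, par); last = zi; }
    out[i] = rpg1_draw(par);
  }
  return out;
}

// [[Rcpp::export(name = ".rtnorm_interval_cpp")]]
NumericVector rtnorm_interval_cpp(int n, NumericVector mean, NumericVector sd,
                                  double lo, double hi) {
  NumericVector out(n);
  int nm = mean.size(), ns = sd.size();
  for (int i = 0; i < n; ++i) {
    out[i] = rtnorm_ab(mean[i % nm], sd[i % ns], lo, hi);
  }
  return out;
}
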