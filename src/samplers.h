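#ifndef DINAPG_SAMPLERS_H
#define DINAPG_SAMPLERS_H

// precomputed proposal constants for PG(1, z) draws at a fixed tilt z
struct PGParams {
  double h;      // |z| / 2
  double K;      // pi^2/8 + h^2/2
  double r_exp;  // probability of the exponential-tail proposal component
};

void pg_setup(double z, PGParams& par);
double rpg1_draw(const PGParams& par);
double rpg1(double z);
double rtnorm_pos(double m, double sd);
double rtnorm_ab(double m, double sd, double lo, double hi);

#endif
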