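#ifndef ESFM_SYSTEMS_H
#define ESFM_SYSTEMS_H

#include <Rcpp.h>
#include <cmath>
#include <vector>

// Builtin potential codes (kept in sync with R-side registry in R/systems.R)
enum PotCode {
  POT_HARMONIC_1D = 1,
  POT_DOUBLE_WELL_1D = 2,
  POT_GAUSSIAN_2D = 3,
  POT_MULLER_BROWN = 4,
  POT_DIHEDRAL_CHAIN = 5
};

// Evaluate raw (untransformed) potential energy and gradient at x (length dim).
// grad may be NULL when only the energy is needed.
double pot_eval_raw(int code, const double* par, const double* x, int dim,
                    double* grad);

// Affine-wrapped evaluation: u(x) = escale * u0((x - offset)/scale),
// grad_i = escale/scale_i * g0_i.  Buffers xs and gs must hold dim doubles.
inline double pot_eval(int code, const double* par, const double* x, int dim,
                       const double* offset, const double* scale, double escale,
                       double* grad, double* xs, double* gs) {
  for (int i = 0; i < dim; ++i) xs[i] = (x[i] - offset[i]) / scale[i];
  double u = pot_eval_raw(code, par, xs, dim, grad ? gs : (double*)0);
  if (grad) {
    for (int i = 0; i < dim; ++i) grad[i] = escale / scale[i] * gs[i];
  }
  return escale * u;
}

// Dihedral angle over beads (r1..r4) stored as x[0..11]; IUPAC sign,
// range (-pi, pi].  If grad != NULL it receives d(phi)/dx (12 values).
// Returns NA (and sets ok=false) for collinear triples.
double dihedral_angle(const double* x, double* grad, bool* ok);

#endif
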