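#include "systems.h"
using namespace Rcpp;

static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }

double dihedral_angle(const double* x, double* grad, bool* ok) {
  // beads r1..r4 at x[0..2], x[3..5], x[6..8], x[9..11]
  double b1[3], b2[3], b3[3], n1[3], n2[3], m[3];
  for (int k = 0; k < 3; ++k) {
    b1[k] = x[3 + k] - x[k];
    b2[k] = x[6 + k] - x[3 + k];
    b3[k] = x[9 + k] - x[6 + k];
  }
  cross3(b1, b2, n1);
  cross3(b2, b3, n2);
  double n1sq = dot3(n1, n1), n2sq = dot3(n2, n2), lb2 = norm3(b2);
  if (ok) *ok = true;
  if (n1sq < 1e-18 || n2sq < 1e-18 || lb2 < 1e-12) {
    if (ok) *ok = false;
    if (grad) for (int i = 0; i < 12; ++i) grad[i] = NA_REAL;
    return NA_REAL;
  }
  cross3(n1, n2, m);
  double phi = std::atan2(dot3(m, b2) / lb2, dot3(n1, n2));
  if (grad) {
    double F1[3], F4[3];
    double c1 = -lb2 / n1sq, c4 = lb2 / n2sq;
    for (int k = 0; k < 3; ++k) {
      F1[k] = c1 * n1[k];
      F4[k] = c4 * n2[k];
    }
    double t = dot3(b1, b2) / (lb2 * lb2);
    double s = dot3(b3, b2) / (lb2 * lb2);
    for (int k = 0; k < 3; ++k) {
      grad[0 + k] = F1[k];
      grad[3 + k] = -(1.0 + t) * F1[k] + s * F4[k];
      grad[6 + k] = t * F1[k] - (1.0 + s) * F4[k];
      grad[9 + k] = F4[k];
    }
  }
  return phi;
}

// angle at j between atoms i and k; adds gradient of 0.5*ka*(theta-theta0)^2
static double angle_term(const double* ri, const double* rj, const double* rk,
                         double ka, double theta0,
                         double* gi, double* gj, double* gk) {
  double u[3], v[3];
  for (int m = 0; m < 3; ++m) { u[m] = ri[m] - rj[m]; v[m] = rk[m] - rj[m]; }
  double lu = norm3(u), lv = norm3(v);
  double ct = dot3(u, v) / (lu * lv);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  double theta = std::acos(ct);
  double st = std::sqrt(1.0 - ct * ct);
  if (st < 1e-10) st = 1e-10;  // near-collinear guard
  double pref = ka * (theta - theta0);
  if (gi) {
    for (int m = 0; m < 3; ++m) {
      double dthi = (ct * u[m] / lu - v[m] / lv) / (lu * st);
      double dthk = (ct * v[m] / lv - u[m] / lu) / (lv * st);
      gi[m] += pref * dthi;
      gk[m] += pref * dthk;
      gj[m] += -pref * (dthi + dthk);
    }
  }
  return 0.5 * ka * (theta - theta0) * (theta - theta0);
}

double pot_eval_raw(int code, const double* par, const double* x, int dim,
                    double* grad) {
  switch (code) {
  case POT_HARMONIC_1D: {
    double k = par[0];
    if (grad) grad[0] = k * x[0];
    return 0.5 * k * x[0] * x[0];
  }
  case POT_DOUBLE_WELL_1D: {
    double a = par[0];
    double q = x[0] * x[0] - 1.0;
    if (grad) grad[0] = 4.0 * a * q * x[0];
    return a * q * q;
  }
  case POT_GAUSSIAN_2D: {
    double kx = par[0], ky = par[1];
    if (grad) { grad[0] = kx * x[0]; grad[1] = ky * x[1]; }
    return 0.5 * (kx * x[0] * x[0] + ky * x[1] * x[1]);
  }
  case POT_MULLER_BROWN: {
    // par: A[4], a[4], b[4], c[4], x0[4], y0[4]
    double u = 0.0, gx = 0.0, gy = 0.0;
    for (int k = 0; k < 4; ++k) {
      double A = par[k], a = par[4 + k], b = par[8 + k], c = par[12 + k];
      double dx = x[0] - par[16 + k], dy = x[1] - par[20 + k];
      double e = A * std::exp(a * dx * dx + b * dx * dy + c * dy * dy);
      u += e;
      gx += e * (2.0 * a * dx + b * dy);
      gy += e * (b * dx + 2.0 * c * dy);
    }
    if (grad) { grad[0] = gx; grad[1] = gy; }
    return u;
  }
  case POT_DIHEDRAL_CHAIN: {
    // par: kb, r0, ka, theta0, kd; x holds 4 beads in 3D
    double kb = par[0], r0 = par[1], ka = par[2], th0 = par[3], kd = par[4];
    double u = 0.0;
    double g[12];
    for (int i = 0; i < 12; ++i) g[i] = 0.0;
    for (int b = 0; b < 3; ++b) {  // bonds (1-2),(2-3),(3-4)
      const double* ri = x + 3 * b;
      const double* rj = x + 3 * (b + 1);
      double d[3];
      for (int m = 0; m < 3; ++m) d[m] = rj[m] - ri[m];
      double l = norm3(d);
      u += 0.5 * kb * (l - r0) * (l - r0);
      double pref = kb * (l - r0) / l;
      for (int m = 0; m < 3; ++m) {
        g[3 * (b + 1) + m] += pref * d[m];
        g[3 * b + m] -= pref * d[m];
      }
    }
    u += angle_term(x, x + 3, x + 6, ka, th0, g, g + 3, g + 6);
    u += angle_term(x + 3, x + 6, x + 9, ka, th0, g + 3, g + 6, g + 9);
    bool ok;
    double dphi[12];
    double phi = dihedral_angle(x, dphi, &ok);
    if (ok) {
      u += kd * (1.0 + std::cos(phi));
      double pref = -kd * std::sin(phi);
      for (int i = 0; i < 12; ++i) g[i] += pref * dphi[i];
    } else {
      u += 2.0 * kd;  // degenerate geometry; angle guard keeps this rare
    }
    if (grad) for (int i = 0; i < 12; ++i) grad[i] = g[i];
    return u;
  }
  default:
    Rcpp::stop("unknown potential code %d", code);
  }
  return NA_REAL;  // not reached
}

// ---- batched R-facing evaluators -------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_potential(int code, NumericVector par, NumericMatrix pos,
                            NumericVector offset, NumericVector scale,
                            double escale) {
  int n = pos.nrow(), dim = pos.ncol();
  NumericVector out(n);
  std::vector<double> x(dim), xs(dim), gs(dim);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < dim; ++j) x[j] = pos(i, j);
    out[i] = pot_eval(code, par.begin(), x.data(), dim, offset.begin(),
                      scale.begin(), escale, (double*)0, xs.data(), gs.data());
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_force(int code, NumericVector par, NumericMatrix pos,
                        NumericVector offset, NumericVector scale,
                        double escale) {
  int n = pos.nrow(), dim = pos.ncol();
  NumericMatrix out(n, dim);
  std::vector<double> x(dim), g(dim), xs(dim), gs(dim);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < dim; ++j) x[j] = pos(i, j);
    pot_eval(code, par.begin(), x.data(), dim, offset.begin(), scale.begin(),
             escale, g.data(), xs.data(), gs.data());
    for (int j = 0; j < dim; ++j) out(i, j) = -g[j];  // f = -grad u
  }
  return out;
}

// [[Rcpp::export]]
List cpp_dihedral(NumericMatrix pos) {
  // pos: frames x 12 (four beads, xyz each)
  int n = pos.nrow();
  if (pos.ncol() != 12) stop("dihedral CV requires 12 coordinate columns");
  NumericVector phi(n);
  NumericMatrix grad(n, 12);
  LogicalVector valid(n);
  std::vector<double> x(12), g(12);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < 12; ++j) x[j] = pos(i, j);
    bool ok;
    phi[i] = dihedral_angle(x.data(), g.data(), &ok);
    valid[i] = ok;
    for (int j = 0; j < 12; ++j) grad(i, j) = g[j];
  }
  return List::create(_["angle"] = phi, _["grad"] = grad, _["valid"] = valid);
}
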