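#include "systems.h"
using namespace Rcpp;

// Bias kinds (kept in sync with R/bias.R)
enum BiasKind {
  BIAS_NONE = 0,
  BIAS_UMBRELLA = 1,
  BIAS_GAUSSIAN = 2,
  BIAS_METAD = 3
};

static inline double wrap_diff(double d, double period) {
  if (period <= 0.0) return d;
  return d - period * std::floor(d / period + 0.5);
}

// Evaluate bias energy W(R) and gradient dW/dR at a CV point R (length ncv).
// deposits: flat array of ndep * (ncv + 1) doubles (centers..., height).
static double bias_eval(int kind, const double* par, const double* deposits,
                        int ndep, int ncv, double period, const double* R,
                        double* dWdR) {
  for (int k = 0; k < ncv; ++k) dWdR[k] = 0.0;
  switch (kind) {
  case BIAS_NONE:
    return 0.0;
  case BIAS_UMBRELLA: {
    double kappa = par[0], W = 0.0;
    for (int k = 0; k < ncv; ++k) {
      double d = wrap_diff(R[k] - par[1 + k], period);
      W += 0.5 * kappa * d * d;
      dWdR[k] = kappa * d;
    }
    return W;
  }
  case BIAS_GAUSSIAN: {
    double height = par[0], width = par[1];
    double q = 0.0;
    for (int k = 0; k < ncv; ++k) {
      double d = wrap_diff(R[k] - par[2 + k], period);
      q += d * d;
    }
    double W = height * std::exp(-q / (2.0 * width * width));
    for (int k = 0; k < ncv; ++k) {
      double d = wrap_diff(R[k] - par[2 + k], period);
      dWdR[k] = -W * d / (width * width);
    }
    return W;
  }
  case BIAS_METAD: {
    double sigma = par[1];
    double W = 0.0;
    for (int j = 0; j < ndep; ++j) {
      const double* row = deposits + j * (ncv + 1);
      double q = 0.0;
      for (int k = 0; k < ncv; ++k) {
        double d = wrap_diff(R[k] - row[k], period);
        q += d * d;
      }
      double g = row[ncv] * std::exp(-q / (2.0 * sigma * sigma));
      W += g;
      for (int k = 0; k < ncv; ++k) {
        double d = wrap_diff(R[k] - row[k], period);
        dWdR[k] += -g * d / (sigma * sigma);
      }
    }
    return W;
  }
  default:
    Rcpp::stop("unknown bias kind %d", kind);
  }
  return 0.0;
}

// [[Rcpp::export]]
List cpp_bias_eval(int kind, NumericVector par, NumericMatrix deposits,
                   NumericMatrix cv, double period) {
  int n = cv.nrow(), ncv = cv.ncol();
  int ndep = deposits.nrow();
  std::vector<double> dep(ndep * (ncv + 1));
  for (int j = 0; j < ndep; ++j)
    for (int k = 0; k < ncv + 1; ++k) dep[j * (ncv + 1) + k] = deposits(j, k);
  NumericVector W(n);
  NumericMatrix G(n, ncv);
  std::vector<double> R(ncv), g(ncv);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < ncv; ++k) R[k] = cv(i, k);
    W[i] = bias_eval(kind, par.begin(), dep.data(), ndep, ncv, period,
                     R.data(), g.data());
    for (int k = 0; k < ncv; ++k) G(i, k) = g[k];
  }
  return List::create(_["energy"] = W, _["grad"] = G);
}

// Overdamped Langevin (Euler-Maruyama) targeting exp(-beta*(u + W(cv(x)))).
//   dx = -grad(u + W) * dt + sqrt(2*dt/beta) * eta
// Reflective walls at domain box edges; aborts if a step overshoots the box
// by more than `margin` or the energy turns non-finite.
// cv_type: 0 = linear projection (cvmat, ncv x dim), 1 = four-bead dihedral.
// [[Rcpp::export]]
List cpp_langevin(int code, NumericVector par, NumericVector offset,
                  NumericVector scale, double escale, NumericVector x0,
                  double beta, double dt, double n_steps_d, int burn_in,
                  int stride, NumericMatrix dbox, double margin, int bias_kind,
                  int cv_type, NumericMatrix cvmat, NumericVector bias_par,
                  double period, NumericMatrix deposits0) {
  int dim = x0.size();
  long n_steps = (long)n_steps_d;
  int ncv = (cv_type == 1) ? 1 : cvmat.nrow();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> grad(dim), xs(dim), gs(dim), fbias(dim);
  std::vector<double> R(ncv), dWdR(ncv), dphi(12);

  // metadynamics state
  double h = 0, sigma = 0, gamma = 0;
  long tau = 0;
  std::vector<double> dep;
  int ndep = 0;
  // Grid-accumulated bias (1D CV): summing thousands of deposits per step is
  // O(ndep); instead each deposit is splatted once onto a fine grid
  // (spacing sigma/8) holding W and dW/dR, and per-step evaluation is linear
  // interpolation.  Interpolation error is ~h/512 per deposit.
  std::vector<double> Wg, Dg;
  double glo = 0, ghi = 0, gdx = 0;
  int ng = 0;
  bool periodic = (cv_type == 1);
  if (bias_kind == BIAS_METAD) {
    h = bias_par[0];
    sigma = bias_par[1];
    tau = (long)bias_par[2];
    gamma = bias_par[3];
    if (ncv != 1) stop("metadynamics supports a single CV");
    if (periodic) {
      glo = -M_PI; ghi = M_PI;
    } else {
      double lo = 0, hi = 0;
      for (int j = 0; j < dim; ++j) {
        double a = cvmat(0, j) * dbox(0, j), b = cvmat(0, j) * dbox(1, j);
        lo += std::min(a, b); hi += std::max(a, b);
      }
      double pad = margin + 8.0 * sigma;
      glo = lo - pad; ghi = hi + pad;
    }
    gdx = sigma / 8.0;
    ng = (int)std::ceil((ghi - glo) / gdx) + 1;
    Wg.assign(ng, 0.0);
    Dg.assign(ng, 0.0);
    ndep = deposits0.nrow();
    dep.resize((size_t)ndep * 2);
    for (int j = 0; j < ndep; ++j) {
      dep[j * 2] = deposits0(j, 0);
      dep[j * 2 + 1] = deposits0(j, 1);
    }
  }
  double cut = 8.0 * sigma;
  auto metad_splat = [&](double c0, double hj) {
    for (int i = 0; i < ng; ++i) {
      double gx = glo + i * gdx;
      double d = wrap_diff(gx - c0, periodic ? period : 0.0);
      if (std::fabs(d) > cut) continue;
      double g = hj * std::exp(-d * d / (2.0 * sigma * sigma));
      Wg[i] += g;
      Dg[i] += -g * d / (sigma * sigma);
    }
  };
  if (bias_kind == BIAS_METAD)
    for (int j = 0; j < ndep; ++j) metad_splat(dep[j * 2], dep[j * 2 + 1]);
  auto metad_eval = [&](double Rv, double* dWout) -> double {
    double r = Rv;
    if (periodic) r = r - period * std::floor((r - glo) / period);
    if (r < glo) r = glo;
    if (r > ghi) r = ghi;
    double u = (r - glo) / gdx;
    int i0 = (int)u;
    if (i0 >= ng - 1) i0 = ng - 2;
    double w = u - i0;
    *dWout = (1.0 - w) * Dg[i0] + w * Dg[i0 + 1];
    return (1.0 - w) * Wg[i0] + w * Wg[i0 + 1];
  };

  long n_frames = 0;
  if (n_steps > burn_in)
    n_frames = (n_steps - burn_in - 1) / stride + 1;
  NumericMatrix pos_out(n_frames, dim), fb_out(n_frames, dim),
      cv_out(n_frames, ncv);
  NumericVector wbias_out(n_frames);

  double noise_scale = std::sqrt(2.0 * dt / beta);
  RNGScope rng;
  long frame = 0;
  for (long step = 0; step < n_steps; ++step) {
    // CV value and Jacobian handle
    bool cv_ok = true;
    if (ncv > 0 && bias_kind != BIAS_NONE) {
      if (cv_type == 1) {
        R[0] = dihedral_angle(x.data(), dphi.data(), &cv_ok);
      } else {
        for (int k = 0; k < ncv; ++k) {
          double s = 0.0;
          for (int j = 0; j < dim; ++j) s += cvmat(k, j) * x[j];
          R[k] = s;
        }
      }
    }
    // metadynamics deposition (before force evaluation on deposit steps)
    if (bias_kind == BIAS_METAD && step > 0 && step % tau == 0 && cv_ok) {
      double dtmp;
      double Wtau = metad_eval(R[0], &dtmp);
      double heff = h * std::exp(-Wtau * beta / (gamma - 1.0));
      dep.push_back(R[0]);
      dep.push_back(heff);
      ++ndep;
      metad_splat(R[0], heff);
    }
    // forces
    double u = pot_eval(code, par.begin(), x.data(), dim, offset.begin(),
                        scale.begin(), escale, grad.data(), xs.data(),
                        gs.data());
    double W = 0.0;
    for (int j = 0; j < dim; ++j) fbias[j] = -grad[j];
    if (bias_kind != BIAS_NONE && cv_ok) {
      if (bias_kind == BIAS_METAD)
        W = metad_eval(R[0], &dWdR[0]);
      else
        W = bias_eval(bias_kind, bias_par.begin(), dep.data(), ndep, ncv,
                      period, R.data(), dWdR.data());
      if (cv_type == 1) {
        for (int j = 0; j < dim; ++j) fbias[j] -= dWdR[0] * dphi[j];
      } else {
        for (int k = 0; k < ncv; ++k)
          for (int j = 0; j < dim; ++j) fbias[j] -= dWdR[k] * cvmat(k, j);
      }
    }
    if (!std::isfinite(u) || !std::isfinite(W))
      stop("non-finite energy encountered at step %ld", step);
    // record
    if (step >= burn_in && (step - burn_in) % stride == 0) {
      for (int j = 0; j < dim; ++j) {
        pos_out(frame, j) = x[j];
        fb_out(frame, j) = fbias[j];
      }
      for (int k = 0; k < ncv; ++k) cv_out(frame, k) = (bias_kind == BIAS_NONE) ? NA_REAL : R[k];
      wbias_out[frame] = W;
      ++frame;
    }
    // Euler-Maruyama update with reflective walls
    for (int j = 0; j < dim; ++j) {
      double xn = x[j] + fbias[j] * dt + noise_scale * norm_rand();
      double lo = dbox(0, j), hi = dbox(1, j);
      if (xn < lo - margin || xn > hi + margin)
        stop("trajectory escaped the domain box at step %ld (coordinate %d); "
             "reduce dt or widen the box", step, j + 1);
      for (int it = 0; it < 50 && (xn < lo || xn > hi); ++it) {
        if (xn < lo) xn = 2.0 * lo - xn;
        if (xn > hi) xn = 2.0 * hi - xn;
      }
      x[j] = xn;
    }
  }

  NumericMatrix dep_out(ndep, ncv + 1);
  for (int j = 0; j < ndep; ++j)
    for (int k = 0; k < ncv + 1; ++k) dep_out(j, k) = dep[j * (ncv + 1) + k];
  return List::create(_["positions"] = pos_out, _["biased_forces"] = fb_out,
                      _["bias_energy"] = wbias_out, _["cv"] = cv_out,
                      _["deposits"] = dep_out, _["n_frames"] = (double)n_frames);
}
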