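// RBF-feature neural network for a 1D CG potential U(R; theta), with the
// force -dU/dR propagated analytically (forward-mode tangent) and the
// force-matching loss gradient with respect to theta computed by
// reverse-mode differentiation through the tangent computation.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;

struct NetShape {
  arma::ivec sizes;  // c(K, hidden..., 1)
  int L;             // number of dense layers
};

static NetShape shape_from(IntegerVector sizes) {
  NetShape s;
  s.sizes = arma::ivec(sizes.size());
  for (int i = 0; i < sizes.size(); ++i) s.sizes[i] = sizes[i];
  s.L = sizes.size() - 1;
  return s;
}

static int theta_length(const NetShape& s) {
  int n = 0;
  for (int l = 1; l <= s.L; ++l) n += s.sizes[l] * s.sizes[l - 1] + s.sizes[l];
  return n;
}

static void unpack(const NetShape& s, const vec& theta, std::vector<mat>& W,
                   std::vector<vec>& b) {
  W.resize(s.L + 1);
  b.resize(s.L + 1);
  int off = 0;
  for (int l = 1; l <= s.L; ++l) {
    int nr = s.sizes[l], nc = s.sizes[l - 1];
    W[l] = mat(theta.memptr() + off, nr, nc);
    off += nr * nc;
    b[l] = vec(theta.memptr() + off, nr);
    off += nr;
  }
}

// Forward pass: returns z (activations) and t (d z / d x tangents) per layer.
// Hidden layers use tanh; output layer is linear (scalar).
static void forward(const NetShape& s, const std::vector<mat>& W,
                    const std::vector<vec>& b, const rowvec& x,
                    const vec& centers, double sigma, std::vector<mat>& z,
                    std::vector<mat>& t) {
  int B = x.n_cols;
  int K = centers.n_elem;
  z.assign(s.L + 1, mat());
  t.assign(s.L + 1, mat());
  mat D = arma::repmat(x, K, 1) - arma::repmat(centers, 1, B);  // K x B
  mat Phi = arma::exp(-arma::square(D) / (2.0 * sigma * sigma));
  z[0] = Phi;
  t[0] = Phi % (-D / (sigma * sigma));
  for (int l = 1; l <= s.L; ++l) {
    mat S = W[l] * z[l - 1];
    S.each_col() += b[l];
    if (l < s.L) {
      z[l] = arma::tanh(S);
      t[l] = (1.0 - arma::square(z[l])) % (W[l] * t[l - 1]);
    } else {
      z[l] = S;                // linear output (1 x B)
      t[l] = W[l] * t[l - 1];  // dU/dx
    }
  }
}

// [[Rcpp::export]]
List cpp_net_eval(NumericVector centers_, double sigma, IntegerVector sizes,
                  NumericVector theta_, NumericVector x_) {
  NetShape s = shape_from(sizes);
  vec theta(theta_.begin(), theta_.size());
  if ((int)theta.n_elem != theta_length(s)) stop("theta length mismatch");
  vec centers(centers_.begin(), centers_.size());
  rowvec x(x_.begin(), x_.size());
  std::vector<mat> W;
  std::vector<vec> b;
  unpack(s, theta, W, b);
  std::vector<mat> z, t;
  forward(s, W, b, x, centers, sigma, z, t);
  NumericVector energy(x_.size()), force(x_.size());
  for (int i = 0; i < x_.size(); ++i) {
    energy[i] = z[s.L](0, i);
    force[i] = -t[s.L](0, i);
  }
  return List::create(_["energy"] = energy, _["force"] = force);
}

// Force-matching loss  L = mean_i (G_i + U'(x_i))^2  and dL/dtheta.
// [[Rcpp::export]]
List cpp_net_loss_grad(NumericVector centers_, double sigma,
                       IntegerVector sizes, NumericVector theta_,
                       NumericVector x_, NumericVector G_) {
  NetShape s = shape_from(sizes);
  vec theta(theta_.begin(), theta_.size());
  if ((int)theta.n_elem != theta_length(s)) stop("theta length mismatch");
  vec centers(centers_.begin(), centers_.size());
  rowvec x(x_.begin(), x_.size());
  rowvec G(G_.begin(), G_.size());
  int B = x.n_cols;
  std::vector<mat> W;
  std::vector<vec> b;
  unpack(s, theta, W, b);
  std::vector<mat> z, t;
  forward(s, W, b, x, centers, sigma, z, t);

  rowvec ty = t[s.L].row(0);  // U'(x)
  rowvec r = G + ty;
  double loss = arma::mean(arma::square(r));
  rowvec rho = (2.0 / B) * r;  // dL/d(ty)

  std::vector<mat> gW(s.L + 1);
  std::vector<vec> gb(s.L + 1);
  // Output layer: U = W_L z_{L-1} + b_L, ty = W_L t_{L-1}
  gW[s.L] = t[s.L - 1] * rho.t();       // (n_{L-1} x 1) -> transposed below
  gW[s.L] = gW[s.L].t();                // 1 x n_{L-1}
  gb[s.L] = vec(1, arma::fill::zeros);  // b_L does not enter ty
  mat Lt = W[s.L].t() * rho;            // adjoint on t_{L-1}, n_{L-1} x B
  mat Lz(s.sizes[s.L - 1], B, arma::fill::zeros);  // adjoint on z_{L-1}
  for (int l = s.L - 1; l >= 1; --l) {
    mat ap = 1.0 - arma::square(z[l]);       // tanh'
    mat Wt = W[l] * t[l - 1];                // pre-activation tangent
    mat mu = Lz % ap + Lt % Wt % (-2.0 * z[l] % ap);  // adjoint on s_l
    mat nu = Lt % ap;                        // adjoint on (W_l t_{l-1})
    gW[l] = mu * z[l - 1].t() + nu * t[l - 1].t();
    gb[l] = arma::sum(mu, 1);
    Lz = W[l].t() * mu;
    Lt = W[l].t() * nu;
  }
  NumericVector grad(theta_.size());
  int off = 0;
  for (int l = 1; l <= s.L; ++l) {
    int nr = s.sizes[l], nc = s.sizes[l - 1];
    for (int c = 0; c < nc; ++c)
      for (int rI = 0; rI < nr; ++rI) grad[off++] = gW[l](rI, c);
    for (int rI = 0; rI < nr; ++rI) grad[off++] = gb[l](rI);
  }
  return List::create(_["loss"] = loss, _["grad"] = grad);
}
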