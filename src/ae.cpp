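// Concentration-anchored convolutional autoencoder.
//
// Encoder: conv(16 filters, kernel 3, ReLU, same padding, stride 1)
//       -> conv(16 filters, kernel 5, ReLU, same padding, stride 1)
//       -> flatten -> dense 128 (LeakyReLU 0.02) -> dense latent (LeakyReLU).
// Decoder: single dense linear map latent -> channels, no bias, weights
// projected onto >= 0 after every optimizer step.
// Loss: mean spectral angle distance (SAD) between input and reconstruction
// plus w_c times the mean squared error between latent activations and the
// known component concentrations (the anchoring term).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <random>

using namespace arma;

namespace {

struct AEParams {
  mat W1c, W2c, Wd1, Wd2, Wdec;
  vec b1c, b2c, bd1, bd2;
};

AEParams params_from_list(const Rcpp::List& p) {
  AEParams q;
  q.W1c = Rcpp::as<mat>(p["W1c"]); q.b1c = Rcpp::as<vec>(p["b1c"]);
  q.W2c = Rcpp::as<mat>(p["W2c"]); q.b2c = Rcpp::as<vec>(p["b2c"]);
  q.Wd1 = Rcpp::as<mat>(p["Wd1"]); q.bd1 = Rcpp::as<vec>(p["bd1"]);
  q.Wd2 = Rcpp::as<mat>(p["Wd2"]); q.bd2 = Rcpp::as<vec>(p["bd2"]);
  q.Wdec = Rcpp::as<mat>(p["Wdec"]);
  return q;
}

Rcpp::List params_to_list(const AEParams& q) {
  return Rcpp::List::create(
      Rcpp::Named("W1c") = q.W1c, Rcpp::Named("b1c") = q.b1c,
      Rcpp::Named("W2c") = q.W2c, Rcpp::Named("b2c") = q.b2c,
      Rcpp::Named("Wd1") = q.Wd1, Rcpp::Named("bd1") = q.bd1,
      Rcpp::Named("Wd2") = q.Wd2, Rcpp::Named("bd2") = q.bd2,
      Rcpp::Named("Wdec") = q.Wdec);
}

inline mat leaky(const mat& x, double a) {
  mat y(size(x));
  const double* xp = x.memptr(); double* yp = y.memptr();
  for (uword i = 0; i < x.n_elem; ++i) yp[i] = xp[i] > 0 ? xp[i] : a * xp[i];
  return y;
}
inline mat relu(const mat& x) {
  mat y(size(x));
  const double* xp = x.memptr(); double* yp = y.memptr();
  for (uword i = 0; i < x.n_elem; ++i) yp[i] = xp[i] > 0 ? xp[i] : 0.0;
  return y;
}
// d *= activation'(pre), fused in place
inline void mask_relu(mat& d, const mat& pre) {
  double* dp = d.memptr(); const double* pp = pre.memptr();
  for (uword i = 0; i < d.n_elem; ++i) if (pp[i] <= 0) dp[i] = 0.0;
}
inline void mask_leaky(mat& d, const mat& pre, double a) {
  double* dp = d.memptr(); const double* pp = pre.memptr();
  for (uword i = 0; i < d.n_elem; ++i) if (pp[i] <= 0) dp[i] *= a;
}

// im2col for a batch of 1-D feature maps stacked sample-major in rows.
// A: (m*b) x cin feature rows; out: (m*b) x (k*cin), zero-padded borders.
void im2col(const mat& A, int m, int b, int k, mat& M) {
  const int cin = A.n_cols, pad = (k - 1) / 2;
  M.zeros(m * (uword)b, (uword)k * cin);
  for (int i = 0; i < m; ++i) {
    const int base = i * b;
    for (int dk = 0; dk < k; ++dk) {
      const int off = dk - pad;
      const int t0 = std::max(0, -off), t1 = std::min(b - 1, b - 1 - off);
      if (t0 > t1) continue;
      M.submat(base + t0, dk * cin, base + t1, (dk + 1) * cin - 1) =
          A.rows(base + t0 + off, base + t1 + off);
    }
  }
}

// transpose of im2col: scatter-add column blocks back onto feature rows
void col2im(const mat& dM, int m, int b, int k, mat& dA) {
  const int cin = dA.n_cols, pad = (k - 1) / 2;
  dA.zeros();
  for (int i = 0; i < m; ++i) {
    const int base = i * b;
    for (int dk = 0; dk < k; ++dk) {
      const int off = dk - pad;
      const int t0 = std::max(0, -off), t1 = std::min(b - 1, b - 1 - off);
      if (t0 > t1) continue;
      dA.rows(base + t0 + off, base + t1 + off) +=
          dM.submat(base + t0, dk * cin, base + t1, (dk + 1) * cin - 1);
    }
  }
}

struct Cache {
  mat M1, Z1, M2, Z2, F, H1pre, H1, Zpre, Z, Xhat;
};

// X: b x m (columns are spectra)
void forward(const AEParams& q, const mat& X, Cache& c) {
  const int b = X.n_rows, m = X.n_cols;
  const int k1 = q.W1c.n_rows, f1 = q.W1c.n_cols;
  const int k2 = q.W2c.n_rows / f1, f2 = q.W2c.n_cols;
  mat A0(m * (uword)b, 1);
  for (int i = 0; i < m; ++i) A0.col(0).subvec(i * b, (i + 1) * b - 1) = X.col(i);
  im2col(A0, m, b, k1, c.M1);
  c.Z1 = c.M1 * q.W1c;
  c.Z1.each_row() += q.b1c.t();
  mat A1 = relu(c.Z1);
  im2col(A1, m, b, k2, c.M2);
  c.Z2 = c.M2 * q.W2c;
  c.Z2.each_row() += q.b2c.t();
  mat A2 = relu(c.Z2);
  c.F.set_size(b * (uword)f2, m);
  for (int i = 0; i < m; ++i)
    c.F.col(i) = vectorise(A2.rows(i * b, (i + 1) * b - 1));
  c.H1pre = q.Wd1 * c.F;
  c.H1pre.each_col() += q.bd1;
  c.H1 = leaky(c.H1pre, 0.02);
  c.Zpre = q.Wd2 * c.H1;
  c.Zpre.each_col() += q.bd2;
  c.Z = leaky(c.Zpre, 0.02);
  c.Xhat = q.Wdec * c.Z;
}

// SAD between columns of X and Xhat plus gradient wrt Xhat (d mean SAD)
double sad_batch(const mat& X, const mat& Xhat, mat& dXhat) {
  const int m = X.n_cols;
  double total = 0.0;
  dXhat.zeros(size(Xhat));
  for (int i = 0; i < m; ++i) {
    const vec x = X.col(i), xh = Xhat.col(i);
    const double nx = norm(x), nxh = norm(xh);
    if (nx < 1e-12 || nxh < 1e-12) continue;   // zero vector: no angle defined
    double u = dot(x, xh) / (nx * nxh);
    u = std::min(1.0 - 1e-9, std::max(-1.0 + 1e-9, u));
    total += std::acos(u);
    const double denom = std::sqrt(std::max(1.0 - u * u, 1e-12));
    dXhat.col(i) += (-1.0 / denom) * (x / (nx * nxh) - u * xh / (nxh * nxh)) / m;
  }
  return total / m;
}

struct Adam {
  mat m_, v_;
  void init(const mat& w) { m_.zeros(size(w)); v_.zeros(size(w)); }
  // single fused pass: update moments and weights in place, no temporaries
  void step(mat& w, const mat& g, double lr, long t) {
    const double a = lr * std::sqrt(1.0 - std::pow(0.999, (double)t)) /
                     (1.0 - std::pow(0.9, (double)t));
    double* wp = w.memptr();
    double* mp = m_.memptr();
    double* vp = v_.memptr();
    const double* gp = g.memptr();
    const uword nel = w.n_elem;
    for (uword i = 0; i < nel; ++i) {
      const double gi = gp[i];
      mp[i] = 0.9 * mp[i] + 0.1 * gi;
      vp[i] = 0.999 * vp[i] + 0.001 * gi * gi;
      wp[i] -= a * mp[i] / (std::sqrt(vp[i]) + 1e-8);
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".ae_init_cpp")]]
Rcpp::List ae_init_cpp(int n_channels, int latent_dim, int conv1_filters,
                       int conv1_kernel, int conv2_filters, int conv2_kernel,
                       int dense1_units, int seed) {
  std::mt19937 rng(seed);
  auto glorot = [&](int rows, int cols, int fan_in, int fan_out) {
    const double lim = std::sqrt(6.0 / (fan_in + fan_out));
    std::uniform_real_distribution<double> U(-lim, lim);
    mat w(rows, cols);
    for (uword j = 0; j < w.n_cols; ++j)        // column-major fill, fixed order
      for (uword i = 0; i < w.n_rows; ++i) w(i, j) = U(rng);
    return w;
  };
  AEParams q;
  q.W1c = glorot(conv1_kernel, conv1_filters, conv1_kernel, conv1_kernel * conv1_filters);
  q.b1c = zeros<vec>(conv1_filters);
  q.W2c = glorot(conv2_kernel * conv1_filters, conv2_filters,
                 conv2_kernel * conv1_filters, conv2_kernel * conv2_filters);
  q.b2c = zeros<vec>(conv2_filters);
  const int flat = n_channels * conv2_filters;
  q.Wd1 = glorot(dense1_units, flat, flat, dense1_units);
  q.bd1 = zeros<vec>(dense1_units);
  q.Wd2 = glorot(latent_dim, dense1_units, dense1_units, latent_dim);
  q.bd2 = zeros<vec>(latent_dim);
  q.Wdec = abs(glorot(n_channels, latent_dim, latent_dim, n_channels));
  return params_to_list(q);
}

// [[Rcpp::export(name = ".ae_forward_cpp")]]
Rcpp::List ae_forward_cpp(const Rcpp::List& params, const arma::mat& X) {
  AEParams q = params_from_list(params);
  Cache c;
  forward(q, X, c);
  return Rcpp::List::create(Rcpp::Named("latent") = c.Z,
                            Rcpp::Named("reconstruction") = c.Xhat);
}

// [[Rcpp::export(name = ".ae_train_cpp")]]
Rcpp::List ae_train_cpp(const Rcpp::List& params, const arma::mat& X,
                        const arma::mat& targets, double w_c, double lr,
                        int max_epochs, int batch_size, int patience,
                        double min_delta, int seed) {
  AEParams q = params_from_list(params);
  const int b = X.n_rows, n = X.n_cols;
  const int latent = q.Wdec.n_cols;
  const int f1 = q.W1c.n_cols, k2 = q.W2c.n_rows / f1, f2 = q.W2c.n_cols;
  if ((int)targets.n_rows != latent || (int)targets.n_cols != n)
    Rcpp::stop("targets must be latent_dim x n_spectra");

  Adam aW1, ab1, aW2, ab2, aWd1, abd1, aWd2, abd2, aWdec;
  aW1.init(q.W1c); ab1.init(mat(q.b1c)); aW2.init(q.W2c); ab2.init(mat(q.b2c));
  aWd1.init(q.Wd1); abd1.init(mat(q.bd1)); aWd2.init(q.Wd2); abd2.init(mat(q.bd2));
  aWdec.init(q.Wdec);

  std::mt19937 rng(seed + 1);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  std::vector<double> hist_total, hist_sad, hist_mse;
  double best = datum::inf;
  int wait = 0;
  long t = 0;
  Cache c;
  mat dXhat, dZ, dZpre, dH1, dH1pre, dF, dA2, dZ2, dM2, dA1, dZ1;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_sad = 0.0, ep_mse = 0.0;
    for (int start = 0; start < n; start += batch_size) {
      const int m = std::min(batch_size, n - start);
      mat Xb(b, m), Cb(latent, m);
      for (int i = 0; i < m; ++i) {
        Xb.col(i) = X.col(order[start + i]);
        Cb.col(i) = targets.col(order[start + i]);
      }
      forward(q, Xb, c);
      const double sad_term = sad_batch(Xb, c.Xhat, dXhat);
      const mat zerr = c.Z - Cb;
      const double mse_term = accu(square(zerr)) / (m * latent);
      const double loss = sad_term + w_c * mse_term;
      if (!std::isfinite(loss))
        Rcpp::stop("NaN/Inf training loss at epoch %d", epoch + 1);
      ep_sad += sad_term * m;
      ep_mse += mse_term * m;

      // backward
      dZ = q.Wdec.t() * dXhat + (2.0 * w_c / (m * latent)) * zerr;
      mat gWdec = dXhat * c.Z.t();
      dZpre = dZ; mask_leaky(dZpre, c.Zpre, 0.02);
      mat gWd2 = dZpre * c.H1.t();
      vec gbd2 = sum(dZpre, 1);
      dH1 = q.Wd2.t() * dZpre;
      dH1pre = dH1; mask_leaky(dH1pre, c.H1pre, 0.02);
      mat gWd1 = dH1pre * c.F.t();
      vec gbd1 = sum(dH1pre, 1);
      dF = q.Wd1.t() * dH1pre;
      dA2.set_size(m * (uword)b, f2);
      for (int i = 0; i < m; ++i)
        dA2.rows(i * b, (i + 1) * b - 1) = reshape(dF.col(i), b, f2);
      dZ2 = dA2; mask_relu(dZ2, c.Z2);
      mat gW2c = c.M2.t() * dZ2;
      vec gb2c = sum(dZ2, 0).t();
      dM2 = dZ2 * q.W2c.t();
      dA1.set_size(m * (uword)b, f1);
      col2im(dM2, m, b, k2, dA1);
      dZ1 = dA1; mask_relu(dZ1, c.Z1);
      mat gW1c = c.M1.t() * dZ1;
      vec gb1c = sum(dZ1, 0).t();

      ++t;
      aW1.step(q.W1c, gW1c, lr, t);
      { mat bw(q.b1c); ab1.step(bw, mat(gb1c), lr, t); q.b1c = bw.col(0); }
      aW2.step(q.W2c, gW2c, lr, t);
      { mat bw(q.b2c); ab2.step(bw, mat(gb2c), lr, t); q.b2c = bw.col(0); }
      aWd1.step(q.Wd1, gWd1, lr, t);
      { mat bw(q.bd1); abd1.step(bw, mat(gbd1), lr, t); q.bd1 = bw.col(0); }
      aWd2.step(q.Wd2, gWd2, lr, t);
      { mat bw(q.bd2); abd2.step(bw, mat(gbd2), lr, t); q.bd2 = bw.col(0); }
      aWdec.step(q.Wdec, gWdec, lr, t);
      q.Wdec = max(q.Wdec, zeros(size(q.Wdec)));   // non-negativity projection
    }
    const double mean_sad = ep_sad / n, mean_mse = ep_mse / n;
    const double ep_loss = mean_sad + w_c * mean_mse;
    hist_total.push_back(ep_loss);
    hist_sad.push_back(mean_sad);
    hist_mse.push_back(mean_mse);
    if (ep_loss < best - min_delta) {
      best = ep_loss;
      wait = 0;
    } else if (++wait >= patience) break;        // early stopping
  }

  return Rcpp::List::create(
      Rcpp::Named("params") = params_to_list(q),
      Rcpp::Named("loss_total") = hist_total,
      Rcpp::Named("loss_sad") = hist_sad,
      Rcpp::Named("loss_mse") = hist_mse);
}
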