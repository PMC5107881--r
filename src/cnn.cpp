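// 1D CNN forward/backward core: single conv+pool stage, two-class softmax
// output, momentum SGD. Layout conventions shared with the R layer functions:
// kernels are m x K, pooled activations flatten kernel-major (column-major
// P x K), dense weights are D x C with D = P*K, labels are 0/1. Per-sample
// loss weights implement class-balanced training on imbalanced folds.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Dims {
  int n, N, m, K, L, P, D, C;
  int conv_stride, pool_len, pool_stride;
};

// patch matrix: row s*L + i holds x_s[i*stride .. i*stride + m - 1], so the
// convolution of every sample with every kernel is one GEMM
mat build_patches(const mat& X, const Dims& d) {
  mat Xp(d.n * d.L, d.m);
  for (int s = 0; s < d.n; ++s)
    for (int i = 0; i < d.L; ++i)
      for (int a = 0; a < d.m; ++a)
        Xp(s * d.L + i, a) = X(s, i * d.conv_stride + a);
  return Xp;
}

inline double act(double u, int activation) {
  if (activation == 0) return u > 0.0 ? u : 0.0;   // rectifier
  return 1.0 / (1.0 + std::exp(-u));               // logistic
}

inline double act_grad(double u, double y, int activation) {
  if (activation == 0) return u > 0.0 ? 1.0 : 0.0;
  return y * (1.0 - y);
}

// preallocated intermediates for one batch size, reused across epochs
struct Work {
  mat U, Y, dY;    // (n_b*L) x K
  mat F, dF;       // n_b x D
  umat amax;       // n_b x D
  mat Z, Pm, G;    // n_b x C
  Work(int n_b, const Dims& d)
    : U(n_b * d.L, d.K), Y(n_b * d.L, d.K), dY(n_b * d.L, d.K),
      F(n_b, d.D), dF(n_b, d.D), amax(n_b, d.D),
      Z(n_b, d.C), Pm(n_b, d.C), G(n_b, d.C) {}
};

// forward + (optionally) backward over the n_b samples whose patch rows are
// in Xpb and whose labels/weights are lab/wts; gradients and the loss are
// weighted means over samples. Returns the batch loss.
double pass(const mat& Xpb, const ivec& lab, const vec& wts,
            const mat& kernels, const mat& Wd, const vec& bias,
            const Dims& d, int activation, int loss_type, bool want_grad,
            Work& w, mat& dK, mat& dW, vec& db) {
  const int n_b = lab.n_elem;
  w.U = Xpb * kernels;
  for (uword j = 0; j < w.U.n_elem; ++j) w.Y(j) = act(w.U(j), activation);

  for (int bi = 0; bi < n_b; ++bi) {
    for (int k = 0; k < d.K; ++k) {
      for (int c = 0; c < d.P; ++c) {
        int base = bi * d.L + c * d.pool_stride;
        double best = w.Y(base, k);
        int best_r = base;
        for (int a = 1; a < d.pool_len; ++a)
          if (w.Y(base + a, k) > best) { best = w.Y(base + a, k); best_r = base + a; }
        w.F(bi, k * d.P + c) = best;
        w.amax(bi, k * d.P + c) = best_r;
      }
    }
  }

  w.Z = w.F * Wd;
  w.Z.each_row() += bias.t();
  double loss = 0.0;
  for (int bi = 0; bi < n_b; ++bi) {
    double zmax = w.Z.row(bi).max();
    double denom = 0.0;
    for (int j = 0; j < d.C; ++j) denom += std::exp(w.Z(bi, j) - zmax);
    for (int j = 0; j < d.C; ++j)
      w.Pm(bi, j) = std::exp(w.Z(bi, j) - zmax) / denom;
    int l = lab(bi);
    if (loss_type == 0) {
      loss += wts(bi) * -std::log(std::max(w.Pm(bi, l), 1e-12));
    } else {
      for (int j = 0; j < d.C; ++j) {
        double t = (j == l) ? 1.0 : 0.0;
        loss += wts(bi) * (w.Pm(bi, j) - t) * (w.Pm(bi, j) - t);
      }
    }
  }
  loss /= n_b;
  if (!want_grad) return loss;

  for (int bi = 0; bi < n_b; ++bi) {
    int l = lab(bi);
    double ws = wts(bi) / n_b;
    if (loss_type == 0) {
      for (int j = 0; j < d.C; ++j)
        w.G(bi, j) = ws * (w.Pm(bi, j) - ((j == l) ? 1.0 : 0.0));
    } else {
      // through the softmax Jacobian:
      // g_j = p_j (2(p_j - t_j) - sum_c 2(p_c - t_c) p_c)
      double dot = 0.0;
      for (int c = 0; c < d.C; ++c)
        dot += 2.0 * (w.Pm(bi, c) - ((c == l) ? 1.0 : 0.0)) * w.Pm(bi, c);
      for (int j = 0; j < d.C; ++j)
        w.G(bi, j) = ws * w.Pm(bi, j) *
          (2.0 * (w.Pm(bi, j) - ((j == l) ? 1.0 : 0.0)) - dot);
    }
  }

  dW = w.F.t() * w.G;
  db = sum(w.G, 0).t();
  w.dF = w.G * Wd.t();
  w.dY.zeros();
  for (int bi = 0; bi < n_b; ++bi)
    for (int k = 0; k < d.K; ++k)
      for (int c = 0; c < d.P; ++c)
        w.dY(w.amax(bi, k * d.P + c), k) += w.dF(bi, k * d.P + c);
  for (uword j = 0; j < w.dY.n_elem; ++j)
    w.dY(j) *= act_grad(w.U(j), w.Y(j), activation);
  dK = Xpb.t() * w.dY;
  return loss;
}

Dims make_dims(const mat& X, const mat& kernels, const mat& Wd,
               int conv_stride, int pool_len, int pool_stride) {
  Dims d;
  d.n = X.n_rows; d.N = X.n_cols;
  d.m = kernels.n_rows; d.K = kernels.n_cols;
  d.conv_stride = conv_stride; d.pool_len = pool_len; d.pool_stride = pool_stride;
  if (d.N < d.m) Rcpp::stop("input length is shorter than the kernel");
  d.L = (d.N - d.m) / conv_stride + 1;
  if (d.L < pool_len) Rcpp::stop("feature map is shorter than the pool window");
  d.P = (d.L - pool_len) / pool_stride + 1;
  d.D = d.P * d.K;
  d.C = Wd.n_cols;
  if ((int)Wd.n_rows != d.D)
    Rcpp::stop("dense weight rows (%d) do not match pooled length x kernels (%d)",
               (int)Wd.n_rows, d.D);
  return d;
}

} // namespace

// [[Rcpp::export]]
Rcpp::List cnn_grad_cpp(const arma::mat& X, const arma::ivec& labels,
                        const arma::vec& weights, const arma::mat& kernels,
                        const arma::mat& dense_w, const arma::vec& bias,
                        int conv_stride, int pool_len, int pool_stride,
                        int activation, int loss_type) {
  Dims d = make_dims(X, kernels, dense_w, conv_stride, pool_len, pool_stride);
  mat Xp = build_patches(X, d);
  Work w(d.n, d);
  mat dK, dW; vec db;
  double loss = pass(Xp, labels, weights, kernels, dense_w, bias, d,
                     activation, loss_type, true, w, dK, dW, db);
  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("probs") = w.Pm,
    Rcpp::Named("kernel_grad") = dK,
    Rcpp::Named("dense_grad") = dW,
    Rcpp::Named("bias_grad") = db);
}

// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(const arma::mat& X, const arma::ivec& labels,
                         const arma::vec& weights, arma::mat kernels,
                         arma::mat dense_w, arma::vec bias, int conv_stride,
                         int pool_len, int pool_stride, int activation,
                         int loss_type, double lr, double momentum,
                         int epochs, int batch_mode, int momentum_form) {
  Dims d = make_dims(X, kernels, dense_w, conv_stride, pool_len, pool_stride);
  mat Xp = build_patches(X, d);
  mat vK(d.m, d.K, fill::zeros), vW(d.D, d.C, fill::zeros);
  vec vb(d.C, fill::zeros);
  vec trace(epochs, fill::zeros);
  mat dK, dW; vec db;

  // velocity update: plain heavy ball v <- mom*v - lr*g, w <- w + v;
  // "ema" (momentum-corrected) form v <- mom*v + (1-mom)*g, w <- w - lr*v
  auto update = [&](const mat& gK, const mat& gW, const vec& gb) {
    if (momentum_form == 0) {
      vK = momentum * vK - lr * gK;  kernels += vK;
      vW = momentum * vW - lr * gW;  dense_w += vW;
      vb = momentum * vb - lr * gb;  bias += vb;
    } else {
      vK = momentum * vK + (1.0 - momentum) * gK;  kernels -= lr * vK;
      vW = momentum * vW + (1.0 - momentum) * gW;  dense_w -= lr * vW;
      vb = momentum * vb + (1.0 - momentum) * gb;  bias -= lr * vb;
    }
  };

  if (batch_mode == 0) { // full batch: one weighted-mean-gradient update/epoch
    Work w(d.n, d);
    for (int e = 0; e < epochs; ++e) {
      trace(e) = pass(Xp, labels, weights, kernels, dense_w, bias, d,
                      activation, loss_type, true, w, dK, dW, db);
      update(dK, dW, db);
    }
  } else {               // per-sample updates in fixed data order
    Work w(1, d);
    ivec lab1(1); vec wt1(1);
    for (int e = 0; e < epochs; ++e) {
      double acc = 0.0;
      for (int s = 0; s < d.n; ++s) {
        lab1(0) = labels(s); wt1(0) = weights(s);
        mat Xpb = Xp.rows(s * d.L, (s + 1) * d.L - 1);
        acc += pass(Xpb, lab1, wt1, kernels, dense_w, bias, d,
                    activation, loss_type, true, w, dK, dW, db);
        update(dK, dW, db);
      }
      trace(e) = acc / d.n;
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("kernels") = kernels,
    Rcpp::Named("dense_weights") = dense_w,
    Rcpp::Named("dense_bias") = bias,
    Rcpp::Named("loss_trace") = trace);
}
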