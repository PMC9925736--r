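#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Mini-batch Adam training of a fully connected rectifier network with a
// linear output and mean-squared-error loss. Layer weights/biases and the
// per-epoch batch permutations are supplied by the caller (drawn from R's
// RNG), so results are reproducible from the R-side seed alone.
// [[Rcpp::export(name = ".mlp_train_cpp")]]
List mlp_train_cpp(List W0, List b0, NumericMatrix X, NumericVector y,
                   Nullable<NumericMatrix> Xval_, Nullable<NumericVector> yval_,
                   IntegerMatrix perms, int batch_size, double lr) {
  const int L = W0.size();
  const int n = X.nrow();
  const int epochs = perms.ncol();
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;

  std::vector<std::vector<double> > W(L), b(L), mW(L), vW(L), mb(L), vb(L);
  std::vector<int> din(L), dout(L);
  for (int l = 0; l < L; ++l) {
    NumericMatrix w = W0[l];
    NumericVector bb = b0[l];
    din[l] = w.nrow(); dout[l] = w.ncol();
    W[l].assign(w.begin(), w.end());          // column-major din x dout
    b[l].assign(bb.begin(), bb.end());
    mW[l].assign(W[l].size(), 0.0); vW[l].assign(W[l].size(), 0.0);
    mb[l].assign(b[l].size(), 0.0); vb[l].assign(b[l].size(), 0.0);
  }
  const int D = din[0];

  // forward pass for a set of row indices (or all rows when idx empty)
  auto forward_mse = [&](const NumericMatrix &M, const NumericVector &t) {
    double sse = 0.0;
    std::vector<double> a, znext;
    for (int i = 0; i < M.nrow(); ++i) {
      a.assign(D, 0.0);
      for (int j = 0; j < D; ++j) a[j] = M(i, j);
      for (int l = 0; l < L; ++l) {
        znext.assign(dout[l], 0.0);
        for (int k = 0; k < dout[l]; ++k) {
          double s = b[l][k];
          const double *wcol = &W[l][static_cast<size_t>(k) * din[l]];
          for (int j = 0; j < din[l]; ++j) s += a[j] * wcol[j];
          znext[k] = (l < L - 1 && s < 0) ? 0.0 : s;
        }
        a = znext;
      }
      const double e = a[0] - t[i];
      sse += e * e;
    }
    return sse / M.nrow();
  };

  NumericVector train_loss(epochs), val_loss(epochs);
  const bool has_val = Xval_.isNotNull();
  NumericMatrix Xval;
  NumericVector yval;
  if (has_val) { Xval = Xval_.get(); yval = yval_.get(); }

  // batch work buffers
  std::vector<std::vector<double> > acts(L + 1), zs(L);
  std::vector<double> delta, delta_prev;
  long step = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int start = 0; start < n; start += batch_size) {
      const int m = std::min(batch_size, n - start);
      // gather batch
      acts[0].assign(static_cast<size_t>(m) * D, 0.0);
      for (int r = 0; r < m; ++r) {
        const int row = perms(start + r, ep) - 1;
        for (int j = 0; j < D; ++j) acts[0][static_cast<size_t>(j) * m + r] = X(row, j);
      }
      // forward (activations column-major m x dout)
      for (int l = 0; l < L; ++l) {
        zs[l].assign(static_cast<size_t>(m) * dout[l], 0.0);
        for (int k = 0; k < dout[l]; ++k) {
          const double *wcol = &W[l][static_cast<size_t>(k) * din[l]];
          double *zcol = &zs[l][static_cast<size_t>(k) * m];
          for (int r = 0; r < m; ++r) zcol[r] = b[l][k];
          for (int j = 0; j < din[l]; ++j) {
            const double wjk = wcol[j];
            const double *acol = &acts[l][static_cast<size_t>(j) * m];
            for (int r = 0; r < m; ++r) zcol[r] += wjk * acol[r];
          }
        }
        acts[l + 1] = zs[l];
        if (l < L - 1)
          for (double &v : acts[l + 1]) if (v < 0) v = 0;
      }
      // output delta = d(MSE)/d(z_L), m x 1
      delta.assign(m, 0.0);
      for (int r = 0; r < m; ++r) {
        const int row = perms(start + r, ep) - 1;
        delta[r] = 2.0 * (acts[L][r] - y[row]) / m;
      }
      ++step;
      const double bc1 = 1.0 - std::pow(beta1, static_cast<double>(step));
      const double bc2 = 1.0 - std::pow(beta2, static_cast<double>(step));
      for (int l = L - 1; l >= 0; --l) {
        // gradients
        std::vector<double> gW(static_cast<size_t>(din[l]) * dout[l], 0.0);
        std::vector<double> gb(dout[l], 0.0);
        for (int k = 0; k < dout[l]; ++k) {
          const double *dcol = &delta[static_cast<size_t>(k) * m];
          double s = 0.0;
          for (int r = 0; r < m; ++r) s += dcol[r];
          gb[k] = s;
          for (int j = 0; j < din[l]; ++j) {
            const double *acol = &acts[l][static_cast<size_t>(j) * m];
            double g = 0.0;
            for (int r = 0; r < m; ++r) g += acol[r] * dcol[r];
            gW[static_cast<size_t>(k) * din[l] + j] = g;
          }
        }
        // propagate delta to previous layer (before the weight update)
        if (l > 0) {
          delta_prev.assign(static_cast<size_t>(m) * din[l], 0.0);
          for (int j = 0; j < din[l]; ++j) {
            double *dpcol = &delta_prev[static_cast<size_t>(j) * m];
            for (int k = 0; k < dout[l]; ++k) {
              const double wjk = W[l][static_cast<size_t>(k) * din[l] + j];
              const double *dcol = &delta[static_cast<size_t>(k) * m];
              for (int r = 0; r < m; ++r) dpcol[r] += wjk * dcol[r];
            }
            const double *acol = &acts[l][static_cast<size_t>(j) * m];
            for (int r = 0; r < m; ++r) if (acol[r] <= 0) dpcol[r] = 0.0;
          }
          delta = delta_prev;
        }
        // Adam updates
        for (size_t t = 0; t < gW.size(); ++t) {
          mW[l][t] = beta1 * mW[l][t] + (1 - beta1) * gW[t];
          vW[l][t] = beta2 * vW[l][t] + (1 - beta2) * gW[t] * gW[t];
          W[l][t] -= lr * (mW[l][t] / bc1) / (std::sqrt(vW[l][t] / bc2) + eps);
        }
        for (int k = 0; k < dout[l]; ++k) {
          mb[l][k] = beta1 * mb[l][k] + (1 - beta1) * gb[k];
          vb[l][k] = beta2 * vb[l][k] + (1 - beta2) * gb[k] * gb[k];
          b[l][k] -= lr * (mb[l][k] / bc1) / (std::sqrt(vb[l][k] / bc2) + eps);
        }
      }
    }
    train_loss[ep] = forward_mse(X, y);
    if (!std::isfinite(train_loss[ep]))
      stop("training diverged: non-finite loss at epoch %d", ep + 1);
    val_loss[ep] = has_val ? forward_mse(Xval, yval) : NA_REAL;
  }

  List Wout(L), bout(L);
  for (int l = 0; l < L; ++l) {
    NumericMatrix w(din[l], dout[l]);
    std::copy(W[l].begin(), W[l].end(), w.begin());
    Wout[l] = w;
    bout[l] = NumericVector(b[l].begin(), b[l].end());
  }
  return List::create(_["W"] = Wout, _["b"] = bout,
                      _["train_loss"] = train_loss, _["val_loss"] = val_loss);
}
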