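// Convolution primitives for the residual EEG block system.
//
// Activation layout: a feature-map stack over a batch is stored as an
// F x (T*B) matrix, where F = number of feature maps, T = temporal extent
// and B = number of (channel, trial) blocks; within each block the T
// columns are consecutive time samples. Temporal convolutions act along
// time within a block and mix feature maps; they never mix blocks.
// All convolutions are cross-correlations (deep-learning convention),
// bias-free, with zero padding.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// im2col buffer sized to stay cache-resident (~4 MB of doubles), so the
// K-fold data expansion never round-trips through DRAM.
static arma::uword chunk_blocks(arma::uword rows, arma::uword T) {
  arma::uword b = (arma::uword)(16e6 / (8.0 * rows * T));
  return b < 1 ? 1 : b;
}

// im2col for a chunk of blocks [b0, b1): X is (Fin*K) x (T*(b1-b0)),
// row index g + Fin*k (tap-major), so each output column is filled by
// K contiguous copies of Fin-long input columns.
static void fill_im2col(const arma::mat& A, arma::mat& X,
                        arma::uword T, arma::uword K, int pad,
                        arma::uword b0, arma::uword b1) {
  const arma::uword Fin = A.n_rows;
  for (arma::uword b = b0; b < b1; ++b) {
    const arma::uword xoff = (b - b0) * T, aoff = b * T;
    for (arma::uword t = 0; t < T; ++t) {
      double* xcol = X.colptr(xoff + t);
      for (arma::uword k = 0; k < K; ++k) {
        const int ts = (int)t + (int)k - pad;
        double* xk = xcol + k * Fin;
        if (ts < 0 || ts >= (int)T) {
          for (arma::uword g = 0; g < Fin; ++g) xk[g] = 0.0;
        } else {
          const double* acol = A.colptr(aoff + ts);
          for (arma::uword g = 0; g < Fin; ++g) xk[g] = acol[g];
        }
      }
    }
  }
}

// Temporal convolution, kernel (1, K): W is Fout x (Fin*K), weight for
// input map g at tap k sits at column g + Fin*k.
// [[Rcpp::export]]
arma::mat conv_time_fw(const arma::mat& A, const arma::mat& W,
                       int T_, int K_, int pad) {
  const arma::uword T = T_, K = K_, M = A.n_cols, B = M / T;
  const arma::uword rows = A.n_rows * K;
  const arma::uword BC = chunk_blocks(rows, T);
  arma::mat O(W.n_rows, M);
  arma::mat X(rows, T * std::min(BC, B));
  for (arma::uword b0 = 0; b0 < B; b0 += BC) {
    const arma::uword b1 = std::min(b0 + BC, B);
    arma::mat Xv(X.memptr(), rows, T * (b1 - b0), false, true);
    fill_im2col(A, Xv, T, K, pad, b0, b1);
    O.cols(b0 * T, b1 * T - 1) = W * Xv;
  }
  return O;
}

// [[Rcpp::export]]
List conv_time_bw(const arma::mat& A, const arma::mat& W, const arma::mat& dO,
                  int T_, int K_, int pad) {
  const arma::uword T = T_, K = K_, M = A.n_cols, B = M / T;
  const arma::uword Fin = A.n_rows, rows = Fin * K;
  const arma::uword BC = chunk_blocks(rows, T);
  arma::mat dW(W.n_rows, rows, arma::fill::zeros);
  arma::mat dA(Fin, M, arma::fill::zeros);
  arma::mat X(rows, T * std::min(BC, B));
  for (arma::uword b0 = 0; b0 < B; b0 += BC) {
    const arma::uword b1 = std::min(b0 + BC, B);
    arma::mat Xv(X.memptr(), rows, T * (b1 - b0), false, true);
    fill_im2col(A, Xv, T, K, pad, b0, b1);
    const arma::mat dOc = dO.cols(b0 * T, b1 * T - 1);
    dW += dOc * Xv.t();
    arma::mat dX = W.t() * dOc;  // (Fin*K) x (T*chunk)
    for (arma::uword b = b0; b < b1; ++b) {
      const arma::uword xoff = (b - b0) * T, aoff = b * T;
      for (arma::uword t = 0; t < T; ++t) {
        const double* xcol = dX.colptr(xoff + t);
        for (arma::uword k = 0; k < K; ++k) {
          const int ts = (int)t + (int)k - pad;
          if (ts < 0 || ts >= (int)T) continue;
          double* acol = dA.colptr(aoff + ts);
          const double* xk = xcol + k * Fin;
          for (arma::uword g = 0; g < Fin; ++g) acol[g] += xk[g];
        }
      }
    }
  }
  return List::create(_["dA"] = dA, _["dW"] = dW);
}

// Spatial convolution, kernel (C, 1) collapsing the channel axis:
// A is Fin x (T*C*N) (C channel blocks per trial), W is Fout x (Fin*C)
// with weight for map f, channel c at column c*Fin + f. Output Fout x (T*N).
// [[Rcpp::export]]
arma::mat conv_spatial_fw(const arma::mat& A, const arma::mat& W,
                          int T_, int C_) {
  const arma::uword T = T_, C = C_, Fin = A.n_rows;
  const arma::uword N = A.n_cols / (T * C);
  arma::mat O(W.n_rows, T * N);
  arma::mat X(Fin * C, T);
  for (arma::uword n = 0; n < N; ++n) {
    for (arma::uword c = 0; c < C; ++c)
      X.rows(c * Fin, c * Fin + Fin - 1) =
        A.cols((n * C + c) * T, (n * C + c) * T + T - 1);
    O.cols(n * T, n * T + T - 1) = W * X;
  }
  return O;
}

// [[Rcpp::export]]
List conv_spatial_bw(const arma::mat& A, const arma::mat& W,
                     const arma::mat& dO, int T_, int C_) {
  const arma::uword T = T_, C = C_, Fin = A.n_rows;
  const arma::uword N = A.n_cols / (T * C);
  arma::mat dW(W.n_rows, Fin * C, arma::fill::zeros);
  arma::mat dA(Fin, A.n_cols);
  arma::mat X(Fin * C, T);
  for (arma::uword n = 0; n < N; ++n) {
    for (arma::uword c = 0; c < C; ++c)
      X.rows(c * Fin, c * Fin + Fin - 1) =
        A.cols((n * C + c) * T, (n * C + c) * T + T - 1);
    const arma::mat dOn = dO.cols(n * T, n * T + T - 1);
    dW += dOn * X.t();
    const arma::mat dX = W.t() * dOn;  // (Fin*C) x T
    for (arma::uword c = 0; c < C; ++c)
      dA.cols((n * C + c) * T, (n * C + c) * T + T - 1) =
        dX.rows(c * Fin, c * Fin + Fin - 1);
  }
  return List::create(_["dA"] = dA, _["dW"] = dW);
}

// Depthwise temporal convolution, kernel (1, K), one filter per map:
// A is F x (T*B), w is F x K.
// [[Rcpp::export]]
arma::mat conv_dw_fw(const arma::mat& A, const arma::mat& w,
                     int T_, int K_, int pad) {
  const arma::uword T = T_, K = K_, M = A.n_cols, B = M / T;
  const arma::uword F = A.n_rows;
  arma::mat O(F, M, arma::fill::zeros);
  for (arma::uword b = 0; b < B; ++b) {
    const arma::uword off = b * T;
    for (arma::uword t = 0; t < T; ++t) {
      double* ocol = O.colptr(off + t);
      for (arma::uword k = 0; k < K; ++k) {
        const int ts = (int)t + (int)k - pad;
        if (ts < 0 || ts >= (int)T) continue;
        const double* acol = A.colptr(off + ts);
        for (arma::uword f = 0; f < F; ++f) ocol[f] += w(f, k) * acol[f];
      }
    }
  }
  return O;
}

// [[Rcpp::export]]
List conv_dw_bw(const arma::mat& A, const arma::mat& w, const arma::mat& dO,
                int T_, int K_, int pad) {
  const arma::uword T = T_, K = K_, M = A.n_cols, B = M / T;
  const arma::uword F = A.n_rows;
  arma::mat dw(F, K, arma::fill::zeros);
  arma::mat dA(F, M, arma::fill::zeros);
  for (arma::uword b = 0; b < B; ++b) {
    const arma::uword off = b * T;
    for (arma::uword t = 0; t < T; ++t) {
      const double* dcol = dO.colptr(off + t);
      for (arma::uword k = 0; k < K; ++k) {
        const int ts = (int)t + (int)k - pad;
        if (ts < 0 || ts >= (int)T) continue;
        const double* acol = A.colptr(off + ts);
        double* dacol = dA.colptr(off + ts);
        for (arma::uword f = 0; f < F; ++f) {
          dw(f, k) += dcol[f] * acol[f];
          dacol[f] += dcol[f] * w(f, k);
        }
      }
    }
  }
  return List::create(_["dA"] = dA, _["dw"] = dw);
}

// Fused batch-norm training forward: one pass for batch statistics, one
// for the normalized output. Returns out, xhat, inv (per-map 1/sd).
// [[Rcpp::export]]
List bn_fw_train(const arma::mat& A, const arma::vec& gamma,
                 const arma::vec& beta, double eps) {
  const arma::uword F = A.n_rows, M = A.n_cols;
  arma::vec mu(F, arma::fill::zeros), m2(F, arma::fill::zeros);
  for (arma::uword j = 0; j < M; ++j) {
    const double* a = A.colptr(j);
    for (arma::uword f = 0; f < F; ++f) { mu[f] += a[f]; m2[f] += a[f] * a[f]; }
  }
  mu /= (double)M;
  arma::vec v = m2 / (double)M - mu % mu;
  v.transform([](double x) { return x < 0 ? 0.0 : x; });
  arma::vec inv = 1.0 / arma::sqrt(v + eps);
  arma::mat xhat(F, M), out(F, M);
  for (arma::uword j = 0; j < M; ++j) {
    const double* a = A.colptr(j);
    double* x = xhat.colptr(j);
    double* o = out.colptr(j);
    for (arma::uword f = 0; f < F; ++f) {
      x[f] = (a[f] - mu[f]) * inv[f];
      o[f] = x[f] * gamma[f] + beta[f];
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["inv"] = inv,
                      _["mu"] = mu, _["v"] = v);
}

// Fused batch-norm training backward.
// [[Rcpp::export]]
List bn_bw_train(const arma::mat& dO, const arma::mat& xhat,
                 const arma::vec& inv, const arma::vec& gamma) {
  const arma::uword F = dO.n_rows, M = dO.n_cols;
  arma::vec rs1(F, arma::fill::zeros), rs2(F, arma::fill::zeros);
  arma::vec dg(F, arma::fill::zeros), db(F, arma::fill::zeros);
  for (arma::uword j = 0; j < M; ++j) {
    const double* d = dO.colptr(j);
    const double* x = xhat.colptr(j);
    for (arma::uword f = 0; f < F; ++f) {
      const double dx = d[f] * gamma[f];
      rs1[f] += dx; rs2[f] += dx * x[f];
      dg[f] += d[f] * x[f]; db[f] += d[f];
    }
  }
  arma::mat dA(F, M);
  for (arma::uword j = 0; j < M; ++j) {
    const double* d = dO.colptr(j);
    const double* x = xhat.colptr(j);
    double* o = dA.colptr(j);
    for (arma::uword f = 0; f < F; ++f) {
      const double dx = d[f] * gamma[f];
      o[f] = (inv[f] / (double)M) * ((double)M * dx - rs1[f] - x[f] * rs2[f]);
    }
  }
  return List::create(_["dA"] = dA, _["dgamma"] = dg, _["dbeta"] = db);
}
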