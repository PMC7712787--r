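// Batched stride-1 'same' 2D convolution via im2col, used by the CNN layers.
// A batch of N images with C channels is passed as an (H, W, C*N) cube whose
// slices are ordered channel-fastest (image n occupies slices [n*C, (n+1)*C)).
// Weights are passed as a (K*K*C, Cout) matrix matching R's column-major
// reshape of a (K, K, C, Cout) array.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static mat im2col_same(const cube& x, int first_slice, int C, int K) {
  const int H = x.n_rows, W = x.n_cols, P = (K - 1) / 2;
  mat col(H * W, K * K * C);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < K; ++kj) {
      for (int ki = 0; ki < K; ++ki) {
        int cc = c * K * K + kj * K + ki;
        double* dst = col.colptr(cc);
        for (int oj = 0; oj < W; ++oj) {
          int sj = oj + kj - P;
          if (sj < 0 || sj >= W) {
            for (int oi = 0; oi < H; ++oi) dst[oj * H + oi] = 0.0;
          } else {
            const double* src = x.slice_colptr(first_slice + c, sj);
            for (int oi = 0; oi < H; ++oi) {
              int si = oi + ki - P;
              dst[oj * H + oi] = (si < 0 || si >= H) ? 0.0 : src[si];
            }
          }
        }
      }
    }
  }
  return col;
}

// adjoint of im2col_same: scatter-add column entries back onto the image grid
static void col2im_same(const mat& col, cube& x, int first_slice, int C, int K) {
  const int H = x.n_rows, W = x.n_cols, P = (K - 1) / 2;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < K; ++kj) {
      for (int ki = 0; ki < K; ++ki) {
        int cc = c * K * K + kj * K + ki;
        const double* src = col.colptr(cc);
        for (int oj = 0; oj < W; ++oj) {
          int sj = oj + kj - P;
          if (sj < 0 || sj >= W) continue;
          double* dst = x.slice_colptr(first_slice + c, sj);
          for (int oi = 0; oi < H; ++oi) {
            int si = oi + ki - P;
            if (si >= 0 && si < H) dst[si] += src[oj * H + oi];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv_fwd_batch")]]
arma::cube conv_fwd_batch(const arma::cube& x, int N, int C,
                          const arma::mat& Wm, const arma::vec& b, int K) {
  const int H = x.n_rows, W = x.n_cols, Cout = Wm.n_cols;
  cube out(H, W, Cout * N);
  for (int n = 0; n < N; ++n) {
    mat col = im2col_same(x, n * C, C, K);
    mat o = col * Wm;             // (H*W) x Cout
    o.each_row() += b.t();
    for (int co = 0; co < Cout; ++co)
      out.slice(n * Cout + co) = reshape(o.col(co), H, W);
  }
  return out;
}

// [[Rcpp::export(name = ".conv_bwd_batch")]]
Rcpp::List conv_bwd_batch(const arma::cube& x, const arma::cube& dout,
                          int N, int C, const arma::mat& Wm, int K,
                          bool need_dx) {
  const int H = x.n_rows, W = x.n_cols, Cout = Wm.n_cols;
  mat dW(Wm.n_rows, Cout, fill::zeros);
  vec db(Cout, fill::zeros);
  cube dx;
  if (need_dx) dx.zeros(H, W, C * N);
  mat dmat(H * W, Cout);
  for (int n = 0; n < N; ++n) {
    mat col = im2col_same(x, n * C, C, K);
    for (int co = 0; co < Cout; ++co)
      dmat.col(co) = vectorise(dout.slice(n * Cout + co));
    dW += col.t() * dmat;
    db += sum(dmat, 0).t();
    if (need_dx) {
      mat dcol = dmat * Wm.t();
      col2im_same(dcol, dx, n * C, C, K);
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
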