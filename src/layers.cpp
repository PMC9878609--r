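// Hot inner kernels of the 3D CNN: im2col convolution forward/backward and
// rowwise affine maps. Index tables are 1-based with pad index nvox + 1
// (out-of-volume taps read as zero, receive no gradient).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix conv3d_fwd(NumericMatrix Xr, IntegerMatrix idxr,
                         NumericMatrix Wr, NumericVector br, int B) {
  const int nvoxB = Xr.nrow(), cin = Xr.ncol();
  const int nvox = nvoxB / B, k3 = idxr.ncol();
  const int cout = Wr.ncol();
  arma::mat X(Xr.begin(), nvoxB, cin, false, true);
  arma::mat W(Wr.begin(), Wr.nrow(), cout, false, true);
  NumericMatrix Yr(nvoxB, cout);
  arma::mat Y(Yr.begin(), nvoxB, cout, false, true);
  const int* idx = idxr.begin();

  arma::mat P(nvox, (std::size_t)k3 * cin);
  for (int s = 0; s < B; ++s) {
    const int off = s * nvox;
    for (int c = 0; c < cin; ++c) {
      const double* xc = X.colptr(c) + off;
      for (int t = 0; t < k3; ++t) {
        double* pc = P.colptr((std::size_t)c * k3 + t);
        const int* ic = idx + (std::size_t)t * nvox;
        for (int v = 0; v < nvox; ++v) {
          int i = ic[v];
          pc[v] = (i <= nvox) ? xc[i - 1] : 0.0;
        }
      }
    }
    Y.rows(off, off + nvox - 1) = P * W;
  }
  arma::rowvec b(br.begin(), cout);
  Y.each_row() += b;
  return Yr;
}

// [[Rcpp::export]]
List conv3d_bwd(NumericMatrix Xr, IntegerMatrix idxr, NumericMatrix Wr,
                NumericMatrix dYr, int B) {
  const int nvoxB = Xr.nrow(), cin = Xr.ncol();
  const int nvox = nvoxB / B, k3 = idxr.ncol();
  const int cout = Wr.ncol();
  arma::mat X(Xr.begin(), nvoxB, cin, false, true);
  arma::mat W(Wr.begin(), Wr.nrow(), cout, false, true);
  arma::mat dY(dYr.begin(), nvoxB, cout, false, true);
  const int* idx = idxr.begin();

  NumericMatrix dXr(nvoxB, cin);
  arma::mat dX(dXr.begin(), nvoxB, cin, false, true);
  arma::mat dW((std::size_t)k3 * cin, cout, arma::fill::zeros);
  arma::mat P(nvox, (std::size_t)k3 * cin);

  for (int s = 0; s < B; ++s) {
    const int off = s * nvox;
    for (int c = 0; c < cin; ++c) {
      const double* xc = X.colptr(c) + off;
      for (int t = 0; t < k3; ++t) {
        double* pc = P.colptr((std::size_t)c * k3 + t);
        const int* ic = idx + (std::size_t)t * nvox;
        for (int v = 0; v < nvox; ++v) {
          int i = ic[v];
          pc[v] = (i <= nvox) ? xc[i - 1] : 0.0;
        }
      }
    }
    arma::mat dYs = dY.rows(off, off + nvox - 1);
    dW += P.t() * dYs;
    arma::mat dP = dYs * W.t();          // nvox x (k3*cin), tap fastest
    for (int c = 0; c < cin; ++c) {
      double* dxc = dX.colptr(c) + off;
      for (int t = 0; t < k3; ++t) {
        const double* dpc = dP.colptr((std::size_t)c * k3 + t);
        const int* ic = idx + (std::size_t)t * nvox;
        for (int v = 0; v < nvox; ++v) {
          int i = ic[v];
          if (i <= nvox) dxc[i - 1] += dpc[v];
        }
      }
    }
  }
  arma::rowvec db = arma::sum(dY, 0);
  return List::create(_["dX"] = dXr,
                      _["dW"] = NumericMatrix(wrap(dW)),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Y = X * a[col] + s[col]
// [[Rcpp::export]]
NumericMatrix row_scale_shift(NumericMatrix Xr, NumericVector a,
                              NumericVector s) {
  const int n = Xr.nrow(), m = Xr.ncol();
  NumericMatrix Yr(n, m);
  for (int c = 0; c < m; ++c) {
    const double ac = a[c], sc = s[c];
    const double* x = &Xr(0, c);
    double* y = &Yr(0, c);
    for (int i = 0; i < n; ++i) y[i] = x[i] * ac + sc;
  }
  return Yr;
}

// [[Rcpp::export]]
NumericMatrix leaky_fwd(NumericMatrix Xr, double slope) {
  const R_xlen_t n = (R_xlen_t)Xr.nrow() * Xr.ncol();
  NumericMatrix Yr(Xr.nrow(), Xr.ncol());
  const double* x = Xr.begin();
  double* y = Yr.begin();
  for (R_xlen_t i = 0; i < n; ++i) y[i] = x[i] >= 0 ? x[i] : slope * x[i];
  return Yr;
}

// gradient from the forward *output* (slope > 0 preserves sign)
// [[Rcpp::export]]
NumericMatrix leaky_bwd(NumericMatrix Yr, NumericMatrix dYr, double slope) {
  const R_xlen_t n = (R_xlen_t)Yr.nrow() * Yr.ncol();
  NumericMatrix dXr(Yr.nrow(), Yr.ncol());
  const double* y = Yr.begin();
  const double* dy = dYr.begin();
  double* dx = dXr.begin();
  for (R_xlen_t i = 0; i < n; ++i) dx[i] = y[i] >= 0 ? dy[i] : slope * dy[i];
  return dXr;
}
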