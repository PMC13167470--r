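// Hot loops of the convolution layers. A stride-1, zero-padded ("same")
// convolution over feature matrices (rows = pixels, cols = channels) is
// computed as a sum over kernel offsets: out += shift_k(X) %*% W_k.
// Shifted copies go through one small reusable buffer and BLAS dgemm,
// avoiding the 9x memory blow-up of a materialized im2col matrix.
// Row shifts come as precomputed 0-based index vectors (-1 = zero pad),
// offset-major, length K * nrow.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

static void gather(const double* X, const int* idx, double* buf,
                   const int n, const int c, const int xrows) {
  for (int j = 0; j < c; ++j) {
    const double* xcol = X + (R_xlen_t)j * xrows;
    double* bcol = buf + (R_xlen_t)j * n;
    for (int i = 0; i < n; ++i) {
      const int r = idx[i];
      bcol[i] = (r < 0) ? 0.0 : xcol[r];
    }
  }
}

// depthwise fixed-stencil filter: out[:, c] = sum_k w[k] * shift_k(X)[:, c]
// (used for the bilinear-upsampling smoothing; symmetric kernels make the
// op self-adjoint under zero padding)
// [[Rcpp::export(name = ".cpp_stencil")]]
NumericMatrix cpp_stencil(const NumericMatrix& X, const IntegerVector& idx,
                          const NumericVector& w) {
  const int n = X.nrow(), c = X.ncol(), K = w.size();
  NumericMatrix out(n, c);
  for (int k = 0; k < K; ++k) {
    const int* ip = &idx[(R_xlen_t)k * n];
    const double wk = w[k];
    if (wk == 0.0) continue;
    for (int j = 0; j < c; ++j) {
      const double* xcol = &X(0, j);
      double* ocol = &out(0, j);
      for (int i = 0; i < n; ++i) {
        const int r = ip[i];
        if (r >= 0) ocol[i] += wk * xcol[r];
      }
    }
  }
  return out;
}

// forward: out = sum_k shift_k(X) %*% W[k-block] + bias
// [[Rcpp::export(name = ".cpp_conv_fwd")]]
NumericMatrix cpp_conv_fwd(const NumericMatrix& X, const NumericMatrix& W,
                           const NumericVector& bias,
                           const IntegerVector& idx, const int K) {
  const int n = X.nrow(), cin = X.ncol(), cout = W.ncol();
  NumericMatrix out(n, cout);
  for (int j = 0; j < cout; ++j) {
    double* ocol = &out(0, j);
    const double bj = bias[j];
    for (int i = 0; i < n; ++i) ocol[i] = bj;
  }
  std::vector<double> buf((R_xlen_t)n * cin);
  const double one = 1.0;
  const int wr = W.nrow();
  for (int k = 0; k < K; ++k) {
    gather(&X(0, 0), &idx[(R_xlen_t)k * n], buf.data(), n, cin, n);
    // out += buf (n x cin) %*% W[k*cin .. , ] (cin x cout)
    F77_CALL(dgemm)("N", "N", &n, &cout, &cin, &one, buf.data(), &n,
                    &W(k * cin, 0), &wr, &one, &out(0, 0), &n
                    FCONE FCONE);
  }
  return out;
}

// backward: dX = sum_j shift_j(G) %*% t(W[(K-1-j)-block]),
//           dW[k-block] = t(shift_k(X)) %*% G,  db = colSums(G)
// [[Rcpp::export(name = ".cpp_conv_bwd")]]
List cpp_conv_bwd(const NumericMatrix& X, const NumericMatrix& W,
                  const NumericMatrix& G, const IntegerVector& idx,
                  const int K) {
  const int n = X.nrow(), cin = X.ncol(), cout = W.ncol();
  NumericMatrix dX(n, cin);
  NumericMatrix dW(W.nrow(), cout);
  NumericVector db(cout);
  std::vector<double> buf((R_xlen_t)n * std::max(cin, cout));
  const double one = 1.0;
  const int wr = W.nrow();
  for (int j = 0; j < cout; ++j) {
    const double* gcol = &G(0, j);
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += gcol[i];
    db[j] = s;
  }
  for (int k = 0; k < K; ++k) {
    // dX += shift_k(G) %*% t(W[(K-1-k)-block])
    gather(&G(0, 0), &idx[(R_xlen_t)k * n], buf.data(), n, cout, n);
    F77_CALL(dgemm)("N", "T", &n, &cin, &cout, &one, buf.data(), &n,
                    &W((K - 1 - k) * cin, 0), &wr, &one, &dX(0, 0),
                    &n FCONE FCONE);
  }
  for (int k = 0; k < K; ++k) {
    // dW[k-block] += t(shift_k(X)) %*% G
    gather(&X(0, 0), &idx[(R_xlen_t)k * n], buf.data(), n, cin, n);
    F77_CALL(dgemm)("T", "N", &cin, &cout, &n, &one, buf.data(), &n,
                    &G(0, 0), &n, &one, &dW(k * cin, 0), &wr
                    FCONE FCONE);
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}
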