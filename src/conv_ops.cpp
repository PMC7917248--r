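// Compiled kernels for the convolution tunnel and the optimizer.
//
// The 1-D convolution over a stack of n equal-length sequences is expressed
// as a sum over kernel offsets of BLAS dgemm calls on contiguous views of
// the channels-by-positions layout (the transpose of the R-side activation
// matrix). This avoids materializing im2col patch matrices, which dominated
// memory traffic. Shapes on the R side stay (n * L) x C, sequence-major.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// Transpose a (nr x nc) column-major block src into dst (nc x nr).
static void transpose_into(const double* src, double* dst, int nr, int nc) {
  for (int j = 0; j < nc; ++j) {
    const double* s = src + (R_xlen_t)j * nr;
    double* d = dst + j;
    for (int i = 0; i < nr; ++i) d[(R_xlen_t)i * nc] = s[i];
  }
}

// Forward convolution. A: (n * L_in) x C activations (column-major),
// W: (C * k) x F kernel, returns pre-activations (n * L_out) x F (no bias).
// [[Rcpp::export]]
NumericMatrix conv1d_forward_cpp(const NumericMatrix& A, const NumericMatrix& W,
                                 int n, int L_in, int k) {
  const int C = A.ncol();
  const int F = W.ncol();
  const int Ck = W.nrow();
  if (Ck != C * k) stop("kernel rows do not match C * k");
  const int L_out = L_in - k + 1;
  const int NRin = n * L_in;
  const int NRout = n * L_out;

  // B = A^T, C x (n * L_in), column r = features of position r
  std::vector<double> B((R_xlen_t)C * NRin);
  transpose_into(A.begin(), B.data(), NRin, C);
  // preT = F x (n * L_out), accumulated over kernel offsets
  std::vector<double> preT((R_xlen_t)F * NRout, 0.0);

  const double one = 1.0;
  const char* tA = "T";
  const char* nN = "N";
  for (int i = 0; i < k; ++i) {
    // W_i: rows i*C .. i*C+C-1 of W -> view with lda = Ck
    const double* Wi = W.begin() + (R_xlen_t)i * C;
    for (int p = 0; p < n; ++p) {
      const double* Bp = B.data() + (R_xlen_t)(p * L_in + i) * C;
      double* Pp = preT.data() + (R_xlen_t)(p * L_out) * F;
      // preT_p (F x L_out) += W_i^T (F x C) * B_view (C x L_out)
      F77_CALL(dgemm)(tA, nN, &F, const_cast<int*>(&L_out), const_cast<int*>(&C),
                      const_cast<double*>(&one), const_cast<double*>(Wi),
                      const_cast<int*>(&Ck), const_cast<double*>(Bp),
                      const_cast<int*>(&C), const_cast<double*>(&one), Pp,
                      const_cast<int*>(&F) FCONE FCONE);
    }
  }
  NumericMatrix pre(NRout, F);
  transpose_into(preT.data(), pre.begin(), F, NRout);
  return pre;
}

// Backward convolution: given input activations A, kernel W and the gradient
// dpre at the pre-activations, return dW ((C*k) x F) and dA ((n*L_in) x C).
// [[Rcpp::export]]
List conv1d_backward_cpp(const NumericMatrix& A, const NumericMatrix& W,
                         const NumericMatrix& dpre, int n, int L_in, int k) {
  const int C = A.ncol();
  const int F = W.ncol();
  const int Ck = W.nrow();
  if (Ck != C * k) stop("kernel rows do not match C * k");
  const int L_out = L_in - k + 1;
  const int NRin = n * L_in;
  const int NRout = n * L_out;
  if (dpre.nrow() != NRout || dpre.ncol() != F) stop("dpre has wrong shape");

  std::vector<double> B((R_xlen_t)C * NRin);
  transpose_into(A.begin(), B.data(), NRin, C);

  NumericMatrix dW(Ck, F);
  std::vector<double> dB((R_xlen_t)C * NRin, 0.0);

  const double one = 1.0;
  const char* nN = "N";
  const char* tT = "T";
  for (int i = 0; i < k; ++i) {
    double* dWi = dW.begin() + (R_xlen_t)i * C;
    for (int p = 0; p < n; ++p) {
      const double* Bp = B.data() + (R_xlen_t)(p * L_in + i) * C;
      const double* Dp = dpre.begin() + (R_xlen_t)p * L_out;   // view, lda = NRout
      // dW_i (C x F) += B_view (C x L_out) * dpre_p (L_out x F)
      F77_CALL(dgemm)(nN, nN, const_cast<int*>(&C), const_cast<int*>(&F),
                      const_cast<int*>(&L_out), const_cast<double*>(&one),
                      const_cast<double*>(Bp), const_cast<int*>(&C),
                      const_cast<double*>(Dp), const_cast<int*>(&NRout),
                      const_cast<double*>(&one), dWi, const_cast<int*>(&Ck)
                      FCONE FCONE);
      // dB_view (C x L_out) += W_i (C x F) * dpre_p^T (F x L_out)
      double* dBp = dB.data() + (R_xlen_t)(p * L_in + i) * C;
      F77_CALL(dgemm)(nN, tT, const_cast<int*>(&C), const_cast<int*>(&L_out),
                      const_cast<int*>(&F), const_cast<double*>(&one),
                      const_cast<double*>(W.begin() + (R_xlen_t)i * C),
                      const_cast<int*>(&Ck), const_cast<double*>(Dp),
                      const_cast<int*>(&NRout), const_cast<double*>(&one), dBp,
                      const_cast<int*>(&C) FCONE FCONE);
    }
  }
  NumericMatrix dA(NRin, C);
  transpose_into(dB.data(), dA.begin(), C, NRin);
  return List::create(Named("W") = dW, Named("dA") = dA);
}

// Elementwise max(x, 0).
// [[Rcpp::export]]
NumericMatrix relu_cpp(const NumericMatrix& X) {
  NumericMatrix Y(X.nrow(), X.ncol());
  const double* xp = X.begin();
  double* yp = Y.begin();
  const R_xlen_t nn = (R_xlen_t)X.nrow() * X.ncol();
  for (R_xlen_t i = 0; i < nn; ++i) yp[i] = xp[i] > 0 ? xp[i] : 0;
  return Y;
}

// Elementwise d * (pre > 0): gradient through a ReLU.
// [[Rcpp::export]]
NumericMatrix relu_backward_cpp(const NumericMatrix& d, const NumericMatrix& pre) {
  if (d.nrow() != pre.nrow() || d.ncol() != pre.ncol()) stop("shape mismatch");
  NumericMatrix Y(d.nrow(), d.ncol());
  const double* dp = d.begin();
  const double* pp = pre.begin();
  double* yp = Y.begin();
  const R_xlen_t nn = (R_xlen_t)d.nrow() * d.ncol();
  for (R_xlen_t i = 0; i < nn; ++i) yp[i] = pp[i] > 0 ? dp[i] : 0;
  return Y;
}

// Fused in-place Adam update of one parameter leaf. p, m, v are modified in
// place (the caller owns the only references); g is the gradient. c1, c2 are
// the bias-correction factors 1 - beta^t.
// [[Rcpp::export]]
void adam_update_cpp(NumericVector p, NumericVector m, NumericVector v,
                     const NumericVector& g, double lr, double beta1,
                     double beta2, double eps, double c1, double c2) {
  const R_xlen_t nn = p.size();
  if (m.size() != nn || v.size() != nn || g.size() != nn) stop("length mismatch");
  double* pp = p.begin();
  double* mp = m.begin();
  double* vp = v.begin();
  const double* gp = g.begin();
  for (R_xlen_t i = 0; i < nn; ++i) {
    const double gi = gp[i];
    mp[i] = beta1 * mp[i] + (1 - beta1) * gi;
    vp[i] = beta2 * vp[i] + (1 - beta2) * gi * gi;
    pp[i] -= lr * (mp[i] / c1) / (std::sqrt(vp[i] / c2) + eps);
  }
}
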