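// im2col / col2im for the tall activation layout ([n*L, C], position-major
// row blocks). Pure memory movement; numerically exact in double precision.
#include <Rcpp.h>

// [[Rcpp::export(name = ".cpp_im2col")]]
Rcpp::NumericMatrix cpp_im2col(const Rcpp::NumericMatrix& A, const int n,
                               const int L, const int C, const int k,
                               const int s, const int pl, const int Lo) {
  Rcpp::NumericMatrix X(n * Lo, k * C);
  const double* a = A.begin();
  double* x = X.begin();
  const int xrows = n * Lo, arows = n * L;
  for (int t = 0; t < Lo; ++t) {
    for (int j = 0; j < k; ++j) {
      const int p = t * s + j - pl;      // 0-based input position
      if (p < 0 || p >= L) continue;
      for (int c = 0; c < C; ++c) {
        std::memcpy(x + (size_t)(j * C + c) * xrows + (size_t)t * n,
                    a + (size_t)c * arows + (size_t)p * n,
                    sizeof(double) * n);
      }
    }
  }
  return X;
}

// [[Rcpp::export(name = ".cpp_col2im")]]
Rcpp::NumericMatrix cpp_col2im(const Rcpp::NumericMatrix& dX, const int n,
                               const int L, const int C, const int k,
                               const int s, const int pl, const int Lo) {
  Rcpp::NumericMatrix dA(n * L, C);
  const double* x = dX.begin();
  double* a = dA.begin();
  const int xrows = n * Lo, arows = n * L;
  for (int t = 0; t < Lo; ++t) {
    for (int j = 0; j < k; ++j) {
      const int p = t * s + j - pl;
      if (p < 0 || p >= L) continue;
      for (int c = 0; c < C; ++c) {
        double* dst = a + (size_t)c * arows + (size_t)p * n;
        const double* src = x + (size_t)(j * C + c) * xrows + (size_t)t * n;
        for (int i = 0; i < n; ++i) dst[i] += src[i];
      }
    }
  }
  return dA;
}
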