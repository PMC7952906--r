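// Single-precision GEMM kernels used by the neural-network layers.
// Training deep nets in float32 is the field standard and roughly halves
// BLAS time relative to R's double-precision %*%; a double path is kept in
// R for finite-difference gradient checks.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".cpp_sgemm")]]
Rcpp::NumericMatrix cpp_sgemm(const arma::mat& A, const arma::mat& B,
                              const bool transA = false,
                              const bool transB = false) {
  fmat Af = conv_to<fmat>::from(A);
  fmat Bf = conv_to<fmat>::from(B);
  fmat Cf;
  if (!transA && !transB)      Cf = Af * Bf;
  else if (transA && !transB)  Cf = Af.t() * Bf;
  else if (!transA && transB)  Cf = Af * Bf.t();
  else                         Cf = Af.t() * Bf.t();
  mat C = conv_to<mat>::from(Cf);
  return Rcpp::wrap(C);
}
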