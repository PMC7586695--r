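// In-place Adam update for the classifier's dense parameter blocks.
// The caller owns param/m/v (deep-copied at training start), so writing
// through their data pointers is safe and avoids per-step allocation of
// multi-megabyte temporaries.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
void adam_update_cpp(NumericVector param, NumericVector grad,
                     NumericVector m, NumericVector v, double lr,
                     int t, double beta1, double beta2, double eps) {
  const R_xlen_t n = param.size();
  if (grad.size() != n || m.size() != n || v.size() != n)
    stop("adam_update_cpp: length mismatch");
  const double bc1 = 1.0 - std::pow(beta1, (double)t);
  const double bc2 = 1.0 - std::pow(beta2, (double)t);
  double* p = REAL(param); double* g = REAL(grad);
  double* mm = REAL(m); double* vv = REAL(v);
  for (R_xlen_t i = 0; i < n; ++i) {
    mm[i] = beta1 * mm[i] + (1.0 - beta1) * g[i];
    vv[i] = beta2 * vv[i] + (1.0 - beta2) * g[i] * g[i];
    p[i] -= lr * (mm[i] / bc1) / (std::sqrt(vv[i] / bc2) + eps);
  }
}
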