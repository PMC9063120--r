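#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fused Adam/AdamW update, applied in place: p (parameters), m and v
// (first/second moment estimates) are all modified directly, avoiding the
// per-step temporaries that dominate optimizer cost for multi-million
// parameter tensors in pure R. Callers own p/m/v exclusively and must
// deep-copy before retaining snapshots (see nn_fit's best-parameter copy).
//
// scale and eps2 carry the bias corrections: scale = lr*sqrt(1-beta2^t)/
// (1-beta1^t), eps2 = eps*sqrt(1-beta2^t). lr_wd = lr*weight_decay adds
// decoupled weight decay (pass 0 for bias vectors).
// [[Rcpp::export]]
void adam_update_inplace(NumericVector p, NumericVector m, NumericVector v,
                         NumericVector g, double beta1, double beta2,
                         double scale, double eps2, double lr_wd) {
  R_xlen_t n = p.size();
  if (m.size() != n || v.size() != n || g.size() != n)
    stop("adam_update_inplace: length mismatch");
  double *pp = p.begin(), *pm = m.begin(), *pv = v.begin(), *pg = g.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    double gi = pg[i];
    double mi = pm[i] = beta1 * pm[i] + (1.0 - beta1) * gi;
    double vi = pv[i] = beta2 * pv[i] + (1.0 - beta2) * gi * gi;
    double step = scale * mi / (std::sqrt(vi) + eps2);
    if (lr_wd > 0) step += lr_wd * pp[i];
    pp[i] -= step;
  }
}
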