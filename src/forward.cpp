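#include <Rcpp.h>
using namespace Rcpp;

// Exact marginal log-likelihood of a multi-season detection history, one
// value per site, by forward recursion over the latent occupancy state.
//
// phi1: first-season occupancy probability, length n
// gam, eps: colonization / extinction probabilities, n x (T-1)
// p: detection probabilities, n x (T*K); column index t*K + k (0-based)
// y: detections, n x (T*K) in {0, 1, NA}; NA = occasion with effort < 1 day
//
// Occasions with y = NA contribute emission factor 1 (marginalized out).
// A season that is entirely NA contributes factor 1 for both latent states.
// Probabilities exactly 0 or 1 are handled by the usual limit conventions;
// a history impossible under every latent path returns -Inf.
// Per-season rescaling keeps the recursion in a stable range; the returned
// value is the exact log-likelihood regardless of internal scaling.
// [[Rcpp::export]]
NumericVector forward_loglik_cpp(NumericVector phi1, NumericMatrix gam,
                                 NumericMatrix eps, NumericMatrix p,
                                 IntegerMatrix y, int T, int K) {
  int n = phi1.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    double a0 = 1.0 - phi1[i];
    double a1 = phi1[i];
    double logscale = 0.0;
    bool dead = false;
    for (int t = 0; t < T; t++) {
      double e1 = 1.0;
      bool all_zero = true;
      for (int k = 0; k < K; k++) {
        int yv = y(i, t * K + k);
        if (yv == NA_INTEGER) continue;
        double pv = p(i, t * K + k);
        if (yv == 1) {
          e1 *= pv;
          all_zero = false;
        } else {
          e1 *= 1.0 - pv;
        }
      }
      double b0 = all_zero ? a0 : 0.0;  // e0 = 1 iff no detection this season
      double b1 = a1 * e1;
      double s = b0 + b1;
      if (s <= 0.0) { dead = true; break; }
      b0 /= s;
      b1 /= s;
      logscale += std::log(s);
      if (t < T - 1) {
        double g = gam(i, t), e = eps(i, t);
        a0 = b0 * (1.0 - g) + b1 * e;
        a1 = b0 * g + b1 * (1.0 - e);
      }
    }
    out[i] = dead ? R_NegInf : logscale;
  }
  return out;
}
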