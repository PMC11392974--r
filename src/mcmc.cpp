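#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Forward recursion over the latent occupancy state (see forward.cpp for
// the contract). Probabilities are stored compressed: prob arrays hold
// values for the *unique* design-matrix rows of each block, and the map
// arrays give, per observation slot, the 0-based index into them. Writes
// per-site log-likelihoods into out_ll and returns their sum.
static double forward_sum_c(int n, int T, int K,
                            const double* p1, const int* m1,
                            const double* pg, const int* mg,
                            const double* pe, const int* me,
                            const double* pp, const int* mp,
                            const int* y, double* out_ll) {
  double total = 0.0;
  for (int i = 0; i < n; i++) {
    double phi1 = p1[m1[i]];
    double a0 = 1.0 - phi1;
    double a1 = phi1;
    double logscale = 0.0;
    bool dead = false;
    for (int t = 0; t < T; t++) {
      double e1 = 1.0;
      bool all_zero = true;
      for (int k = 0; k < K; k++) {
        int idx = i + n * (t * K + k);
        int yv = y[idx];
        if (yv == NA_INTEGER) continue;
        double pv = pp[mp[idx]];
        if (yv == 1) { e1 *= pv; all_zero = false; }
        else         { e1 *= 1.0 - pv; }
      }
      double b0 = all_zero ? a0 : 0.0;
      double b1 = a1 * e1;
      double s = b0 + b1;
      if (s <= 0.0) { dead = true; break; }
      b0 /= s; b1 /= s;
      logscale += std::log(s);
      if (t < T - 1) {
        int idx = i + n * t;
        double g = pg[mg[idx]], e = pe[me[idx]];
        a0 = b0 * (1.0 - g) + b1 * e;
        a1 = b0 * g + b1 * (1.0 - e);
      }
    }
    out_ll[i] = dead ? R_NegInf : logscale;
    total += out_ll[i];
  }
  return total;
}

static inline double inv_logit(double x) {
  return x > 0 ? 1.0 / (1.0 + std::exp(-x))
               : std::exp(x) / (1.0 + std::exp(x));
}

// One chain of componentwise adaptive random-walk Metropolis on the
// posterior (exact marginal likelihood x independent Logistic(0,1)
// priors). X1/Xg/Xe/Xp hold the *unique* design-matrix rows per block;
// map1/mapg/mape/mapp (0-based) expand them to observation slots.
// Proposal scales adapt toward `target_accept` during burn-in only
// (Robbins-Monro on the log scale, every `adapt_every` sweeps) and are
// frozen afterwards. Uses R's RNG, so set.seed() on the R side makes
// chains reproducible. Returns retained draws, the per-draw pointwise
// log-likelihood matrix (needed for LOO), acceptance rates and final
// proposal scales.
// [[Rcpp::export]]
List mcmc_chain_cpp(NumericMatrix X1, NumericMatrix Xg, NumericMatrix Xe,
                    NumericMatrix Xp, IntegerVector map1, IntegerVector mapg,
                    IntegerVector mape, IntegerVector mapp,
                    IntegerMatrix y, int n, int T, int K,
                    NumericVector theta_init, int n_iter, int n_burn,
                    double init_scale, double target_accept,
                    int adapt_every) {
  const int d1 = X1.ncol(), dg = Xg.ncol(), de = Xe.ncol(), dp = Xp.ncol();
  const int d = d1 + dg + de + dp;

  std::vector<double> theta(theta_init.begin(), theta_init.end());
  std::vector<int> block(d), col(d);
  {
    int j = 0;
    for (int c = 0; c < d1; c++) { block[j] = 0; col[j++] = c; }
    for (int c = 0; c < dg; c++) { block[j] = 1; col[j++] = c; }
    for (int c = 0; c < de; c++) { block[j] = 2; col[j++] = c; }
    for (int c = 0; c < dp; c++) { block[j] = 3; col[j++] = c; }
  }

  std::vector<double> eta[4], etaN[4], prob[4], probN[4];
  const NumericMatrix* X[4] = { &X1, &Xg, &Xe, &Xp };
  const int off[4] = { 0, d1, d1 + dg, d1 + dg + de };
  int rows[4];
  for (int b = 0; b < 4; b++) {
    rows[b] = X[b]->nrow();
    eta[b].assign(rows[b], 0.0);
    for (int c = 0; c < X[b]->ncol(); c++) {
      double th = theta[off[b] + c];
      for (int r = 0; r < rows[b]; r++) eta[b][r] += (*X[b])(r, c) * th;
    }
    prob[b].resize(rows[b]);
    for (int r = 0; r < rows[b]; r++) prob[b][r] = inv_logit(eta[b][r]);
    etaN[b] = eta[b];
    probN[b] = prob[b];
  }

  std::vector<double> ll(n), llN(n);
  double lsum = forward_sum_c(n, T, K,
                              prob[0].data(), map1.begin(),
                              prob[1].data(), mapg.begin(),
                              prob[2].data(), mape.begin(),
                              prob[3].data(), mapp.begin(),
                              y.begin(), ll.data());
  double lprior = 0.0;
  for (int j = 0; j < d; j++) lprior += R::dlogis(theta[j], 0.0, 1.0, 1);

  std::vector<double> lscale(d, std::log(init_scale));
  std::vector<int> acc_win(d, 0);
  std::vector<long> acc_tot(d, 0);
  int n_keep = n_iter - n_burn;
  NumericMatrix draws(n_keep, d);
  NumericMatrix ll_out(n_keep, n);
  int adapt_round = 0;

  RNGScope scope;
  for (int it = 0; it < n_iter; it++) {
    for (int j = 0; j < d; j++) {
      int b = block[j], c = col[j];
      double delta = R::norm_rand() * std::exp(lscale[j]);
      for (int r = 0; r < rows[b]; r++) {
        etaN[b][r] = eta[b][r] + (*X[b])(r, c) * delta;
        probN[b][r] = inv_logit(etaN[b][r]);
      }
      const double* pb[4];
      for (int bb = 0; bb < 4; bb++) {
        pb[bb] = (bb == b) ? probN[bb].data() : prob[bb].data();
      }
      double lsum_new = forward_sum_c(n, T, K,
                                      pb[0], map1.begin(),
                                      pb[1], mapg.begin(),
                                      pb[2], mape.begin(),
                                      pb[3], mapp.begin(),
                                      y.begin(), llN.data());
      double th_new = theta[j] + delta;
      double lprior_new = lprior - R::dlogis(theta[j], 0.0, 1.0, 1)
                                 + R::dlogis(th_new, 0.0, 1.0, 1);
      double logr = (lsum_new + lprior_new) - (lsum + lprior);
      if (!std::isfinite(lsum) && std::isfinite(lsum_new)) logr = 0.0;
      if (std::isfinite(logr) && std::log(R::unif_rand()) < logr) {
        theta[j] = th_new;
        std::swap(eta[b], etaN[b]);
        std::swap(prob[b], probN[b]);
        std::swap(ll, llN);
        lsum = lsum_new;
        lprior = lprior_new;
        acc_win[j]++;
        acc_tot[j]++;
      }
    }
    if (it < n_burn && (it + 1) % adapt_every == 0) {
      adapt_round++;
      double step = 1.0 / std::sqrt((double)adapt_round);
      for (int j = 0; j < d; j++) {
        double rate = (double)acc_win[j] / adapt_every;
        lscale[j] += step * (rate - target_accept);
        if (lscale[j] < -10.0) lscale[j] = -10.0;
        if (lscale[j] > 3.0) lscale[j] = 3.0;
        acc_win[j] = 0;
      }
    }
    if (it >= n_burn) {
      int r = it - n_burn;
      for (int j = 0; j < d; j++) draws(r, j) = theta[j];
      for (int i = 0; i < n; i++) ll_out(r, i) = ll[i];
    }
  }

  NumericVector acc_rate(d), scales(d);
  for (int j = 0; j < d; j++) {
    acc_rate[j] = (double)acc_tot[j] / n_iter;
    scales[j] = std::exp(lscale[j]);
  }
  return List::create(_["draws"] = draws, _["loglik"] = ll_out,
                      _["accept_rate"] = acc_rate, _["scale"] = scales);
}
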