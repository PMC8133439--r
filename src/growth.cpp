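#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Growth-model log probability masses over the yearly grid i = 0..T, where
// i indexes calendar years t = a - i (i = 0 at the OLDER boundary a).
// Model codes: 1 exponential(r); 2 double exponential(r1, r2, c);
// 3 exponential-logistic(r1, r2, c, k).
// All masses are built in log space and normalised by log-sum-exp, so large
// windows and rates up to ~0.01 do not overflow.

// Fills lp (length T+1) with the normalised log pmf; returns false when the
// parameters are outside the model's domain.
bool growth_logpmf_fill(int model, const double *par, double a, double b,
                        int logistic_variant, std::vector<double> &lp) {
  const int T = static_cast<int>(a - b);
  lp.resize(T + 1);
  if (model == 1) {
    const double r = par[0];
    if (r <= -1.0) return false;
    const double l1r = log1p(r);
    for (int i = 0; i <= T; ++i) lp[i] = i * l1r;
  } else if (model == 2) {
    const double r1 = par[0], r2 = par[1], c = par[2];
    if (r1 <= -1.0 || r2 <= -1.0) return false;
    if (!(c > b && c < a)) return false;
    // The step from year t_{i-1} = a-i+1 into year t_i uses the rate of the
    // year being left: r1 while a - i + 1 > c, r2 afterwards. This keeps the
    // trajectory continuous, collapses to the single exponential when
    // r1 == r2, and puts the rise-then-fall peak exactly at the changepoint.
    const double l1 = log1p(r1), l2 = log1p(r2);
    lp[0] = 0.0;
    for (int i = 1; i <= T; ++i) lp[i] = lp[i - 1] + ((a - i + 1 > c) ? l1 : l2);
  } else if (model == 3) {
    const double r1 = par[0], r2 = par[1], c = par[2], k = par[3];
    if (r1 <= -1.0) return false;
    if (!(c > b && c < a)) return false;
    if (!(k > 0.0 && k < 1.0)) return false;
    const double lK = log(k) + (a - c) * log1p(r1); // log of k(1+r1)^(a-c)
    if (lK >= 0.0) return false;                    // k(1+r1)^(a-c) >= 1
    // log((1-K)/K) computed stably from log K
    const double lratio = log1p(-exp(lK)) - lK;
    const double l1 = log1p(r1), lk = log(k);
    for (int i = 0; i <= T; ++i) {
      const double t = a - i;
      if (t > c) {
        lp[i] = lk + i * l1; // exponential part: k (1+r1)^i
      } else {
        // logistic part: 1 / (1 + ((1-K)/K) exp(-r2 x)); x is the global
        // index i as printed, or i - (a - c) measured from the changepoint.
        const double x = (logistic_variant == 1) ? (i - (a - c)) : i;
        const double z = lratio - r2 * x;
        lp[i] = (z > 35.0) ? -z : -log1p(exp(z));
      }
    }
  } else {
    return false;
  }
  // log-sum-exp normalisation
  double m = lp[0];
  for (int i = 1; i <= T; ++i) if (lp[i] > m) m = lp[i];
  double s = 0.0;
  for (int i = 0; i <= T; ++i) s += exp(lp[i] - m);
  const double lse = m + log(s);
  for (int i = 0; i <= T; ++i) lp[i] -= lse;
  return true;
}

// [[Rcpp::export]]
NumericVector cpp_growth_logpmf(int model, NumericVector par, double a,
                                double b, int logistic_variant) {
  std::vector<double> lp;
  if (!growth_logpmf_fill(model, par.begin(), a, b, logistic_variant, lp))
    stop("Growth-model parameters outside the model's domain.");
  return NumericVector(lp.begin(), lp.end());
}
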