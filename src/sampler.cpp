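#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

bool growth_logpmf_fill(int model, const double *par, double a, double b,
                        int logistic_variant, std::vector<double> &lp);

// Prior codes: 1 exponential(rate); 2 normal(mu, sigma);
// 3 truncated normal(mu, sigma, lower, upper); 4 uniform(lower, upper);
// 5 fixed(value).
static double prior_logpdf_c(int type, const double *hp, double x) {
  switch (type) {
  case 1:
    if (x < 0.0) return R_NegInf;
    return log(hp[0]) - hp[0] * x;
  case 2:
    return R::dnorm(x, hp[0], hp[1], 1);
  case 3: {
    if (x < hp[2] || x > hp[3]) return R_NegInf;
    double z = R::pnorm(hp[3], hp[0], hp[1], 1, 0) -
               R::pnorm(hp[2], hp[0], hp[1], 1, 0);
    return R::dnorm(x, hp[0], hp[1], 1) - log(z);
  }
  case 4:
    if (x < hp[0] || x > hp[1]) return R_NegInf;
    return -log(hp[1] - hp[0]);
  case 5:
    return 0.0; // fixed parameters never move
  }
  return R_NegInf;
}

// Single-chain sampler for the hierarchical model
//   theta_j ~ BoundedGrowth(a, b, params)   (discrete, yearly)
//   X_j     ~ Normal(mu(theta_j), sigma_j)
// Growth parameters move by univariate adaptive Gaussian random-walk MH
// (target acceptance `target_accept`, proposal log-sd nudged every
// `adapt_interval` iterations with Robbins-Monro decay); latent calendar
// dates move by exact discrete Gibbs from their categorical full
// conditional p(theta_j = t | .) proportional to p_t * N(X_j; mu(t), s_t).
//
// The per-date likelihood over grid years, exp(loglik_j(t) - max_t
// loglik_j(t)), is passed as contiguous band segments: for date j the
// nonzero grid columns are band_lo[j]..band_hi[j] (0-based) and their
// values sit at band_vals[band_off[j] .. band_off[j] + width - 1]. Outside
// the band the likelihood is numerically zero (truncation at 1e-14 of the
// row maximum — a likelihood evaluation detail, not a model choice).
// Uses R's RNG throughout, so results are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_run_chain(NumericVector band_vals, IntegerVector band_off,
                   IntegerVector band_lo, IntegerVector band_hi, int model,
                   int logistic_variant, NumericVector init,
                   IntegerVector prior_type, NumericMatrix prior_hp, // 4 x P, one column per parameter
                   double a, double b, int n_iter, int burnin, int thin,
                   double target_accept, int adapt_interval,
                   bool store_theta, IntegerVector theta_init) {
  const int n = band_lo.size();
  const int G = static_cast<int>(a - b) + 1;
  const int P = init.size();

  std::vector<double> par(init.begin(), init.end());
  std::vector<int> theta(theta_init.begin(), theta_init.end());
  std::vector<double> counts(G, 0.0);
  for (int j = 0; j < n; ++j) counts[theta[j]] += 1.0;

  std::vector<double> lp(G), lp_prop(G), p(G), w(G);
  if (!growth_logpmf_fill(model, par.data(), a, b, logistic_variant, lp))
    stop("Initial growth parameters outside the model's domain.");
  for (int i = 0; i < G; ++i) p[i] = exp(lp[i]);

  auto theta_loglik = [&](const std::vector<double> &lpv) {
    double s = 0.0;
    for (int i = 0; i < G; ++i)
      if (counts[i] > 0.0) s += counts[i] * lpv[i];
    return s;
  };
  auto prior_total = [&](const std::vector<double> &pv) {
    double s = 0.0;
    for (int k = 0; k < P; ++k)
      s += prior_logpdf_c(prior_type[k], &prior_hp(0, k), pv[k]);
    return s;
  };

  double cur_ll = theta_loglik(lp);
  double cur_lprior = prior_total(par);
  if (!R_finite(cur_lprior))
    stop("Initial parameter values have zero prior density.");

  std::vector<double> log_sd(P, log(0.1));
  for (int k = 0; k < P; ++k) {
    // initial proposal scale: the prior's rough spread shrunk by sqrt(n),
    // anticipating the posterior contraction the data will impose
    double s0 = 0.1;
    if (prior_type[k] == 1) s0 = 1.0 / prior_hp(0, k);
    else if (prior_type[k] == 2 || prior_type[k] == 3) s0 = prior_hp(1, k);
    else if (prior_type[k] == 4) s0 = (prior_hp(1, k) - prior_hp(0, k)) / 4.0;
    log_sd[k] = log(s0 / sqrt(static_cast<double>(n) + 1.0));
  }
  std::vector<int> acc_batch(P, 0), acc_total(P, 0), n_batch(P, 0),
      n_total(P, 0);
  int batch = 0;

  const int n_keep = (n_iter > burnin) ? (n_iter - burnin) / thin : 0;
  NumericMatrix draws(n_keep, P);
  IntegerMatrix theta_draws(store_theta ? n_keep : 0, store_theta ? n : 0);
  int kept = 0;

  RNGScope scope;
  for (int it = 1; it <= n_iter; ++it) {
    // --- adaptive RW-MH update of each free growth parameter ---
    for (int k = 0; k < P; ++k) {
      if (prior_type[k] == 5) continue;
      std::vector<double> prop(par);
      prop[k] += R::norm_rand() * exp(log_sd[k]);
      n_batch[k]++;
      if (it > burnin) n_total[k]++; // reported rates are post-burn-in
      double lprior_prop = prior_total(prop);
      if (R_finite(lprior_prop) &&
          growth_logpmf_fill(model, prop.data(), a, b, logistic_variant,
                             lp_prop)) {
        double ll_prop = theta_loglik(lp_prop);
        double lr = (ll_prop + lprior_prop) - (cur_ll + cur_lprior);
        if (lr >= 0.0 || log(R::unif_rand()) < lr) {
          par = prop;
          lp.swap(lp_prop);
          cur_ll = ll_prop;
          cur_lprior = lprior_prop;
          for (int i = 0; i < G; ++i) p[i] = exp(lp[i]);
          acc_batch[k]++;
          if (it > burnin) acc_total[k]++;
        }
      }
    }
    if (adapt_interval > 0 && it % adapt_interval == 0) {
      ++batch;
      // Robbins-Monro decay; the factor 2 lets the scale cross several
      // orders of magnitude within a typical burn-in while adaptation
      // still vanishes asymptotically
      const double step = 2.0 / sqrt(static_cast<double>(batch));
      for (int k = 0; k < P; ++k) {
        if (prior_type[k] == 5 || n_batch[k] == 0) continue;
        double rate = static_cast<double>(acc_batch[k]) / n_batch[k];
        log_sd[k] += step * (rate - target_accept);
        acc_batch[k] = 0; n_batch[k] = 0;
      }
    }

    // --- exact Gibbs update of each latent calendar date ---
    for (int j = 0; j < n; ++j) {
      const int lo = band_lo[j], hi = band_hi[j];
      const double *dj = &band_vals[band_off[j]];
      const int width = hi - lo + 1;
      double tot = 0.0;
      for (int t = 0; t < width; ++t) {
        w[t] = dj[t] * p[lo + t];
        tot += w[t];
      }
      if (tot <= 0.0) continue; // numerically empty conditional: keep theta
      double u = R::unif_rand() * tot;
      int pick = hi;
      double csum = 0.0;
      for (int t = 0; t < width; ++t) {
        csum += w[t];
        if (u <= csum) { pick = lo + t; break; }
      }
      counts[theta[j]] -= 1.0;
      theta[j] = pick;
      counts[pick] += 1.0;
    }
    cur_ll = theta_loglik(lp);

    if (it > burnin && (it - burnin) % thin == 0 && kept < n_keep) {
      for (int k = 0; k < P; ++k) draws(kept, k) = par[k];
      if (store_theta)
        for (int j = 0; j < n; ++j) theta_draws(kept, j) = theta[j];
      ++kept;
    }
  }

  NumericVector acc_rate(P);
  for (int k = 0; k < P; ++k)
    acc_rate[k] = n_total[k] > 0
                      ? static_cast<double>(acc_total[k]) / n_total[k]
                      : NA_REAL;
  return List::create(_["draws"] = draws, _["acceptance_rate"] = acc_rate,
                      _["theta"] = theta_draws,
                      _["proposal_sd"] = NumericVector(log_sd.begin(),
                                                       log_sd.end()));
}
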