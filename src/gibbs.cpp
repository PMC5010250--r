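#include <Rcpp.h>
using namespace Rcpp;

// Log posterior kernel for mu_j on the unit interval, after the change of
// variables x = logit(mu) (the log-Jacobian mu(1-mu) is folded into the
// prior exponents, turning (a0-1, b0-1) into (a0, b0)).
//
//   prior:      mu_j ~ Beta(a0 = mu0*M0, b0 = (1-mu0)*M0)
//   likelihood: theta_nj ~ Beta(mu_j*Mj, (1-mu_j)*Mj), n = 1..N
//
// S1 = sum_n log(theta_nj), S2 = sum_n log(1 - theta_nj) are sufficient for
// the mu update within a sweep, so each MH proposal costs three lgamma calls.
static inline double mu_logpost(double mu, double S1, double S2, int N,
                                double Mj, double a0, double b0) {
  double a = mu * Mj;
  double b = (1.0 - mu) * Mj;
  return a0 * std::log(mu) + b0 * std::log1p(-mu)
       + (a - 1.0) * S1 + (b - 1.0) * S2
       - N * (R::lgammafn(a) + R::lgammafn(b) - R::lgammafn(Mj));
}

static inline double clamp01(double x) {
  const double eps = 1e-12;
  if (x < eps) return eps;
  if (x > 1.0 - eps) return 1.0 - eps;
  return x;
}

// Metropolis-within-Gibbs sampler for the replicate-aware VAF model.
// r, d: N x J matrices of non-reference counts and depths.
// Returns retained samples of mu (n_keep x J) and optionally theta
// (n_keep * N * J, to be given dim (n_keep, N, J) on the R side).
// Uses R's RNG, so set.seed() on the R side makes runs reproducible.
// [[Rcpp::export(name = ".gibbs_vaf")]]
List gibbs_vaf(const IntegerMatrix& r, const IntegerMatrix& d,
               double mu0, double M0, const NumericVector& Mj,
               int n_gibbs, int n_mh, int n_warm, int thin,
               bool keep_theta) {
  const int N = r.nrow(), J = r.ncol();
  if (d.nrow() != N || d.ncol() != J || Mj.size() != J)
    stop("count/depth/precision dimensions disagree");
  const int n_keep = (n_gibbs - n_warm) / thin;
  if (n_keep < 1) stop("MCMC schedule retains no samples");

  const double a0 = mu0 * M0, b0 = (1.0 - mu0) * M0;

  NumericVector mu(J), sigma(J, 0.5), S1(J), S2(J);
  NumericMatrix mu_out(n_keep, J);
  NumericVector theta_out(keep_theta ? (double)n_keep * N * J : 0.0);
  NumericMatrix theta(N, J);
  IntegerVector acc(J), acc_post(J);
  long prop_post = 0;

  // initialise mu at the pooled, lightly smoothed non-reference rate
  for (int j = 0; j < J; ++j) {
    double rs = 0.0, ds = 0.0;
    for (int n = 0; n < N; ++n) { rs += r(n, j); ds += d(n, j); }
    mu[j] = clamp01((rs + 0.5) / (ds + 1.0));
  }

  const int adapt_block = 50;
  int k = 0;
  for (int t = 1; t <= n_gibbs; ++t) {
    // (i) conjugate draw of theta_nj | mu_j
    for (int j = 0; j < J; ++j) {
      double s1 = 0.0, s2 = 0.0;
      const double aj = mu[j] * Mj[j], bj = (1.0 - mu[j]) * Mj[j];
      for (int n = 0; n < N; ++n) {
        double th = R::rbeta(r(n, j) + aj, d(n, j) - r(n, j) + bj);
        th = clamp01(th);
        theta(n, j) = th;
        s1 += std::log(th);
        s2 += std::log1p(-th);
      }
      S1[j] = s1; S2[j] = s2;
    }

    // (ii) n_mh random-walk MH updates of mu_j on the logit scale
    for (int j = 0; j < J; ++j) {
      double cur = mu[j];
      double lp_cur = mu_logpost(cur, S1[j], S2[j], N, Mj[j], a0, b0);
      for (int s = 0; s < n_mh; ++s) {
        const double x = std::log(cur / (1.0 - cur)) + sigma[j] * R::norm_rand();
        const double prop = clamp01(1.0 / (1.0 + std::exp(-x)));
        const double lp_prop = mu_logpost(prop, S1[j], S2[j], N, Mj[j], a0, b0);
        if (R_finite(lp_prop) &&
            std::log(R::unif_rand()) < lp_prop - lp_cur) {
          cur = prop; lp_cur = lp_prop;
          acc[j] += 1;
          if (t > n_warm) acc_post[j] += 1;
        }
      }
      mu[j] = cur;
    }
    if (t > n_warm) prop_post += n_mh;

    // proposal-scale adaptation, warm-up only, aiming at 0.2-0.5 acceptance
    if (t <= n_warm && t % adapt_block == 0) {
      for (int j = 0; j < J; ++j) {
        const double rate = (double)acc[j] / (adapt_block * n_mh);
        if (rate < 0.2) sigma[j] *= 0.6;
        else if (rate > 0.5) sigma[j] *= 1.6;
        acc[j] = 0;
      }
    }

    if (t > n_warm && (t - n_warm) % thin == 0) {
      for (int j = 0; j < J; ++j) {
        mu_out(k, j) = mu[j];
        if (keep_theta)
          for (int n = 0; n < N; ++n)
            theta_out[k + (double)n_keep * (n + (double)N * j)] = theta(n, j);
      }
      ++k;
    }
  }

  NumericVector acc_rate(J);
  for (int j = 0; j < J; ++j)
    acc_rate[j] = prop_post > 0 ? (double)acc_post[j] / prop_post : NA_REAL;

  return List::create(_["mu"] = mu_out,
                      _["theta"] = theta_out,
                      _["accept_rate"] = acc_rate,
                      _["proposal_sd"] = sigma);
}
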