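#include <Rcpp.h>
using namespace Rcpp;

// Log posterior of the 2x2 factorial log-binomial model with independent
// normal priors on (beta0, beta1, beta2, beta3).  Cells are ordered
// (depth, duration) = (0,0), (1,0), (0,1), (1,1).  Returns -Inf whenever any
// implied cell probability reaches 1 (the support constraint p < 1).
static double log_post(const double b[4],
                       const int ev[4], const int tot[4],
                       const double mu[4], const double tau[4]) {
  double eta[4];
  eta[0] = b[0];
  eta[1] = b[0] + b[1];
  eta[2] = b[0] + b[2];
  eta[3] = b[0] + b[1] + b[2] + b[3];

  double lp = 0.0;
  for (int c = 0; c < 4; ++c) {
    if (eta[c] >= 0.0) return R_NegInf;
    if (tot[c] == 0) continue;               // no-data cell: prior-only
    double p = std::exp(eta[c]);
    lp += ev[c] * eta[c] + (tot[c] - ev[c]) * std::log1p(-p);
  }
  for (int k = 0; k < 4; ++k) {
    double z = (b[k] - mu[k]) / tau[k];
    lp += -0.5 * z * z - std::log(tau[k]) - M_LN_SQRT_2PI;
  }
  return lp;
}

static double log_post_at(double x, int k, double b[4],
                          const int ev[4], const int tot[4],
                          const double mu[4], const double tau[4]) {
  double keep = b[k];
  b[k] = x;
  double lp = log_post(b, ev, tot, mu, tau);
  b[k] = keep;
  return lp;
}

//' @noRd
// [[Rcpp::export(name = ".slice_sample_cpp")]]
NumericMatrix slice_sample_cpp(IntegerVector events, IntegerVector totals,
                               NumericVector mu, NumericVector tau,
                               NumericVector init, int n_iter,
                               double w, int max_steps) {
  int ev[4], tot[4];
  double muv[4], tauv[4], b[4];
  for (int k = 0; k < 4; ++k) {
    ev[k] = events[k]; tot[k] = totals[k];
    muv[k] = mu[k]; tauv[k] = tau[k];
    b[k] = init[k];
  }
  double lp = log_post(b, ev, tot, muv, tauv);
  if (!R_FINITE(lp)) stop("initial point is inadmissible (log-posterior -Inf)");

  NumericMatrix out(n_iter, 4);
  RNGScope scope;  // use R's RNG so seeds set in R govern the chain

  for (int it = 0; it < n_iter; ++it) {
    // univariate slice sampling with stepping out (Neal 2003), one sweep
    for (int k = 0; k < 4; ++k) {
      // near-degenerate priors pin a coordinate; shrink the step width so
      // stepping out stays proportionate to the conditional scale
      double wk = std::min(w, 6.0 * tauv[k]);
      if (wk <= 0.0) continue;
      double y = lp + std::log(unif_rand());
      double x0 = b[k];
      double L = x0 - wk * unif_rand();
      double R = L + wk;
      int J = (int)std::floor(max_steps * unif_rand());
      int K = (max_steps - 1) - J;
      while (J-- > 0 && y < log_post_at(L, k, b, ev, tot, muv, tauv)) L -= wk;
      while (K-- > 0 && y < log_post_at(R, k, b, ev, tot, muv, tauv)) R += wk;
      for (;;) {
        double x1 = L + unif_rand() * (R - L);
        double lp1 = log_post_at(x1, k, b, ev, tot, muv, tauv);
        if (y < lp1) { b[k] = x1; lp = lp1; break; }
        if (x1 < x0) L = x1; else R = x1;
      }
    }
    for (int k = 0; k < 4; ++k) out(it, k) = b[k];
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".log_post_cpp")]]
double log_post_cpp(NumericVector beta, IntegerVector events,
                    IntegerVector totals, NumericVector mu,
                    NumericVector tau) {
  int ev[4], tot[4];
  double muv[4], tauv[4], b[4];
  for (int k = 0; k < 4; ++k) {
    ev[k] = events[k]; tot[k] = totals[k];
    muv[k] = mu[k]; tauv[k] = tau[k];
    b[k] = beta[k];
  }
  return log_post(b, ev, tot, muv, tauv);
}
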