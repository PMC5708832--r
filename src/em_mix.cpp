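#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// EM iterations for a univariate normal mixture from given starting
// parameters. Component sds are floored at var_floor. Returns final
// parameters, the per-iteration log-likelihood trace, and posterior
// responsibilities.
// [[Rcpp::export]]
List em_mix_core(NumericVector x, NumericVector alpha0, NumericVector mu0,
                 NumericVector sigma0, double tol, int max_iter,
                 double var_floor) {
  const int n = x.size();
  const int K = alpha0.size();
  std::vector<double> alpha(alpha0.begin(), alpha0.end());
  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<double> sigma(sigma0.begin(), sigma0.end());
  NumericMatrix post(n, K);
  std::vector<double> trace;
  trace.reserve(64);
  const double log2pi = std::log(2.0 * M_PI);
  bool floored = false;
  double ll_old = R_NegInf, ll = R_NegInf;

  for (int iter = 0; iter < max_iter; ++iter) {
    // E-step and log-likelihood
    ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double rowsum = 0.0;
      for (int k = 0; k < K; ++k) {
        double z = (x[i] - mu[k]) / sigma[k];
        double d = alpha[k] *
          std::exp(-0.5 * (z * z + log2pi) - std::log(sigma[k]));
        post(i, k) = d;
        rowsum += d;
      }
      if (rowsum < DBL_MIN) rowsum = DBL_MIN;
      ll += std::log(rowsum);
      for (int k = 0; k < K; ++k) post(i, k) /= rowsum;
    }
    trace.push_back(ll);
    if (R_finite(ll_old) && std::fabs(ll - ll_old) < tol) break;
    ll_old = ll;
    // M-step
    for (int k = 0; k < K; ++k) {
      double nk = 0.0, sx = 0.0;
      for (int i = 0; i < n; ++i) { nk += post(i, k); sx += post(i, k) * x[i]; }
      if (nk < 1e-10) nk = 1e-10;
      alpha[k] = nk / n;
      mu[k] = sx / nk;
      double ss = 0.0;
      for (int i = 0; i < n; ++i) {
        double d = x[i] - mu[k];
        ss += post(i, k) * d * d;
      }
      double s = std::sqrt(ss / nk);
      if (s < var_floor) { s = var_floor; floored = true; }
      sigma[k] = s;
    }
  }
  return List::create(
    _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
    _["mu"] = NumericVector(mu.begin(), mu.end()),
    _["sigma"] = NumericVector(sigma.begin(), sigma.end()),
    _["log_likelihood"] = ll,
    _["posterior"] = post,
    _["loglik_trace"] = NumericVector(trace.begin(), trace.end()),
    _["sigma_floored"] = floored);
}
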