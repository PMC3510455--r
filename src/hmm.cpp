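#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double gauss_density(double x, double mu, double sd) {
  const double z = (x - mu) / sd;
  double d = std::exp(-0.5 * z * z) / (sd * 2.5066282746310002);
  return (d < 1e-300) ? 1e-300 : d;
}

// Scaled forward-backward pass for a Gaussian-emission HMM on one trace.
// Returns the per-trace log-likelihood and the sufficient statistics needed
// by the Baum-Welch M-step: occupancy sums, first/second moments weighted by
// the posterior, expected transition counts and the posterior at t = 1.
// [[Rcpp::export(name = ".hmm_estep_cpp")]]
List hmm_estep_cpp(NumericVector obs, NumericVector means, NumericVector sds,
                   NumericMatrix trans, NumericVector init) {
  const int T = obs.size(), K = means.size();
  if (T < 1) stop("empty trace");
  NumericMatrix b(T, K), alpha(T, K), beta(T, K);
  NumericVector scale(T);
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k)
      b(t, k) = gauss_density(obs[t], means[k], sds[k]);
  // forward
  double c0 = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = init[k] * b(0, k); c0 += alpha(0, k); }
  scale[0] = c0;
  for (int k = 0; k < K; ++k) alpha(0, k) /= c0;
  for (int t = 1; t < T; ++t) {
    double ct = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * trans(j, k);
      alpha(t, k) = a * b(t, k);
      ct += alpha(t, k);
    }
    if (ct <= 0) ct = 1e-300;
    scale[t] = ct;
    for (int k = 0; k < K; ++k) alpha(t, k) /= ct;
  }
  // backward
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += trans(k, j) * b(t + 1, j) * beta(t + 1, j);
      beta(t, k) = s / scale[t + 1];
    }
  }
  // sufficient statistics
  NumericVector gamma_sum(K), gamma_x(K), gamma_xx(K), gamma1(K);
  NumericMatrix xi_sum(K, K);
  for (int t = 0; t < T; ++t) {
    double norm = 0.0;
    for (int k = 0; k < K; ++k) norm += alpha(t, k) * beta(t, k);
    for (int k = 0; k < K; ++k) {
      double g = alpha(t, k) * beta(t, k) / norm;
      gamma_sum[k] += g;
      gamma_x[k] += g * obs[t];
      gamma_xx[k] += g * obs[t] * obs[t];
      if (t == 0) gamma1[k] = g;
    }
  }
  for (int t = 0; t + 1 < T; ++t) {
    double norm = 0.0;
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        norm += alpha(t, j) * trans(j, k) * b(t + 1, k) * beta(t + 1, k);
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        xi_sum(j, k) += alpha(t, j) * trans(j, k) * b(t + 1, k) * beta(t + 1, k) / norm;
  }
  double loglik = 0.0;
  for (int t = 0; t < T; ++t) loglik += std::log(scale[t]);
  return List::create(_["loglik"] = loglik, _["gamma_sum"] = gamma_sum,
                      _["gamma_x"] = gamma_x, _["gamma_xx"] = gamma_xx,
                      _["xi_sum"] = xi_sum, _["gamma1"] = gamma1);
}

// Most-probable joint state path (Viterbi) in log space; returns 1-based states.
// [[Rcpp::export(name = ".hmm_viterbi_cpp")]]
IntegerVector hmm_viterbi_cpp(NumericVector obs, NumericVector means,
                              NumericVector sds, NumericMatrix trans,
                              NumericVector init) {
  const int T = obs.size(), K = means.size();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  NumericMatrix lA(K, K);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k)
      lA(j, k) = std::log(trans(j, k) > 0 ? trans(j, k) : 1e-300);
  for (int k = 0; k < K; ++k)
    delta(0, k) = std::log(init[k] > 0 ? init[k] : 1e-300) +
                  std::log(gauss_density(obs[0], means[k], sds[k]));
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = delta(t - 1, 0) + lA(0, k);
      int arg = 0;
      for (int j = 1; j < K; ++j) {
        double v = delta(t - 1, j) + lA(j, k);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + std::log(gauss_density(obs[t], means[k], sds[k]));
      psi(t, k) = arg;
    }
  }
  IntegerVector path(T);
  int arg = 0;
  for (int k = 1; k < K; ++k) if (delta(T - 1, k) > delta(T - 1, arg)) arg = k;
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = psi(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}
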