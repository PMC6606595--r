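#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for one sequence.
//
// logE: T x K matrix of per-position log emission probabilities
// a:    length-K initial state distribution
// b:    K x K transition matrix (rows sum to 1)
//
// Per-position scaling keeps the recursion in linear space; the log emission
// matrix is shifted by its row maximum before exponentiation so that models
// with many species (where a single emission can be ~1e-300) do not underflow.
//
// Returns posteriors (gamma), summed expected transition counts (xiSum),
// the forward log-likelihood, and an independently scaled backward
// log-likelihood (used as a numerical cross-check).
// [[Rcpp::export]]
List fb_core(const NumericMatrix& logE, const NumericVector& a,
             const NumericMatrix& b) {
  const int T = logE.nrow();
  const int K = logE.ncol();
  if (a.size() != K || b.nrow() != K || b.ncol() != K)
    stop("dimension mismatch between emissions, initial and transition parameters");

  NumericMatrix emis(T, K);
  NumericVector shift(T);
  for (int t = 0; t < T; ++t) {
    double m = logE(t, 0);
    for (int k = 1; k < K; ++k) if (logE(t, k) > m) m = logE(t, k);
    shift[t] = m;
    for (int k = 0; k < K; ++k) emis(t, k) = std::exp(logE(t, k) - m);
  }

  NumericMatrix alpha(T, K);
  NumericVector cvec(T);
  double csum;

  csum = 0.0;
  for (int k = 0; k < K; ++k) {
    alpha(0, k) = a[k] * emis(0, k);
    csum += alpha(0, k);
  }
  if (csum <= 0.0) stop("forward scaling constant underflowed to zero at position 1");
  cvec[0] = csum;
  for (int k = 0; k < K; ++k) alpha(0, k) /= csum;

  for (int t = 1; t < T; ++t) {
    csum = 0.0;
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int u = 0; u < K; ++u) s += alpha(t - 1, u) * b(u, k);
      s *= emis(t, k);
      alpha(t, k) = s;
      csum += s;
    }
    if (csum <= 0.0) stop("forward scaling constant underflowed to zero");
    cvec[t] = csum;
    for (int k = 0; k < K; ++k) alpha(t, k) /= csum;
  }

  double loglik = 0.0;
  for (int t = 0; t < T; ++t) loglik += std::log(cvec[t]) + shift[t];

  // backward pass sharing the forward scaling constants -> gamma, xi
  NumericMatrix beta(T, K);
  NumericMatrix xiSum(K, K);
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int u = 0; u < K; ++u)
        s += b(k, u) * emis(t + 1, u) * beta(t + 1, u);
      beta(t, k) = s / cvec[t + 1];
    }
    for (int k = 0; k < K; ++k) {
      double ak = alpha(t, k);
      if (ak == 0.0) continue;
      for (int u = 0; u < K; ++u)
        xiSum(k, u) += ak * b(k, u) * emis(t + 1, u) * beta(t + 1, u) / cvec[t + 1];
    }
  }

  NumericMatrix gamma(T, K);
  for (int t = 0; t < T; ++t) {
    double rs = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); rs += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= rs;
  }

  // independently scaled backward recursion for a second log-likelihood
  NumericVector bb(K), bbNext(K);
  double loglikB = 0.0;
  for (int k = 0; k < K; ++k) bbNext[k] = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    double d = 0.0;
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int u = 0; u < K; ++u)
        s += b(k, u) * emis(t + 1, u) * bbNext[u];
      bb[k] = s;
      d += s;
    }
    if (d <= 0.0) stop("backward scaling constant underflowed to zero");
    for (int k = 0; k < K; ++k) bbNext[k] = bb[k] / d;
    loglikB += std::log(d);
  }
  double s0 = 0.0;
  for (int k = 0; k < K; ++k) s0 += a[k] * emis(0, k) * bbNext[k];
  loglikB += std::log(s0);
  for (int t = 0; t < T; ++t) loglikB += shift[t];

  return List::create(_["gamma"] = gamma, _["xiSum"] = xiSum,
                      _["loglik"] = loglik, _["loglikBackward"] = loglikB);
}

// Run-length scan: number of maximal constant runs in an integer vector.
// [[Rcpp::export]]
int run_count(const IntegerVector& x) {
  if (x.size() == 0) return 0;
  int n = 1;
  for (R_xlen_t i = 1; i < x.size(); ++i) if (x[i] != x[i - 1]) ++n;
  return n;
}
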