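#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Scaled forward-backward E-step over a set of independent sequences laid
// out in one T x K matrix of log emission probabilities. Sequence s spans
// rows [seq_starts[s], seq_ends[s]) (0-based). Transitions never cross
// sequence boundaries (chromosome ends break the chain).
//
// Returns per-position posteriors gamma (T x K), the accumulated expected
// transition counts xi (K x K), the accumulated first-position posterior
// (K), and the total log-likelihood.
// [[Rcpp::export]]
List hmm_estep_cpp(NumericMatrix logB, NumericMatrix A, NumericVector pi,
                   IntegerVector seq_starts, IntegerVector seq_ends) {
  const int T = logB.nrow(), K = logB.ncol(), S = seq_starts.size();
  NumericMatrix gamma(T, K);
  NumericMatrix xi(K, K);
  NumericVector gamma1(K);
  double loglik = 0.0;

  std::vector<double> alpha(static_cast<size_t>(T) * K);
  std::vector<double> b(static_cast<size_t>(T) * K);
  std::vector<double> beta_next(K), beta_cur(K);
  std::vector<double> cvec(T);

  for (int s = 0; s < S; ++s) {
    const int t0 = seq_starts[s], t1 = seq_ends[s];
    // shifted linear emissions and forward pass with per-step scaling
    for (int t = t0; t < t1; ++t) {
      double m = logB(t, 0);
      for (int k = 1; k < K; ++k) if (logB(t, k) > m) m = logB(t, k);
      loglik += m;
      double c = 0.0;
      if (t == t0) {
        for (int k = 0; k < K; ++k) {
          double v = pi[k] * std::exp(logB(t, k) - m);
          b[static_cast<size_t>(t) * K + k] = std::exp(logB(t, k) - m);
          alpha[static_cast<size_t>(t) * K + k] = v;
          c += v;
        }
      } else {
        for (int k = 0; k < K; ++k)
          b[static_cast<size_t>(t) * K + k] = std::exp(logB(t, k) - m);
        for (int j = 0; j < K; ++j) {
          double acc = 0.0;
          for (int i = 0; i < K; ++i)
            acc += alpha[static_cast<size_t>(t - 1) * K + i] * A(i, j);
          double v = acc * b[static_cast<size_t>(t) * K + j];
          alpha[static_cast<size_t>(t) * K + j] = v;
          c += v;
        }
      }
      if (c <= 0) c = DBL_MIN;
      cvec[t] = c;
      loglik += std::log(c);
      for (int k = 0; k < K; ++k) alpha[static_cast<size_t>(t) * K + k] /= c;
    }
    // backward pass; gamma and xi on the fly
    for (int k = 0; k < K; ++k) {
      beta_next[k] = 1.0;
      gamma(t1 - 1, k) = alpha[static_cast<size_t>(t1 - 1) * K + k];
    }
    for (int t = t1 - 2; t >= t0; --t) {
      const double cn = cvec[t + 1];
      for (int i = 0; i < K; ++i) {
        double acc = 0.0;
        for (int j = 0; j < K; ++j) {
          double w = A(i, j) * b[static_cast<size_t>(t + 1) * K + j] *
                     beta_next[j] / cn;
          xi(i, j) += alpha[static_cast<size_t>(t) * K + i] * w;
          acc += w;
        }
        beta_cur[i] = acc;
        gamma(t, i) = alpha[static_cast<size_t>(t) * K + i] * acc;
      }
      // guard against drift: renormalize gamma row
      double g = 0.0;
      for (int i = 0; i < K; ++i) g += gamma(t, i);
      if (g > 0) for (int i = 0; i < K; ++i) gamma(t, i) /= g;
      std::swap(beta_next, beta_cur);
    }
    for (int k = 0; k < K; ++k) gamma1[k] += gamma(t0, k);
  }
  return List::create(_["gamma"] = gamma, _["xi"] = xi,
                      _["gamma1"] = gamma1, _["loglik"] = loglik);
}

// Viterbi decoding in log space over the same sequence layout; returns
// 1-based state indices of the jointly most probable path per sequence.
// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(NumericMatrix logB, NumericMatrix logA,
                              NumericVector logpi, IntegerVector seq_starts,
                              IntegerVector seq_ends) {
  const int T = logB.nrow(), K = logB.ncol(), S = seq_starts.size();
  IntegerVector path(T);
  std::vector<double> d_prev(K), d_cur(K);
  std::vector<int> bp(static_cast<size_t>(T) * K);

  for (int s = 0; s < S; ++s) {
    const int t0 = seq_starts[s], t1 = seq_ends[s];
    for (int k = 0; k < K; ++k) d_prev[k] = logpi[k] + logB(t0, k);
    for (int t = t0 + 1; t < t1; ++t) {
      for (int j = 0; j < K; ++j) {
        double best = d_prev[0] + logA(0, j);
        int arg = 0;
        for (int i = 1; i < K; ++i) {
          double v = d_prev[i] + logA(i, j);
          if (v > best) { best = v; arg = i; }
        }
        d_cur[j] = best + logB(t, j);
        bp[static_cast<size_t>(t) * K + j] = arg;
      }
      std::swap(d_prev, d_cur);
    }
    int arg = 0;
    for (int k = 1; k < K; ++k) if (d_prev[k] > d_prev[arg]) arg = k;
    path[t1 - 1] = arg + 1;
    for (int t = t1 - 1; t > t0; --t) {
      arg = bp[static_cast<size_t>(t) * K + arg];
      path[t - 1] = arg + 1;
    }
  }
  return path;
}

// Per-bin posterior state probabilities (forward-backward), returned as a
// T x K matrix plus total log-likelihood.
// [[Rcpp::export]]
List hmm_posterior_cpp(NumericMatrix logB, NumericMatrix A, NumericVector pi,
                       IntegerVector seq_starts, IntegerVector seq_ends) {
  List e = hmm_estep_cpp(logB, A, pi, seq_starts, seq_ends);
  return List::create(_["gamma"] = e["gamma"], _["loglik"] = e["loglik"]);
}
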