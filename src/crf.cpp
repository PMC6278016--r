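#include <Rcpp.h>
using namespace Rcpp;

// Linear-chain CRF inference primitives. Scores arrive as a dense
// (total positions x labels) emission matrix plus a (labels x labels)
// transition matrix; sequences are delimited by `starts`/`lens`
// (1-based starts). All arithmetic is in the log domain.

static inline double log_sum_exp(const double* v, int n) {
  double m = v[0];
  for (int i = 1; i < n; ++i) if (v[i] > m) m = v[i];
  if (m == R_NegInf) return R_NegInf;
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += std::exp(v[i] - m);
  return m + std::log(s);
}

// Forward-backward: returns total log partition, per-position label
// marginals and expected transition counts (summed over sequences).
// [[Rcpp::export]]
List crf_forward_backward(const NumericMatrix& emit,
                          const IntegerVector& starts,
                          const IntegerVector& lens,
                          const NumericMatrix& trans) {
  const int L = emit.ncol();
  const int nseq = starts.size();
  NumericMatrix marg(emit.nrow(), L);
  NumericMatrix etrans(L, L);
  double total_logZ = 0.0;

  std::vector<double> work(L);
  for (int s = 0; s < nseq; ++s) {
    const int off = starts[s] - 1;
    const int T = lens[s];
    NumericMatrix alpha(T, L), beta(T, L);

    for (int l = 0; l < L; ++l) alpha(0, l) = emit(off, l);
    for (int t = 1; t < T; ++t) {
      for (int l = 0; l < L; ++l) {
        for (int k = 0; k < L; ++k) work[k] = alpha(t - 1, k) + trans(k, l);
        alpha(t, l) = log_sum_exp(work.data(), L) + emit(off + t, l);
      }
    }
    for (int l = 0; l < L; ++l) beta(T - 1, l) = 0.0;
    for (int t = T - 2; t >= 0; --t) {
      for (int l = 0; l < L; ++l) {
        for (int k = 0; k < L; ++k)
          work[k] = trans(l, k) + emit(off + t + 1, k) + beta(t + 1, k);
        beta(t, l) = log_sum_exp(work.data(), L);
      }
    }
    for (int l = 0; l < L; ++l) work[l] = alpha(T - 1, l);
    const double logZ = log_sum_exp(work.data(), L);
    total_logZ += logZ;

    for (int t = 0; t < T; ++t)
      for (int l = 0; l < L; ++l)
        marg(off + t, l) = std::exp(alpha(t, l) + beta(t, l) - logZ);

    for (int t = 1; t < T; ++t)
      for (int k = 0; k < L; ++k)
        for (int l = 0; l < L; ++l)
          etrans(k, l) += std::exp(alpha(t - 1, k) + trans(k, l) +
                                   emit(off + t, l) + beta(t, l) - logZ);
  }
  return List::create(_["logZ"] = total_logZ,
                      _["marginals"] = marg,
                      _["expected_trans"] = etrans);
}

// Viterbi decoding; ties resolved toward the lower label index so that
// decoding is fully deterministic. Returns 1-based label indices.
// [[Rcpp::export]]
IntegerVector crf_viterbi(const NumericMatrix& emit,
                          const IntegerVector& starts,
                          const IntegerVector& lens,
                          const NumericMatrix& trans) {
  const int L = emit.ncol();
  const int nseq = starts.size();
  IntegerVector out(emit.nrow());

  for (int s = 0; s < nseq; ++s) {
    const int off = starts[s] - 1;
    const int T = lens[s];
    NumericMatrix delta(T, L);
    IntegerMatrix back(T, L);

    for (int l = 0; l < L; ++l) delta(0, l) = emit(off, l);
    for (int t = 1; t < T; ++t) {
      for (int l = 0; l < L; ++l) {
        double best = delta(t - 1, 0) + trans(0, l);
        int arg = 0;
        for (int k = 1; k < L; ++k) {
          const double v = delta(t - 1, k) + trans(k, l);
          if (v > best) { best = v; arg = k; }
        }
        delta(t, l) = best + emit(off + t, l);
        back(t, l) = arg;
      }
    }
    int arg = 0;
    for (int l = 1; l < L; ++l) if (delta(T - 1, l) > delta(T - 1, arg)) arg = l;
    out[off + T - 1] = arg + 1;
    for (int t = T - 1; t > 0; --t) {
      arg = back(t, arg);
      out[off + t - 1] = arg + 1;
    }
  }
  return out;
}
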