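// Sequential kernels of the two-state forward filter and backward sampler.
// The recursions are O(n) with a two-element state; R-level vectorization
// cannot help, so the loops live here.

#include <Rcpp.h>
using namespace Rcpp;

static inline double lse2(double a, double b) {
  double m = a > b ? a : b;
  return m + log1p(std::exp(-std::fabs(a - b)));
}

// Forward filter of a two-state chain in log space. em1/em2 are per-step
// emission log densities; l11[u] = log P(state 1 at u | state 1 at u-1),
// l21[u] = log P(1 | 2), l12[u] = log P(2 | 1), l22[u] = log P(2 | 2)
// (entries at u = 0 are unused); both states start from log(1/2).
// [[Rcpp::export(name = ".fwd_pair_cpp")]]
List fwd_pair_cpp(NumericVector em1, NumericVector em2,
                  NumericVector l11, NumericVector l21,
                  NumericVector l12, NumericVector l22) {
  int n = em1.size();
  NumericVector f1(n), f2(n);
  if (n == 0) return List::create(_["f1"] = f1, _["f2"] = f2);
  const double lhalf = -0.6931471805599453;
  f1[0] = lhalf + em1[0];
  f2[0] = lhalf + em2[0];
  for (int u = 1; u < n; ++u) {
    f1[u] = lse2(f1[u - 1] + l11[u], f2[u - 1] + l21[u]) + em1[u];
    f2[u] = lse2(f1[u - 1] + l12[u], f2[u - 1] + l22[u]) + em2[u];
  }
  return List::create(_["f1"] = f1, _["f2"] = f2);
}

// Final normalizing constant of the same filter: the marginal log-likelihood
// with the state path summed out.
// [[Rcpp::export(name = ".fwd_pair_loglik_cpp")]]
double fwd_pair_loglik_cpp(NumericVector em1, NumericVector em2,
                           NumericVector l11, NumericVector l21,
                           NumericVector l12, NumericVector l22) {
  int n = em1.size();
  if (n == 0) return 0.0;
  const double lhalf = -0.6931471805599453;
  double f1 = lhalf + em1[0];
  double f2 = lhalf + em2[0];
  for (int u = 1; u < n; ++u) {
    double g1 = lse2(f1 + l11[u], f2 + l21[u]) + em1[u];
    f2 = lse2(f1 + l12[u], f2 + l22[u]) + em2[u];
    f1 = g1;
  }
  return lse2(f1, f2);
}

// Backward pass drawing one path given the filtered probabilities:
// p_if1[u] / p_if2[u] are P(state u = 1 | next state = 1 or 2), ru the
// uniform variates (drawn in R so the R RNG stream governs), last the
// sampled final state.
// [[Rcpp::export(name = ".bwd_sample_cpp")]]
IntegerVector bwd_sample_cpp(NumericVector p_if1, NumericVector p_if2,
                             NumericVector ru, int last) {
  int n = p_if1.size() + 1;
  IntegerVector out(n);
  out[n - 1] = last;
  for (int u = n - 2; u >= 0; --u) {
    double p = (out[u + 1] == 1) ? p_if1[u] : p_if2[u];
    out[u] = (ru[u] < p) ? 1 : 2;
  }
  return out;
}
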