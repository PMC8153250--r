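#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Exact two-sided permutation p-value for a rank correlation.
//
// rx, ry are centered mid-rank vectors. The permutation statistic is
// S = sum(rx * perm(ry)); |rho| is monotone in |S| because the rank
// standard deviations are permutation-invariant. Enumerating distinct
// permutations of the (possibly tied) ry values with std::next_permutation
// is exact: every distinct arrangement has the same multiplicity among the
// n! equally likely permutations.
//
// [[Rcpp::export]]
double exact_perm_spearman_p(NumericVector rx, NumericVector ry) {
  const int n = rx.size();
  if (ry.size() != n) stop("length mismatch");
  if (n > 10) stop("exact permutation limited to n <= 10");
  std::vector<double> x(rx.begin(), rx.end());
  std::vector<double> y(ry.begin(), ry.end());
  double s_obs = 0.0;
  for (int i = 0; i < n; ++i) s_obs += x[i] * y[i];
  const double thr = std::fabs(s_obs) - 1e-9;
  std::sort(y.begin(), y.end());
  double total = 0.0, hits = 0.0;
  do {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += x[i] * y[i];
    total += 1.0;
    if (std::fabs(s) >= thr) hits += 1.0;
  } while (std::next_permutation(y.begin(), y.end()));
  return hits / total;
}
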