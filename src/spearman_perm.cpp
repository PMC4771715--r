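#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Two-sided exact permutation p-value for the Spearman correlation of two
// rank vectors (average-tied ranks allowed).  Enumerates every distinct
// permutation of ry via std::next_permutation; with ties each distinct
// arrangement is equally likely under the null, so counting distinct
// arrangements with uniform weight is exact.  Intended for n <= 10
// (10! = 3,628,800 arrangements).
// [[Rcpp::export]]
double spearman_perm_pvalue(NumericVector rx, NumericVector ry,
                            double rho_obs) {
  const int n = rx.size();
  if (n != ry.size()) stop("rank vectors differ in length");
  if (n > 12) stop("exact enumeration limited to n <= 12");

  std::vector<double> a(rx.begin(), rx.end());
  std::vector<double> b(ry.begin(), ry.end());
  std::sort(b.begin(), b.end());

  double ma = 0.0, mb = 0.0;
  for (int i = 0; i < n; ++i) { ma += a[i]; mb += b[i]; }
  ma /= n; mb /= n;
  double sa = 0.0, sb = 0.0;
  for (int i = 0; i < n; ++i) {
    sa += (a[i] - ma) * (a[i] - ma);
    sb += (b[i] - mb) * (b[i] - mb);
  }
  const double denom = std::sqrt(sa * sb);
  if (denom == 0.0) stop("constant rank vector");

  const double thresh = std::fabs(rho_obs) - 1e-12;
  long long hits = 0, total = 0;
  do {
    double cross = 0.0;
    for (int i = 0; i < n; ++i) cross += (a[i] - ma) * (b[i] - mb);
    if (std::fabs(cross / denom) >= thresh) ++hits;
    ++total;
  } while (std::next_permutation(b.begin(), b.end()));

  return static_cast<double>(hits) / static_cast<double>(total);
}
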