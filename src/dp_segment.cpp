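#include <Rcpp.h>
using namespace Rcpp;

// Exact least-squares segmentation of a 1-d profile.
// Minimises  sum_over_segments(within-segment SSE) + penalty * (#segments)
// by dynamic programming over the last-segment start; O(n^2).
// Ties (within a small relative tolerance) are broken toward fewer segments,
// then toward the earliest last-segment start, so results are deterministic.
// maxseg = 0 disables the maximum-segment-length window.
// [[Rcpp::export(name = ".dp_segment")]]
List dp_segment(NumericVector x, double penalty, int maxseg = 0) {
  const int n = x.size();
  if (n < 1) stop("empty profile");
  std::vector<double> s1(n + 1, 0.0), s2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    if (!R_finite(x[i])) stop("non-finite value in profile");
    s1[i + 1] = s1[i] + x[i];
    s2[i + 1] = s2[i] + x[i] * x[i];
  }
  std::vector<double> dp(n + 1, 0.0);
  std::vector<int> back(n + 1, 0), nseg(n + 1, 0);
  for (int j = 1; j <= n; ++j) {
    double best = R_PosInf;
    int besti = 1, bestk = INT_MAX;
    const int ilo = (maxseg > 0 && j - maxseg + 1 > 1) ? j - maxseg + 1 : 1;
    for (int i = ilo; i <= j; ++i) {
      const int len = j - i + 1;
      const double s = s1[j] - s1[i - 1];
      const double sse = s2[j] - s2[i - 1] - s * s / len;
      const double cost = dp[i - 1] + sse + penalty;
      const int k = nseg[i - 1] + 1;
      const double tol = 1e-9 * (1.0 + std::fabs(best));
      if (cost < best - tol || (cost <= best + tol && k < bestk)) {
        best = cost; besti = i; bestk = k;
      }
    }
    dp[j] = best; back[j] = besti; nseg[j] = bestk;
  }
  // trace back
  const int k = nseg[n];
  IntegerVector starts(k), ends(k);
  int j = n;
  for (int s = k - 1; s >= 0; --s) {
    starts[s] = back[j];
    ends[s] = j;
    j = back[j] - 1;
  }
  NumericVector means(k), sses(k);
  double tot_sse = 0.0;
  for (int s = 0; s < k; ++s) {
    const int i = starts[s], jj = ends[s], len = jj - i + 1;
    const double sum = s1[jj] - s1[i - 1];
    means[s] = sum / len;
    sses[s] = s2[jj] - s2[i - 1] - sum * sum / len;
    tot_sse += sses[s];
  }
  return List::create(_["start"] = starts, _["end"] = ends,
                      _["mean"] = means, _["sse"] = sses,
                      _["total_sse"] = tot_sse,
                      _["objective"] = tot_sse + penalty * k,
                      _["k"] = k);
}
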