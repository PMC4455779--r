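#include <Rcpp.h>
using namespace Rcpp;

// Best candidate segment of x: interval [i, j] (1-based, min_len <= length
// <= max_len, flanks empty or >= min_len) maximizing |mean(interval) -
// mean(complement)|. Returns i = j = 0 when the window cannot be split.
// [[Rcpp::export]]
List best_interval_cpp(NumericVector x, int min_len, int max_len) {
  const int n = x.size();
  if (n < 2 * min_len) {
    return List::create(_["i"] = 0, _["j"] = 0, _["stat"] = NA_REAL);
  }
  std::vector<double> cs(n + 1, 0.0);
  for (int t = 0; t < n; ++t) cs[t + 1] = cs[t] + x[t];
  const double tot = cs[n];
  const int Lmax = std::min(max_len, n - min_len);
  double best_stat = -1.0;
  int best_i = 0, best_j = 0;
  for (int L = min_len; L <= Lmax; ++L) {
    const double invL = 1.0 / L, invC = 1.0 / (n - L);
    for (int i = 0; i <= n - L; ++i) {
      const int p = i;          // flank sizes (0-based start i)
      const int s = n - L - i;
      if ((p != 0 && p < min_len) || (s != 0 && s < min_len)) continue;
      const double intsum = cs[i + L] - cs[i];
      double stat = intsum * invL - (tot - intsum) * invC;
      if (stat < 0) stat = -stat;
      if (stat > best_stat) {
        best_stat = stat;
        best_i = i + 1;
        best_j = i + L;
      }
    }
  }
  return List::create(_["i"] = best_i, _["j"] = best_j,
                      _["stat"] = best_stat);
}
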