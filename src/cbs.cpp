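#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>
#include <utility>

using namespace Rcpp;

// Scan every admissible breakpoint of x[0..n) and return the largest
// absolute two-sample (pooled-variance) t statistic; *best_k receives the
// leftmost maximizing split (size of the left part). A zero-variance window
// with unequal means yields +Inf, so noiseless steps always win the scan.
static double scan_max_t(const double* x, int n, int min_width, int* best_k) {
  double s = 0.0, ss = 0.0;
  for (int i = 0; i < n; ++i) { s += x[i]; ss += x[i] * x[i]; }
  double best = -1.0;
  int bk = -1;
  double s1 = 0.0, ss1 = 0.0;
  for (int k = 1; k <= n - 1; ++k) {
    s1 += x[k - 1];
    ss1 += x[k - 1] * x[k - 1];
    if (k < min_width || n - k < min_width) continue;
    const double n1 = k, n2 = n - k;
    const double m1 = s1 / n1, m2 = (s - s1) / n2;
    double rss = (ss1 - n1 * m1 * m1) + ((ss - ss1) - n2 * m2 * m2);
    if (rss < 0.0) rss = 0.0;          // guard against cancellation
    const double v = rss / (n - 2);
    const double diff = m1 - m2;
    double t;
    if (v <= 0.0) {
      t = (diff == 0.0) ? 0.0 : std::numeric_limits<double>::infinity();
    } else {
      t = std::fabs(diff) / std::sqrt(v * (1.0 / n1 + 1.0 / n2));
    }
    if (t > best) { best = t; bk = k; } // strict '>': leftmost tie wins
  }
  if (best_k) *best_k = bk;
  return best;
}

// Permutation p-value of the observed max |t| within one window, using R's
// RNG. Early exit once the exceedance count guarantees p >= alpha (the
// split will be rejected), which makes flat windows cheap.
static double perm_pvalue(const double* x, int n, int min_width,
                          double t_obs, int n_perm, double alpha) {
  std::vector<double> w(x, x + n);
  int exceed = 0;
  const double reject_at = alpha * (n_perm + 1.0);
  for (int b = 0; b < n_perm; ++b) {
    for (int i = n - 1; i > 0; --i) {   // Fisher-Yates with R RNG
      int j = static_cast<int>(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(w[i], w[j]);
    }
    double t = scan_max_t(w.data(), n, min_width, nullptr);
    if (t >= t_obs) {
      ++exceed;
      if (1.0 + exceed >= reject_at) return alpha;  // p >= alpha: reject
    }
  }
  return (1.0 + exceed) / (n_perm + 1.0);
}

// Recursive binary segmentation of one chromosome profile. Returns the
// 0-based positions k where a new segment starts (0 < k < n), sorted.
// [[Rcpp::export(name = ".cbs_breakpoints")]]
IntegerVector cbs_breakpoints(NumericVector x, double alpha, int min_width,
                              int n_perm) {
  const int n = x.size();
  if (n < 1) stop("empty profile");
  if (min_width < 2) stop("min_width must be >= 2");
  std::vector<int> breaks;
  std::vector<std::pair<int, int> > todo;  // half-open windows [lo, hi)
  todo.push_back(std::make_pair(0, n));
  while (!todo.empty()) {
    const int lo = todo.back().first, hi = todo.back().second;
    todo.pop_back();
    const int len = hi - lo;
    if (len < 2 * min_width) continue;
    int k = -1;
    const double t_obs = scan_max_t(&x[0] + lo, len, min_width, &k);
    if (k < 0 || t_obs <= 0.0) continue;  // constant window
    const double p = perm_pvalue(&x[0] + lo, len, min_width, t_obs,
                                 n_perm, alpha);
    if (p < alpha) {
      breaks.push_back(lo + k);
      todo.push_back(std::make_pair(lo, lo + k));
      todo.push_back(std::make_pair(lo + k, hi));
    }
  }
  std::sort(breaks.begin(), breaks.end());
  return wrap(breaks);
}
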