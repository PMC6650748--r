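// Kendall tau-b via Knight's O(n log n) algorithm, plus a permutation-null
// exceedance counter used by the RSA permutation tests.

#include <Rcpp.h>
#include <algorithm>
#include <random>
#include <vector>

using namespace Rcpp;

// merge sort counting the number of exchanges (discordant pairs)
static double merge_count(std::vector<double>& y, std::vector<double>& buf,
                          size_t lo, size_t hi) {
  if (hi - lo < 2) return 0.0;
  size_t mid = lo + (hi - lo) / 2;
  double swaps = merge_count(y, buf, lo, mid) + merge_count(y, buf, mid, hi);
  size_t i = lo, j = mid, k = lo;
  while (i < mid && j < hi) {
    if (y[j] < y[i]) {
      swaps += (double)(mid - i);
      buf[k++] = y[j++];
    } else {
      buf[k++] = y[i++];
    }
  }
  while (i < mid) buf[k++] = y[i++];
  while (j < hi) buf[k++] = y[j++];
  std::copy(buf.begin() + lo, buf.begin() + hi, y.begin() + lo);
  return swaps;
}

static double tie_term(const std::vector<double>& v) {
  double s = 0.0;
  size_t i = 0;
  while (i < v.size()) {
    size_t j = i;
    while (j < v.size() && v[j] == v[i]) ++j;
    double t = (double)(j - i);
    s += t * (t - 1.0) / 2.0;
    i = j;
  }
  return s;
}

static double tau_b_core(const std::vector<double>& x,
                         const std::vector<double>& y) {
  size_t n = x.size();
  std::vector<size_t> ord(n);
  for (size_t i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    if (x[a] != x[b]) return x[a] < x[b];
    return y[a] < y[b];
  });

  std::vector<double> xs(n), ys(n);
  for (size_t i = 0; i < n; ++i) { xs[i] = x[ord[i]]; ys[i] = y[ord[i]]; }

  // joint ties and x ties on the sorted sequence
  double n3 = 0.0, n1 = 0.0;
  {
    size_t i = 0;
    while (i < n) {
      size_t j = i;
      while (j < n && xs[j] == xs[i] && ys[j] == ys[i]) ++j;
      double t = (double)(j - i);
      n3 += t * (t - 1.0) / 2.0;
      i = j;
    }
    i = 0;
    while (i < n) {
      size_t j = i;
      while (j < n && xs[j] == xs[i]) ++j;
      double t = (double)(j - i);
      n1 += t * (t - 1.0) / 2.0;
      i = j;
    }
  }

  std::vector<double> ysort = ys, buf(n);
  double swaps = merge_count(ysort, buf, 0, n);
  double n2 = tie_term(ysort);  // ysort now fully sorted

  double n0 = (double)n * (n - 1.0) / 2.0;
  double denom = std::sqrt((n0 - n1) * (n0 - n2));
  if (denom == 0.0) return NA_REAL;
  return (n0 - n1 - n2 + n3 - 2.0 * swaps) / denom;
}

// [[Rcpp::export]]
double kendall_tau_cpp(NumericVector x, NumericVector y) {
  if (x.size() != y.size()) stop("x and y must have equal length");
  if (x.size() < 2) stop("need at least 2 observations");
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  return tau_b_core(xv, yv);
}

// Count permutation-null statistics meeting or exceeding the observed
// statistic: y is shuffled n_perm times (Fisher-Yates under a seeded
// mt19937) and tau(y_perm, v) compared with `observed`.
// [[Rcpp::export]]
double kendall_perm_count_cpp(NumericVector y, NumericVector v,
                              int n_perm, double observed,
                              unsigned int seed) {
  if (y.size() != v.size()) stop("y and v must have equal length");
  std::vector<double> yv(y.begin(), y.end()), vv(v.begin(), v.end());
  std::mt19937 rng(seed);
  double r = 0.0;
  const double eps = 1e-12;
  for (int it = 0; it < n_perm; ++it) {
    std::shuffle(yv.begin(), yv.end(), rng);
    double t = tau_b_core(yv, vv);
    if (!ISNA(t) && t >= observed - eps) r += 1.0;
  }
  return r;
}
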