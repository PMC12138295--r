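#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Rank-test kernels shared by the user-facing wrappers in R/stats.R and the
// sequential significance-onset loop.  Exact small-sample null distributions
// come from R's psignrank/pwilcox; the tie-corrected normal approximations
// follow the classical continuity-corrected forms so that results agree with
// stats::wilcox.test(correct = TRUE) on the approximate branch.

namespace {

const double EXACT_SIGNRANK_MAX = 25.0; // largest n with exact signed-rank null
const double EXACT_RANKSUM_MAX = 8.0;   // largest min(m, n) with exact U null

inline double two_sided_from_normal(double znum, double sigma) {
  // continuity correction of 0.5 applied toward the mean
  double corr = (znum > 0.0) - (znum < 0.0);
  double z = (znum - 0.5 * corr) / sigma;
  double p = 2.0 * std::min(R::pnorm(z, 0.0, 1.0, 1, 0),
                            R::pnorm(z, 0.0, 1.0, 0, 0));
  return std::min(p, 1.0);
}

// midranks of v (no NA handling; callers validate)
std::vector<double> midranks(const std::vector<double>& v) {
  const int n = v.size();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return v[a] < v[b]; });
  std::vector<double> r(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && v[idx[j + 1]] == v[idx[i]]) ++j;
    double mid = 0.5 * (i + j) + 1.0;
    for (int k = i; k <= j; ++k) r[idx[k]] = mid;
    i = j + 1;
  }
  return r;
}

// sum of (t^3 - t) over tie groups of a sorted vector
double tie_sum(std::vector<double> v) {
  std::sort(v.begin(), v.end());
  double s = 0.0;
  size_t i = 0;
  while (i < v.size()) {
    size_t j = i;
    while (j + 1 < v.size() && v[j + 1] == v[i]) ++j;
    double t = double(j - i + 1);
    s += t * t * t - t;
    i = j + 1;
  }
  return s;
}

struct TestOut {
  double stat;
  double p;
  int n_effective;
  int method; // 0 exact, 1 approximate, 2 degenerate
};

// Two-sided Wilcoxon signed-rank test on a vector of differences.
// Zero differences are dropped before ranking.
TestOut signed_rank(const double* d, int n) {
  std::vector<double> a;
  a.reserve(n);
  std::vector<bool> pos;
  pos.reserve(n);
  for (int i = 0; i < n; ++i) {
    if (d[i] != 0.0) {
      a.push_back(std::fabs(d[i]));
      pos.push_back(d[i] > 0.0);
    }
  }
  const int m = a.size();
  TestOut out;
  out.n_effective = m;
  if (m == 0) { // all differences zero
    out.stat = 0.0; out.p = 1.0; out.method = 2;
    return out;
  }
  std::vector<double> r = midranks(a);
  double W = 0.0;
  for (int i = 0; i < m; ++i)
    if (pos[i]) W += r[i];
  out.stat = W;
  double ts = tie_sum(a);
  bool ties = ts > 0.0;
  if (m <= EXACT_SIGNRANK_MAX && !ties) {
    double lo = R::psignrank(W, double(m), 1, 0);
    double hi = R::psignrank(W - 1.0, double(m), 0, 0); // P(W >= w)
    out.p = std::min(1.0, 2.0 * std::min(lo, hi));
    out.method = 0;
    return out;
  }
  double mu = m * (m + 1.0) / 4.0;
  double sigma2 = m * (m + 1.0) * (2.0 * m + 1.0) / 24.0 - ts / 48.0;
  if (sigma2 <= 0.0) { // all |d| tied AND ... cannot happen unless m tiny; guard
    out.p = 1.0; out.method = 2;
    return out;
  }
  out.p = two_sided_from_normal(W - mu, std::sqrt(sigma2));
  out.method = 1;
  return out;
}

// Two-sided Mann-Whitney U test (U counts x-over-y wins, midrank form).
TestOut rank_sum(const double* x, int m, const double* y, int n) {
  TestOut out;
  out.n_effective = m + n;
  std::vector<double> all(m + n);
  std::copy(x, x + m, all.begin());
  std::copy(y, y + n, all.begin() + m);
  std::vector<double> r = midranks(all);
  double Rx = 0.0;
  for (int i = 0; i < m; ++i) Rx += r[i];
  double U = Rx - m * (m + 1.0) / 2.0;
  out.stat = U;
  // cross-group ties void the exact null
  bool cross = false;
  {
    std::vector<double> sy(y, y + n);
    std::sort(sy.begin(), sy.end());
    for (int i = 0; i < m && !cross; ++i)
      cross = std::binary_search(sy.begin(), sy.end(), x[i]);
  }
  if (std::min(m, n) <= EXACT_RANKSUM_MAX && !cross) {
    double lo = R::pwilcox(U, double(m), double(n), 1, 0);
    double hi = R::pwilcox(U - 1.0, double(m), double(n), 0, 0);
    out.p = std::min(1.0, 2.0 * std::min(lo, hi));
    out.method = 0;
    return out;
  }
  double N = double(m + n);
  double ts = tie_sum(all);
  double sigma2 = (double(m) * n / 12.0) * ((N + 1.0) - ts / (N * (N - 1.0)));
  if (sigma2 <= 0.0) { // every pooled value identical
    out.p = 1.0; out.method = 2;
    return out;
  }
  out.p = two_sided_from_normal(U - double(m) * n / 2.0, std::sqrt(sigma2));
  out.method = 1;
  return out;
}

double cliff(const double* x, int m, const double* y, int n) {
  std::vector<double> sy(y, y + n);
  std::sort(sy.begin(), sy.end());
  double net = 0.0;
  for (int i = 0; i < m; ++i) {
    long lo = std::lower_bound(sy.begin(), sy.end(), x[i]) - sy.begin();
    long gt = sy.end() - std::upper_bound(sy.begin(), sy.end(), x[i]);
    net += double(lo) - double(gt);
  }
  return net / (double(m) * double(n));
}

CharacterVector method_label(int code) {
  switch (code) {
  case 0: return CharacterVector::create("exact");
  case 1: return CharacterVector::create("approximate");
  default: return CharacterVector::create("degenerate");
  }
}

} // namespace

// [[Rcpp::export]]
double cpp_cliffs_delta(NumericVector x, NumericVector y) {
  return cliff(REAL(x), x.size(), REAL(y), y.size());
}

// [[Rcpp::export]]
List cpp_signed_rank(NumericVector d) {
  TestOut t = signed_rank(REAL(d), d.size());
  return List::create(_["statistic"] = t.stat, _["p_two_sided"] = t.p,
                      _["n_effective"] = t.n_effective,
                      _["method"] = method_label(t.method));
}

// [[Rcpp::export]]
List cpp_rank_sum(NumericVector x, NumericVector y) {
  TestOut t = rank_sum(REAL(x), x.size(), REAL(y), y.size());
  return List::create(_["statistic"] = t.stat, _["p_two_sided"] = t.p,
                      _["n_effective"] = t.n_effective,
                      _["method"] = method_label(t.method));
}

// [[Rcpp::export]]
double cpp_signed_rank_p(NumericVector d) {
  return signed_rank(REAL(d), d.size()).p;
}

// [[Rcpp::export]]
double cpp_rank_sum_p(NumericVector x, NumericVector y) {
  return rank_sum(REAL(x), x.size(), REAL(y), y.size()).p;
}

// Sequential significance onset: test the first k pairs for every
// k = 1..n, return the smallest k with p < alpha together with Cliff's
// delta (weekend vs weekday) over those k pairs.  Degenerate prefixes
// (all ties, all zero differences) count as non-significant.
// [[Rcpp::export]]
List cpp_find_onset(NumericVector weekend, NumericVector weekday,
                    bool paired, double alpha) {
  const int n = weekend.size();
  std::vector<double> d;
  if (paired) {
    d.resize(n);
    for (int i = 0; i < n; ++i) d[i] = weekend[i] - weekday[i];
  }
  for (int k = 1; k <= n; ++k) {
    double p = paired
      ? signed_rank(d.data(), k).p
      : rank_sum(REAL(weekend), k, REAL(weekday), k).p;
    if (p < alpha) {
      double delta = cliff(REAL(weekend), k, REAL(weekday), k);
      return List::create(_["n_pairs_at_onset"] = k, _["p_at_onset"] = p,
                          _["delta_at_onset"] = delta,
                          _["censored"] = false, _["n_available"] = n);
    }
  }
  return List::create(_["n_pairs_at_onset"] = NA_INTEGER,
                      _["p_at_onset"] = NA_REAL,
                      _["delta_at_onset"] = NA_REAL,
                      _["censored"] = true, _["n_available"] = n);
}
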