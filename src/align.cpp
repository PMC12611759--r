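#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Levenshtein distance between two strings (unit costs, two-row DP).
// [[Rcpp::export]]
int edit_distance_cpp(const std::string& a, const std::string& b) {
  const int m = a.size(), n = b.size();
  std::vector<int> prev(n + 1), cur(n + 1);
  for (int j = 0; j <= n; ++j) prev[j] = j;
  for (int i = 1; i <= m; ++i) {
    cur[0] = i;
    const char ai = a[i - 1];
    for (int j = 1; j <= n; ++j) {
      int sub = prev[j - 1] + (ai == b[j - 1] ? 0 : 1);
      cur[j] = std::min(sub, std::min(prev[j] + 1, cur[j - 1] + 1));
    }
    std::swap(prev, cur);
  }
  return prev[n];
}

// Anchored semi-global match: align the whole pattern starting at position 1
// of the subject, with a free end inside the subject (edit distance over
// substitutions + indels). Returns c(distance, end), where `end` is the
// 1-based subject position where the best alignment of the full pattern
// stops (0 when the pattern aligns to the empty prefix). Used for
// prefix-anchored primer/anchor matching; apply to reversed strings for
// suffix-anchored matching.
// [[Rcpp::export]]
IntegerVector prefix_match_cpp(const std::string& pattern,
                               const std::string& subject) {
  const int m = pattern.size(), n = subject.size();
  std::vector<int> prev(n + 1), cur(n + 1);
  for (int j = 0; j <= n; ++j) prev[j] = j;
  for (int i = 1; i <= m; ++i) {
    cur[0] = i;
    const char pi = pattern[i - 1];
    for (int j = 1; j <= n; ++j) {
      int sub = prev[j - 1] + (pi == subject[j - 1] ? 0 : 1);
      cur[j] = std::min(sub, std::min(prev[j] + 1, cur[j - 1] + 1));
    }
    std::swap(prev, cur);
  }
  int best = prev[0], end = 0;
  for (int j = 1; j <= n; ++j) {
    if (prev[j] < best) { best = prev[j]; end = j; }
  }
  return IntegerVector::create(best, end);
}

// Banded Levenshtein distance: cells with |i - j| > band are treated as
// unreachable. Returns the exact distance whenever the optimal path stays
// inside the band (band >= |len(a) - len(b)| is required for any path),
// otherwise an upper bound capped at max(len(a), len(b)).
// [[Rcpp::export]]
int edit_distance_banded_cpp(const std::string& a, const std::string& b,
                             int band) {
  const int m = a.size(), n = b.size();
  const int cap = std::max(m, n);
  if (std::abs(m - n) > band) return cap;
  const int INF = 1 << 29;
  std::vector<int> prev(n + 1, INF), cur(n + 1, INF);
  for (int j = 0; j <= std::min(n, band); ++j) prev[j] = j;
  for (int i = 1; i <= m; ++i) {
    int lo = std::max(1, i - band), hi = std::min(n, i + band);
    std::fill(cur.begin() + lo - 1, cur.begin() + hi + 1, INF);
    if (lo == 1) cur[0] = i;
    const char ai = a[i - 1];
    for (int j = lo; j <= hi; ++j) {
      int best = prev[j - 1] == INF ? INF
                 : prev[j - 1] + (ai == b[j - 1] ? 0 : 1);
      if (prev[j] != INF) best = std::min(best, prev[j] + 1);
      if (cur[j - 1] != INF) best = std::min(best, cur[j - 1] + 1);
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[n] >= INF ? cap : std::min(prev[n], cap);
}

// Leftmost start positions (1-based) where pattern matches subject as a
// contiguous block with at most max_mm mismatches (Hamming, no indels).
// [[Rcpp::export]]
IntegerVector hamming_scan_cpp(const std::string& pattern,
                               const std::string& subject,
                               int max_mm) {
  const int m = pattern.size(), n = subject.size();
  std::vector<int> hits;
  for (int s = 0; s + m <= n; ++s) {
    int mm = 0;
    for (int i = 0; i < m && mm <= max_mm; ++i)
      if (pattern[i] != subject[s + i]) ++mm;
    if (mm <= max_mm) hits.push_back(s + 1);
  }
  return wrap(hits);
}
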