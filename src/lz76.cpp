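#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Lempel-Ziv 1976 exhaustive-history phrase count.
//
// Each phrase is the shortest continuation not reproducible by copying from
// the text already seen (copy sources may start before the phrase and
// overlap it); the trailing word counts even when still reproducible.  The
// phrase starting at p therefore has length LPF[p] + 1, where LPF is the
// longest-previous-factor array: LPF[p] = max over q < p of
// lcp(s[q..], s[p..]).  LPF is computed from a suffix array (rank doubling,
// O(n log^2 n)), the Kasai LCP array, and the linked-list sweep that removes
// text positions in decreasing order so each position's nearest suffix-array
// neighbours among smaller positions yield its LPF.

static std::vector<int> suffix_array(const std::vector<int>& s) {
  const int n = s.size();
  std::vector<int> sa(n), rank_(n), tmp(n);
  for (int i = 0; i < n; ++i) { sa[i] = i; rank_[i] = s[i]; }
  for (int k = 1;; k <<= 1) {
    auto cmp = [&](int a, int b) {
      if (rank_[a] != rank_[b]) return rank_[a] < rank_[b];
      int ra = a + k < n ? rank_[a + k] : -1;
      int rb = b + k < n ? rank_[b + k] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    rank_ = tmp;
    if (rank_[sa[n - 1]] == n - 1) break;
  }
  return sa;
}

// Kasai et al.: lcp[r] = lcp(suffix sa[r-1], suffix sa[r]), lcp[0] = 0
static std::vector<int> kasai_lcp(const std::vector<int>& s,
                                  const std::vector<int>& sa) {
  const int n = s.size();
  std::vector<int> rank_(n), lcp(n, 0);
  for (int r = 0; r < n; ++r) rank_[sa[r]] = r;
  int h = 0;
  for (int p = 0; p < n; ++p) {
    if (rank_[p] > 0) {
      int q = sa[rank_[p] - 1];
      while (p + h < n && q + h < n && s[p + h] == s[q + h]) ++h;
      lcp[rank_[p]] = h;
      if (h > 0) --h;
    } else h = 0;
  }
  return lcp;
}

// [[Rcpp::export]]
int lz76_count(const IntegerVector& seq) {
  const int n = seq.size();
  if (n == 0) stop("empty sequence");
  if (n == 1) return 1;
  std::vector<int> s(seq.begin(), seq.end());
  std::vector<int> sa = suffix_array(s);
  std::vector<int> lcp = kasai_lcp(s, sa);
  // doubly linked list over suffix-array ranks; L[r] = lcp to predecessor
  std::vector<int> prev(n + 1), next(n + 1), rank_(n), L(n + 1, 0);
  for (int r = 0; r < n; ++r) rank_[sa[r]] = r;
  for (int r = 0; r <= n; ++r) { prev[r] = r - 1; next[r] = r + 1; }
  for (int r = 0; r < n; ++r) L[r] = (r == 0) ? 0 : lcp[r];
  L[n] = 0;                                   // sentinel tail
  std::vector<int> lpf(n, 0);
  for (int p = n - 1; p >= 0; --p) {          // remove largest position first
    int r = rank_[p];
    int nr = next[r];
    int lneigh = L[r];                        // lcp with remaining predecessor
    int rneigh = (nr <= n - 1) ? L[nr] : 0;   // lcp with remaining successor
    lpf[p] = std::max(lneigh, rneigh);
    if (nr <= n - 1) L[nr] = std::min(lneigh, L[nr]);
    if (prev[r] >= 0) next[prev[r]] = nr;
    if (nr <= n) prev[nr] = prev[r];
  }
  int c = 0;
  int pos = 0;
  while (pos < n) {
    ++c;
    pos += lpf[pos] + 1;                      // trailing truncation implicit
  }
  return c;
}
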