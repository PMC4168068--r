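#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap penalty, computed in
// linear space by divide and conquer so that whole phage genomes (tens of kb)
// align within ordinary memory. Only the column statistics of one optimal
// alignment are kept: identical columns, mismatch columns, gap columns.
// Tie-breaks: diagonal, then up (gap in b), then left (gap in a); the
// divide-and-conquer split takes the smallest crossing column on ties, so the
// result is deterministic.

struct AlnStats {
  long long n_identical = 0;
  long long n_mismatch = 0;
  long long n_gap = 0;
};

static inline int subst(char x, char y, int match, int mismatch) {
  return x == y ? match : mismatch;
}

// Last row of NW scores for a[0..m) vs all prefixes of b (forward) in O(n) space.
static void nw_score_row(const char* a, int m, const char* b, int n,
                         int match, int mismatch, int gap,
                         std::vector<int>& out) {
  std::vector<int>& prev = out;
  prev.resize(n + 1);
  std::vector<int> cur(n + 1);
  for (int j = 0; j <= n; ++j) prev[j] = gap * j;
  for (int i = 1; i <= m; ++i) {
    cur[0] = gap * i;
    for (int j = 1; j <= n; ++j) {
      int diag = prev[j - 1] + subst(a[i - 1], b[j - 1], match, mismatch);
      int up = prev[j] + gap;
      int left = cur[j - 1] + gap;
      cur[j] = std::max(diag, std::max(up, left));
    }
    std::swap(prev, cur);
  }
}

// Full-matrix NW with traceback; used for small subproblems.
static void nw_full(const char* a, int m, const char* b, int n,
                    int match, int mismatch, int gap, AlnStats& st) {
  std::vector<int> S((size_t)(m + 1) * (n + 1));
  auto at = [&](int i, int j) -> int& { return S[(size_t)i * (n + 1) + j]; };
  for (int j = 0; j <= n; ++j) at(0, j) = gap * j;
  for (int i = 1; i <= m; ++i) {
    at(i, 0) = gap * i;
    for (int j = 1; j <= n; ++j) {
      int diag = at(i - 1, j - 1) + subst(a[i - 1], b[j - 1], match, mismatch);
      int up = at(i - 1, j) + gap;
      int left = at(i, j - 1) + gap;
      at(i, j) = std::max(diag, std::max(up, left));
    }
  }
  int i = m, j = n;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        at(i, j) == at(i - 1, j - 1) + subst(a[i - 1], b[j - 1], match, mismatch)) {
      if (a[i - 1] == b[j - 1]) st.n_identical++; else st.n_mismatch++;
      --i; --j;
    } else if (i > 0 && at(i, j) == at(i - 1, j) + gap) {
      st.n_gap++; --i;
    } else {
      st.n_gap++; --j;
    }
  }
}

static void hirschberg(const char* a, int m, const char* b, int n,
                       int match, int mismatch, int gap, AlnStats& st) {
  if (m == 0) { st.n_gap += n; return; }
  if (n == 0) { st.n_gap += m; return; }
  if ((long long)m * n <= 1000000LL || m <= 2 || n <= 2) {
    nw_full(a, m, b, n, match, mismatch, gap, st);
    return;
  }
  int i_mid = m / 2;
  std::vector<int> fwd, rev;
  nw_score_row(a, i_mid, b, n, match, mismatch, gap, fwd);
  // reversed halves for the suffix scores
  std::string ar(a + i_mid, a + m), br(b, b + n);
  std::reverse(ar.begin(), ar.end());
  std::reverse(br.begin(), br.end());
  nw_score_row(ar.data(), m - i_mid, br.data(), n, match, mismatch, gap, rev);
  int j_best = 0;
  long best = (long)fwd[0] + rev[n];
  for (int j = 1; j <= n; ++j) {
    long v = (long)fwd[j] + rev[n - j];
    if (v > best) { best = v; j_best = j; }
  }
  hirschberg(a, i_mid, b, j_best, match, mismatch, gap, st);
  hirschberg(a + i_mid, m - i_mid, b + j_best, n - j_best, match, mismatch, gap, st);
}

// [[Rcpp::export(name = ".nw_align_stats")]]
List nw_align_stats(std::string a, std::string b,
                    int match = 1, int mismatch = -1, int gap = -2) {
  AlnStats st;
  hirschberg(a.data(), (int)a.size(), b.data(), (int)b.size(),
             match, mismatch, gap, st);
  long long score = st.n_identical * match + st.n_mismatch * mismatch +
                    st.n_gap * gap;
  long long len = st.n_identical + st.n_mismatch + st.n_gap;
  return List::create(_["score"] = (double)score,
                      _["aln_length"] = (double)len,
                      _["n_identical"] = (double)st.n_identical,
                      _["n_mismatch"] = (double)st.n_mismatch,
                      _["n_gap"] = (double)st.n_gap);
}
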