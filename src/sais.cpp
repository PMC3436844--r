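#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// SA-IS (induced sorting) suffix array construction.
// Works on an integer string s of length n whose last symbol is the unique
// minimum (0). Recursion depth is O(log n); each level halves the problem.

static void get_buckets(const std::vector<int>& s, std::vector<int>& bkt,
                        int K, bool ends) {
  std::fill(bkt.begin(), bkt.end(), 0);
  for (size_t i = 0; i < s.size(); ++i) bkt[s[i]]++;
  int sum = 0;
  for (int c = 0; c <= K; ++c) {
    sum += bkt[c];
    bkt[c] = ends ? sum : sum - bkt[c];
  }
}

// Induce L-type then S-type suffixes from the currently placed entries.
static void induce(const std::vector<int>& s, std::vector<int>& SA,
                   const std::vector<char>& t, int K) {
  int n = (int)s.size();
  std::vector<int> bkt(K + 1);
  get_buckets(s, bkt, K, false);
  for (int i = 0; i < n; ++i) {
    int j = SA[i] - 1;
    if (SA[i] > 0 && !t[j]) SA[bkt[s[j]]++] = j;
  }
  get_buckets(s, bkt, K, true);
  for (int i = n - 1; i >= 0; --i) {
    int j = SA[i] - 1;
    if (SA[i] > 0 && t[j]) SA[--bkt[s[j]]] = j;
  }
}

static void sais_rec(const std::vector<int>& s, std::vector<int>& SA, int K) {
  int n = (int)s.size();
  if (n == 1) { SA[0] = 0; return; }
  // classify suffixes: t[i] = 1 iff suffix i is S-type
  std::vector<char> t(n);
  t[n - 1] = 1;
  for (int i = n - 2; i >= 0; --i)
    t[i] = (s[i] < s[i + 1] || (s[i] == s[i + 1] && t[i + 1])) ? 1 : 0;
  std::vector<char> lms(n, 0);
  for (int i = 1; i < n; ++i) lms[i] = (t[i] && !t[i - 1]) ? 1 : 0;

  // stage 1: approximately sort LMS suffixes by induced sorting
  std::vector<int> bkt(K + 1);
  std::fill(SA.begin(), SA.end(), -1);
  get_buckets(s, bkt, K, true);
  for (int i = 1; i < n; ++i)
    if (lms[i]) SA[--bkt[s[i]]] = i;
  induce(s, SA, t, K);

  // collect LMS positions in sorted LMS-substring order and name them
  std::vector<int> lms_sorted;
  lms_sorted.reserve(n / 2 + 1);
  for (int i = 0; i < n; ++i)
    if (SA[i] > 0 && lms[SA[i]]) lms_sorted.push_back(SA[i]);
  int n1 = (int)lms_sorted.size();
  std::vector<int> name(n, -1);
  int cur = -1, prev = -1;
  for (int idx = 0; idx < n1; ++idx) {
    int pos = lms_sorted[idx];
    bool diff = (prev < 0);
    if (!diff) {
      for (int d = 0;; ++d) {
        if (s[pos + d] != s[prev + d] || t[pos + d] != t[prev + d]) {
          diff = true; break;
        }
        if (d > 0 && (lms[pos + d] || lms[prev + d])) {
          if (!(lms[pos + d] && lms[prev + d])) diff = true;
          break;
        }
      }
    }
    if (diff) { ++cur; prev = pos; }
    name[pos] = cur;
  }

  // reduced string over LMS names, in text order
  std::vector<int> p1, s1;
  p1.reserve(n1); s1.reserve(n1);
  for (int i = 1; i < n; ++i)
    if (lms[i]) { p1.push_back(i); s1.push_back(name[i]); }

  std::vector<int> SA1(n1);
  if (cur + 1 < n1) {
    sais_rec(s1, SA1, cur);
  } else {
    for (int i = 0; i < n1; ++i) SA1[s1[i]] = i;
  }

  // stage 2: place LMS suffixes in their true order and induce the rest
  std::fill(SA.begin(), SA.end(), -1);
  get_buckets(s, bkt, K, true);
  for (int i = n1 - 1; i >= 0; --i) {
    int j = p1[SA1[i]];
    SA[--bkt[s[j]]] = j;
  }
  induce(s, SA, t, K);
}

//' @noRd
// [[Rcpp::export(name = ".sais_sa")]]
IntegerVector sais_sa(RawVector txt) {
  int n = txt.size();
  if (n == 0) stop("empty text");
  // append a virtual terminator smaller than every byte so the shorter-suffix-
  // is-smaller (prefix) convention holds and SA-IS preconditions are met
  std::vector<int> s(n + 1);
  for (int i = 0; i < n; ++i) s[i] = (int)txt[i];
  s[n] = 0;
  std::vector<int> SA(n + 1);
  sais_rec(s, SA, 255);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = SA[i + 1];  // drop the terminator
  return out;
}

// lexicographic compare of database suffix txt[p..] vs query suffix q[s..];
// a suffix that is a proper prefix of the other compares smaller
static bool db_suffix_leq(const Rbyte* t, int n, int p,
                          const Rbyte* q, int m, int s) {
  while (p < n && s < m) {
    if (t[p] != q[s]) return t[p] < q[s];
    ++p; ++s;
  }
  return p >= n;
}

//' @noRd
// [[Rcpp::export(name = ".merge_map")]]
IntegerVector merge_map(RawVector txt, IntegerVector sa,
                        RawVector qtxt, IntegerVector qsa) {
  int n = sa.size(), m = qsa.size();
  const Rbyte* t = RAW(txt);
  const Rbyte* q = RAW(qtxt);
  IntegerVector out(m);
  int i = 0;  // number of database suffixes known to be <= current query suffix
  for (int j = 0; j < m; ++j) {
    int s = qsa[j];
    while (i < n && db_suffix_leq(t, txt.size(), sa[i], q, qtxt.size(), s)) ++i;
    out[s] = i - 1;  // element s holds the rank for query offset s; -1 if none
  }
  return out;
}
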