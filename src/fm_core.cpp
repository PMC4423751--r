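#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Base coding used throughout: A=0, C=1, G=2, T=3, N=4, sentinel=5.
// Alphabet order for suffix sorting / C array: $ < A < C < G < T < N.

// ---------------------------------------------------------------------------
// Suffix array over text + sentinel, by prefix doubling.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector sa_build_cpp(IntegerVector text) {
  const int L = text.size();
  const int n = L + 1;            // with sentinel
  std::vector<int> sa(n), rnk(n), tmp(n);
  for (int i = 0; i < L; ++i) rnk[i] = text[i] + 1;   // sentinel rank 0
  rnk[L] = 0;
  for (int i = 0; i < n; ++i) sa[i] = i;
  for (int k = 1;; k <<= 1) {
    auto cmp = [&](int a, int b) {
      if (rnk[a] != rnk[b]) return rnk[a] < rnk[b];
      int ra = a + k < n ? rnk[a + k] : -1;
      int rb = b + k < n ? rnk[b + k] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    rnk = tmp;
    if (rnk[sa[n - 1]] == n - 1) break;
  }
  return IntegerVector(sa.begin(), sa.end());
}

// [[Rcpp::export]]
IntegerVector bwt_from_sa_cpp(IntegerVector text, IntegerVector sa) {
  const int n = sa.size();
  IntegerVector bwt(n);
  for (int r = 0; r < n; ++r)
    bwt[r] = sa[r] == 0 ? 5 : text[sa[r] - 1];
  return bwt;
}

// Occurrence checkpoints: 6 x (nchk) matrix, column q holds counts over
// bwt[0 .. q*occ_rate).
// [[Rcpp::export]]
IntegerMatrix occ_build_cpp(IntegerVector bwt, int occ_rate) {
  const int n = bwt.size();
  const int nchk = n / occ_rate + 1;
  IntegerMatrix cp(6, nchk);
  std::vector<int> run(6, 0);
  int q = 0;
  for (int i = 0; i <= n; ++i) {
    if (i % occ_rate == 0) {
      for (int c = 0; c < 6; ++c) cp(c, q) = run[c];
      ++q;
    }
    if (i < n) run[bwt[i]]++;
  }
  return cp;
}

static inline int occ_at(const int* bwt, const int* cp, int occ_rate,
                         int nchk_rows_unused, int c, int i) {
  int q = i / occ_rate;
  int cnt = cp[q * 6 + c];
  for (int k = q * occ_rate; k < i; ++k)
    if (bwt[k] == c) ++cnt;
  return cnt;
}

struct FMView {
  const int* bwt;
  const int* cp;       // 6 x nchk column-major
  const int* cnt;      // C array length 6: chars < c (order $,A,C,G,T,N)
  int n;
  int occ_rate;
  int occ(int c, int i) const { return occ_at(bwt, cp, occ_rate, 0, c, i); }
  // backward extend [low,high) with base c in 0..4
  void extend(int c, int low, int high, int& nlow, int& nhigh) const {
    nlow = cnt[c + 1] + occ(c, low);   // cnt indexed by coded char+1: see below
    nhigh = cnt[c + 1] + occ(c, high);
  }
};

// The R-side C array `cnt` has length 6 ordered ($,A,C,G,T,N): cnt[k] = number
// of bwt characters with sort order < k.  Coded base c in 0..4 sorts at k=c+1.

static FMView make_view(IntegerVector bwt, IntegerMatrix cp, IntegerVector cnt,
                        int occ_rate) {
  FMView v;
  v.bwt = INTEGER(bwt);
  v.cp = INTEGER(cp);
  v.cnt = INTEGER(cnt);
  v.n = bwt.size();
  v.occ_rate = occ_rate;
  return v;
}

// [[Rcpp::export]]
IntegerVector backward_extend_cpp(IntegerVector bwt, IntegerMatrix cp,
                                  IntegerVector cnt, int occ_rate,
                                  int low, int high, int base) {
  FMView v = make_view(bwt, cp, cnt, occ_rate);
  int nl, nh;
  v.extend(base, low, high, nl, nh);
  return IntegerVector::create(nl, nh);
}

// [[Rcpp::export]]
IntegerVector occ_count_cpp(IntegerVector bwt, IntegerMatrix cp, int occ_rate,
                            int base, IntegerVector at) {
  // occurrence counts of `base` in bwt[0..at) for each position in `at`
  IntegerVector out(at.size());
  for (int k = 0; k < at.size(); ++k)
    out[k] = occ_at(INTEGER(bwt), INTEGER(cp), occ_rate, 0, base, at[k]);
  return out;
}

// LF-walk locate of every row in [low, high).
// [[Rcpp::export]]
IntegerVector locate_cpp(IntegerVector bwt, IntegerMatrix cp, IntegerVector cnt,
                         int occ_rate, IntegerVector sa_samples, int sa_rate,
                         int low, int high) {
  FMView v = make_view(bwt, cp, cnt, occ_rate);
  const int n = v.n;
  IntegerVector out(high - low);
  for (int r0 = low; r0 < high; ++r0) {
    int r = r0, t = 0;
    while (r % sa_rate != 0) {
      int c = v.bwt[r];               // 0..5
      if (c == 5) { r = 0; }          // row of '$': SA[r]=... LF maps to row 0
      else r = v.cnt[c + 1] + v.occ(c, r);
      ++t;
    }
    out[r0 - low] = (sa_samples[r / sa_rate] + t) % n;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Seed search with 1 branching + up to k non-branching mismatches.
// Backward (right-to-left) DFS over the FM-index.  At each step the intervals
// of all four bases are computed; the read base, if it extends, continues at
// no cost.  A mismatching base that extends costs one branching mismatch (BM)
// when >= 2 bases extend, and one non-branching mismatch (NBM) when the read
// base fails and it is the single extending base (forced correction).
// ---------------------------------------------------------------------------

struct SeedHitRec { int low, high, n_bm, n_nbm; };

static void seed_dfs(const FMView& v, const int* seed, int pos,
                     int low, int high, int n_bm, int n_nbm,
                     int max_bm, int max_nbm, std::vector<SeedHitRec>& out) {
  if (pos < 0) {
    out.push_back({low, high, n_bm, n_nbm});
    return;
  }
  int lo[4], hi[4], k = 0;
  for (int c = 0; c < 4; ++c) {
    v.extend(c, low, high, lo[c], hi[c]);
    if (hi[c] > lo[c]) ++k;
  }
  const int rc = seed[pos];
  const bool read_ok = rc < 4 && hi[rc] > lo[rc];
  if (read_ok) {
    seed_dfs(v, seed, pos - 1, lo[rc], hi[rc], n_bm, n_nbm,
             max_bm, max_nbm, out);
    if (k >= 2 && n_bm < max_bm)
      for (int c = 0; c < 4; ++c)
        if (c != rc && hi[c] > lo[c])
          seed_dfs(v, seed, pos - 1, lo[c], hi[c], n_bm + 1, n_nbm,
                   max_bm, max_nbm, out);
  } else if (k == 1) {
    if (n_nbm < max_nbm)
      for (int c = 0; c < 4; ++c)
        if (hi[c] > lo[c])
          seed_dfs(v, seed, pos - 1, lo[c], hi[c], n_bm, n_nbm + 1,
                   max_bm, max_nbm, out);
  } else if (k >= 2) {
    if (n_bm < max_bm)
      for (int c = 0; c < 4; ++c)
        if (hi[c] > lo[c])
          seed_dfs(v, seed, pos - 1, lo[c], hi[c], n_bm + 1, n_nbm,
                   max_bm, max_nbm, out);
  }
}

// [[Rcpp::export]]
IntegerMatrix seed_search_cpp(IntegerVector bwt, IntegerMatrix cp,
                              IntegerVector cnt, int occ_rate,
                              IntegerVector seed, int max_bm, int max_nbm) {
  FMView v = make_view(bwt, cp, cnt, occ_rate);
  std::vector<SeedHitRec> hits;
  seed_dfs(v, INTEGER(seed), seed.size() - 1, 0, v.n, 0, 0,
           max_bm, max_nbm, hits);
  IntegerMatrix out(hits.size(), 4);
  for (size_t i = 0; i < hits.size(); ++i) {
    out(i, 0) = hits[i].low;
    out(i, 1) = hits[i].high;
    out(i, 2) = hits[i].n_bm;
    out(i, 3) = hits[i].n_nbm;
  }
  colnames(out) = CharacterVector::create("low", "high", "n_bm", "n_nbm");
  return out;
}
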