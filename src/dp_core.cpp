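#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Affine-gap alignment, local over the read (free soft clips at both read
// ends) with free reference flanks.  Three score states per cell:
//   M[i,j] = s(i,j) + max(0, M[i-1,j-1], I[i-1,j-1], D[i-1,j-1])
//   I[i,j] = max(M[i-1,j] - open - ext, I[i-1,j] - ext)   (consumes read)
//   D[i,j] = max(M[i,j-1] - open - ext, D[i,j-1] - ext)   (consumes window)
// No direct I<->D transition.  The first gap base costs open + ext.
// Best alignment ends in state M; score <= 0 means unaligned.
//
// The table is stored in anti-diagonal order as a single array: diagonal
// d = i+j, cells within a diagonal ordered by increasing j (decreasing i).
// Every cell on a diagonal depends only on the two previous diagonals, so a
// whole diagonal is filled as a sequence of batched lane computations of up
// to lane_width cells each.
//
// Cell packing: M, I, D live in one 64-bit word as three 17-bit biased
// fields (bias 65536); the word is < 2^51 so it travels exactly in an R
// double.  Scores saturate at +/-65535 (flagged, never silent wraparound).

static const int BIAS = 65536;           // 1 << 16
static const int FMAX = 131071;          // (1 << 17) - 1
static const int SCORE_MIN = -65535;
static const int SCORE_MAX = 65535;
static const int NEG = -65536;           // internal -inf floor (field 0)

static inline double pack3(int m, int i, int d, bool* sat) {
  int fm = m + BIAS, fi = i + BIAS, fd = d + BIAS;
  if (fm < 0 || fm > FMAX || fi < 0 || fi > FMAX || fd < 0 || fd > FMAX) {
    if (sat) *sat = true;
    fm = std::min(std::max(fm, 0), FMAX);
    fi = std::min(std::max(fi, 0), FMAX);
    fd = std::min(std::max(fd, 0), FMAX);
  }
  uint64_t w = (uint64_t)fm | ((uint64_t)fi << 17) | ((uint64_t)fd << 34);
  return (double)w;
}

static inline void unpack3(double x, int* m, int* i, int* d) {
  uint64_t w = (uint64_t)x;
  *m = (int)(w & FMAX) - BIAS;
  *i = (int)((w >> 17) & FMAX) - BIAS;
  *d = (int)((w >> 34) & FMAX) - BIAS;
}

// [[Rcpp::export]]
NumericVector cell_pack_cpp(IntegerVector m, IntegerVector i, IntegerVector d) {
  int n = m.size();
  NumericVector out(n);
  bool sat = false;
  for (int k = 0; k < n; ++k) out[k] = pack3(m[k], i[k], d[k], &sat);
  out.attr("saturated") = sat;
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cell_unpack_cpp(NumericVector x) {
  int n = x.size();
  IntegerMatrix out(n, 3);
  for (int k = 0; k < n; ++k) {
    int m, i, d;
    unpack3(x[k], &m, &i, &d);
    out(k, 0) = m; out(k, 1) = i; out(k, 2) = d;
  }
  colnames(out) = CharacterVector::create("m", "i", "d");
  return out;
}

// flat offset of cell (i,j), 1-based i in 1..m (read), j in 1..n (window):
// diagonals d = 2..(m+n); within d, j runs jmin(d)=max(1,d-m)..jmax(d)=min(n,d-1)
struct DiagMap {
  int m, n;
  std::vector<int> off;   // off[d] = flat index of first cell of diagonal d
  DiagMap(int m_, int n_) : m(m_), n(n_), off(m_ + n_ + 1, 0) {
    int acc = 0;
    for (int d = 2; d <= m + n; ++d) {
      off[d] = acc;
      int jmin = std::max(1, d - m), jmax = std::min(n, d - 1);
      acc += jmax - jmin + 1;
    }
  }
  inline int flat(int i, int j) const {
    int d = i + j;
    return off[d] + (j - std::max(1, d - m));
  }
};

// [[Rcpp::export]]
int diag_flat_cpp(int i, int j, int m, int n) {
  DiagMap dm(m, n);
  return dm.flat(i, j);   // 0-based flat offset
}

static inline int subscore(int r, int w, int match, int mismatch) {
  return (r < 4 && w < 4 && r == w) ? match : -mismatch;
}

// [[Rcpp::export]]
List dp_fill_cpp(IntegerVector read, IntegerVector window,
                 int match, int mismatch, int gap_open, int gap_extend,
                 int lane_width) {
  const int m = read.size(), n = window.size();
  DiagMap dm(m, n);
  std::vector<double> cells((size_t)m * n);
  bool sat = false;
  const int go = gap_open + gap_extend;   // first gap base
  int best = 0, best_i = 0, best_j = 0;

  // lane buffers
  std::vector<int> Mv(lane_width), Iv(lane_width), Dv(lane_width);

  for (int d = 2; d <= m + n; ++d) {
    const int jmin = std::max(1, d - m), jmax = std::min(n, d - 1);
    for (int j0 = jmin; j0 <= jmax; j0 += lane_width) {
      const int lanes = std::min(lane_width, jmax - j0 + 1);
      // batched lane computation: gather, compute, scatter
      for (int l = 0; l < lanes; ++l) {
        const int j = j0 + l, i = d - j;
        int Mdg = NEG, Idg = NEG, Ddg = NEG;   // (i-1, j-1)
        int Mup = NEG, Iup = NEG;              // (i-1, j)
        int Mlf = NEG, Dlf = NEG;              // (i, j-1)
        if (i > 1 && j > 1) unpack3(cells[dm.flat(i - 1, j - 1)], &Mdg, &Idg, &Ddg);
        if (i > 1) { int t; unpack3(cells[dm.flat(i - 1, j)], &Mup, &Iup, &t); }
        if (j > 1) { int u; unpack3(cells[dm.flat(i, j - 1)], &Mlf, &u, &Dlf); }
        int open_best = std::max(0, std::max(Mdg, std::max(Idg, Ddg)));
        int Mij = subscore(read[i - 1], window[j - 1], match, mismatch) + open_best;
        int Iij = std::max(Mup - go, Iup - gap_extend);
        int Dij = std::max(Mlf - go, Dlf - gap_extend);
        Mv[l] = std::max(Mij, NEG);
        Iv[l] = std::max(Iij, NEG);
        Dv[l] = std::max(Dij, NEG);
      }
      for (int l = 0; l < lanes; ++l) {
        const int j = j0 + l, i = d - j;
        cells[dm.flat(i, j)] = pack3(Mv[l], Iv[l], Dv[l], &sat);
        // tie preference: more of the read aligned, then leftmost in window
        if (Mv[l] > best || (Mv[l] == best && best > 0 &&
                             (i > best_i || (i == best_i && j < best_j)))) {
          best = Mv[l]; best_i = i; best_j = j;
        }
      }
    }
  }
  return List::create(_["cells"] = NumericVector(cells.begin(), cells.end()),
                      _["m"] = m, _["n"] = n,
                      _["best_score"] = best,
                      _["best_i"] = best_i, _["best_j"] = best_j,
                      _["saturated"] = sat);
}

// Traceback from the best cell.  Tie preference: M over D over I; extension
// preferred over a zero (local start) of equal score.
// Returns ops as integers: 0=M, 1=I, 2=D (read-local S clips added in R).
// [[Rcpp::export]]
List dp_traceback_cpp(NumericVector cells, int m, int n,
                      IntegerVector read, IntegerVector window,
                      int match, int mismatch, int gap_open, int gap_extend,
                      int best_i, int best_j) {
  DiagMap dm(m, n);
  const int go = gap_open + gap_extend;
  std::vector<int> ops;                 // reversed
  int i = best_i, j = best_j, state = 0;   // 0=M,1=I,2=D
  int n_mismatch = 0, n_indel = 0;
  auto get = [&](int ii, int jj, int* M, int* I, int* D) {
    if (ii < 1 || jj < 1) { *M = *I = *D = NEG; return; }
    unpack3(cells[dm.flat(ii, jj)], M, I, D);
  };
  for (;;) {
    if (state == 0) {
      ops.push_back(0);
      int s = subscore(read[i - 1], window[j - 1], match, mismatch);
      if (s < 0) ++n_mismatch;
      int Mij, Iij, Dij, Md, Id, Dd;
      unpack3(cells[dm.flat(i, j)], &Mij, &Iij, &Dij);
      int target = Mij - s;
      get(i - 1, j - 1, &Md, &Id, &Dd);
      if (Md == target)      { --i; --j; state = 0; }
      else if (Dd == target) { --i; --j; state = 2; }
      else if (Id == target) { --i; --j; state = 1; }
      else break;            // target == 0: local start here
      if (i < 1 || j < 1) break;
    } else if (state == 2) {  // D consumes window char at column j
      ops.push_back(2);
      ++n_indel;
      int Mij, Iij, Dij, Ml, Il, Dl;
      unpack3(cells[dm.flat(i, j)], &Mij, &Iij, &Dij);
      get(i, j - 1, &Ml, &Il, &Dl);
      if (Ml - go == Dij) { --j; state = 0; }
      else               { --j; state = 2; }
    } else {                  // I consumes read char at row i
      ops.push_back(1);
      ++n_indel;
      int Mij, Iij, Dij, Mu, Iu, Du;
      unpack3(cells[dm.flat(i, j)], &Mij, &Iij, &Dij);
      get(i - 1, j, &Mu, &Iu, &Du);
      if (Mu - go == Iij) { --i; state = 0; }
      else                { --i; state = 1; }
    }
  }
  // after loop: (i, j) is the first aligned cell (state M emitted there)
  std::reverse(ops.begin(), ops.end());
  return List::create(_["ops"] = IntegerVector(ops.begin(), ops.end()),
                      _["read_start"] = i, _["read_end"] = best_i,
                      _["win_start"] = j, _["win_end"] = best_j,
                      _["n_mismatch"] = n_mismatch, _["n_indel"] = n_indel);
}
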