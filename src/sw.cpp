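#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps, BLAST gap convention:
// a gap of length L costs gap_open + L * gap_extend.
//
// Sequences arrive as 0-based integer indices into the scoring matrix.
// Three-state DP (M = match/mismatch, X = gap in subject consuming query,
// Y = gap in query consuming subject). An optimal positive-scoring local
// alignment always starts and ends in state M, so ends are scanned over M.
//
// Tie handling: alongside each state's score we propagate the origin
// (start cell) of an optimal alignment ending in that state, taking the
// lexicographically smallest (q_start, s_start) whenever predecessor
// choices score equally. Among all end cells attaining the global optimum
// the smallest origin wins, then the smallest (q_end, s_end). Traceback
// then follows predecessors consistent with both score and chosen origin.

static const int NEG = -(1 << 29);

static inline int64_t pack(int i, int j) {
  return (static_cast<int64_t>(i) << 32) | static_cast<uint32_t>(j);
}

// [[Rcpp::export(name = ".sw_align")]]
IntegerVector sw_align(IntegerVector q, IntegerVector s,
                       IntegerMatrix mat, int gap_open, int gap_extend) {
  const int m = q.size(), n = s.size();
  const int W = n + 1;
  const int open_ext = gap_open + gap_extend;

  std::vector<int> M((m + 1) * W, 0), X((m + 1) * W, NEG), Y((m + 1) * W, NEG);
  std::vector<int64_t> oM((m + 1) * W, 0), oX((m + 1) * W, 0), oY((m + 1) * W, 0);

  int best = 0;
  int64_t best_origin = 0;
  int best_i = -1, best_j = -1;

  for (int i = 1; i <= m; ++i) {
    const int qi = q[i - 1];
    for (int j = 1; j <= n; ++j) {
      const int idx = i * W + j, dg = (i - 1) * W + (j - 1),
                up = (i - 1) * W + j, lf = i * W + (j - 1);
      const int sub = mat(qi, s[j - 1]);

      // M: extend the best alignment ending at (i-1, j-1), or start fresh.
      // Predecessors are only taken when strictly positive, so reported
      // alignments never carry zero-scoring prefixes.
      int prev = 0;
      int64_t org = pack(i, j);
      if (M[dg] > 0 && (M[dg] > prev || (M[dg] == prev && oM[dg] < org))) {
        prev = M[dg]; org = oM[dg];
      }
      if (X[dg] > 0 && (X[dg] > prev || (X[dg] == prev && oX[dg] < org))) {
        prev = X[dg]; org = oX[dg];
      }
      if (Y[dg] > 0 && (Y[dg] > prev || (Y[dg] == prev && oY[dg] < org))) {
        prev = Y[dg]; org = oY[dg];
      }
      M[idx] = prev + sub;
      oM[idx] = org;

      // X: query residue i against a gap.
      int vM = M[up] - open_ext, vX = X[up] - gap_extend;
      if (vM > vX || (vM == vX && oM[up] <= oX[up])) { X[idx] = vM; oX[idx] = oM[up]; }
      else { X[idx] = vX; oX[idx] = oX[up]; }

      // Y: subject residue j against a gap.
      vM = M[lf] - open_ext; int vY = Y[lf] - gap_extend;
      if (vM > vY || (vM == vY && oM[lf] <= oY[lf])) { Y[idx] = vM; oY[idx] = oM[lf]; }
      else { Y[idx] = vY; oY[idx] = oY[lf]; }

      if (M[idx] > best ||
          (M[idx] == best && best > 0 &&
           (oM[idx] < best_origin ||
            (oM[idx] == best_origin && pack(i, j) < pack(best_i, best_j))))) {
        best = M[idx];
        best_origin = oM[idx];
        best_i = i; best_j = j;
      }
    }
  }

  if (best <= 0) {
    return IntegerVector::create(_["score"] = 0, _["q_start"] = NA_INTEGER,
                                 _["q_end"] = NA_INTEGER, _["s_start"] = NA_INTEGER,
                                 _["s_end"] = NA_INTEGER, _["n_ident"] = 0,
                                 _["n_cols"] = 0);
  }

  // Traceback from (best_i, best_j) in state M, following the chosen origin.
  int i = best_i, j = best_j;
  int n_ident = 0, n_cols = 0;
  int state = 0;  // 0 = M, 1 = X, 2 = Y
  int q_start = i, s_start = j;

  for (;;) {
    const int idx = i * W + j;
    if (state == 0) {
      ++n_cols;
      if (q[i - 1] == s[j - 1]) ++n_ident;
      const int rest = M[idx] - mat(q[i - 1], s[j - 1]);
      if (rest == 0 && oM[idx] == pack(i, j)) { q_start = i; s_start = j; break; }
      const int dg = (i - 1) * W + (j - 1);
      if (M[dg] == rest && oM[dg] == oM[idx]) state = 0;
      else if (X[dg] == rest && oX[dg] == oM[idx]) state = 1;
      else if (Y[dg] == rest && oY[dg] == oM[idx]) state = 2;
      else if (M[dg] == rest) state = 0;       // origin mismatch fallback
      else if (X[dg] == rest) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      ++n_cols;
      const int up = (i - 1) * W + j;
      if (M[up] - open_ext == X[idx] && oM[up] == oX[idx]) state = 0;
      else if (X[up] - gap_extend == X[idx] && oX[up] == oX[idx]) state = 1;
      else if (M[up] - open_ext == X[idx]) state = 0;
      else state = 1;
      --i;
    } else {
      ++n_cols;
      const int lf = i * W + (j - 1);
      if (M[lf] - open_ext == Y[idx] && oM[lf] == oY[idx]) state = 0;
      else if (Y[lf] - gap_extend == Y[idx] && oY[lf] == oY[idx]) state = 2;
      else if (M[lf] - open_ext == Y[idx]) state = 0;
      else state = 2;
      --j;
    }
  }

  return IntegerVector::create(_["score"] = best, _["q_start"] = q_start,
                               _["q_end"] = best_i, _["s_start"] = s_start,
                               _["s_end"] = best_j, _["n_ident"] = n_ident,
                               _["n_cols"] = n_cols);
}
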