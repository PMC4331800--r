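#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps, returning successive
// locally optimal hits by position masking (Waterman-Eggert style): after
// each traceback the sequence positions it used are excluded and the DP is
// recomputed, so reported hits never share positions. In self mode only the
// strict upper triangle (j > i) is searched: the main diagonal is the
// trivial self-match and the lower triangle mirrors the upper one.
//
// Codes: 1..4 for A,C,G,T; 0 for ambiguous bases (always scored as
// mismatch). A gap of length g costs gap_open + g * gap_extend (both
// parameters are <= 0).

static const int NEG = -1000000000;

// [[Rcpp::export]]
DataFrame cpp_local_align(IntegerVector a, IntegerVector b,
                          int match, int mismatch,
                          int gap_open, int gap_extend,
                          int min_len, bool self, int max_hits) {
  int n = a.size(), m = b.size();
  std::vector<int> out_sa, out_ea, out_sb, out_eb, out_len, out_id, out_sc;
  if (n == 0 || m == 0) {
    return DataFrame::create(
      _["start_a"] = out_sa, _["end_a"] = out_ea,
      _["start_b"] = out_sb, _["end_b"] = out_eb,
      _["length"] = out_len, _["identities"] = out_id,
      _["score"] = out_sc);
  }
  std::vector<char> used_a(n + 1, 0), used_b(m + 1, 0);
  // (n+1) x (m+1) matrices, row-major
  size_t sz = (size_t)(n + 1) * (m + 1);
  std::vector<int> H(sz), E(sz), F(sz);
  auto idx = [m](int i, int j) { return (size_t)i * (m + 1) + j; };

  int iter_cap = max_hits * 8 + 8;
  for (int iter = 0; iter < iter_cap && (int)out_sa.size() < max_hits; ++iter) {
    // forward pass
    for (int j = 0; j <= m; ++j) { H[idx(0, j)] = 0; E[idx(0, j)] = NEG; F[idx(0, j)] = NEG; }
    int best = 0, bi = 0, bj = 0;
    for (int i = 1; i <= n; ++i) {
      H[idx(i, 0)] = 0; E[idx(i, 0)] = NEG; F[idx(i, 0)] = NEG;
      for (int j = 1; j <= m; ++j) {
        bool blocked = used_a[i] || used_b[j] || (self && j <= i);
        if (blocked) {
          H[idx(i, j)] = 0; E[idx(i, j)] = NEG; F[idx(i, j)] = NEG;
          continue;
        }
        int e = std::max(H[idx(i, j - 1)] + gap_open + gap_extend,
                         E[idx(i, j - 1)] + gap_extend);
        int f = std::max(H[idx(i - 1, j)] + gap_open + gap_extend,
                         F[idx(i - 1, j)] + gap_extend);
        int s = (a[i - 1] != 0 && a[i - 1] == b[j - 1]) ? match : mismatch;
        int h = H[idx(i - 1, j - 1)] + s;
        if (e > h) h = e;
        if (f > h) h = f;
        if (h < 0) h = 0;
        E[idx(i, j)] = e; F[idx(i, j)] = f; H[idx(i, j)] = h;
        if (h > best) { best = h; bi = i; bj = j; }
      }
    }
    if (best <= 0) break;
    // traceback from (bi, bj), state 0 = H(diag), 1 = E, 2 = F
    int i = bi, j = bj, state = 0;
    int cols = 0, ident = 0;
    int ea = bi, eb = bj;
    std::vector<int> path_a, path_b;
    while (true) {
      if (state == 0) {
        int h = H[idx(i, j)];
        if (h == 0) break;
        if (h == E[idx(i, j)]) { state = 1; continue; }
        if (h == F[idx(i, j)]) { state = 2; continue; }
        // diagonal
        cols++;
        path_a.push_back(i); path_b.push_back(j);
        if (a[i - 1] != 0 && a[i - 1] == b[j - 1]) ident++;
        i--; j--;
      } else if (state == 1) {
        cols++;
        path_b.push_back(j);
        int e = E[idx(i, j)];
        j--;
        if (e == H[idx(i, j)] + gap_open + gap_extend) state = 0;
        // else stay in E
      } else {
        cols++;
        path_a.push_back(i);
        int f = F[idx(i, j)];
        i--;
        if (f == H[idx(i, j)] + gap_open + gap_extend) state = 0;
      }
    }
    int sa = i + 1, sb = j + 1;
    // mask consumed positions so the next round finds a disjoint hit
    // In self mode only the a-side is consumed: each repeat instance is
    // reported once as an a-side (no mirrored duplicates, thanks to the
    // upper-triangle restriction) but stays reusable as a b-side, so k
    // copies surface as a connected chain of pairwise hits even when the
    // greedy score order would otherwise orphan an instance.
    for (int p : path_a) used_a[p] = 1;
    if (!self) {
      for (int p : path_b) used_b[p] = 1;
    }
    if (cols >= min_len) {
      out_sa.push_back(sa); out_ea.push_back(ea);
      out_sb.push_back(sb); out_eb.push_back(eb);
      out_len.push_back(cols); out_id.push_back(ident);
      out_sc.push_back(best);
    }
  }
  return DataFrame::create(
    _["start_a"] = out_sa, _["end_a"] = out_ea,
    _["start_b"] = out_sb, _["end_b"] = out_eb,
    _["length"] = out_len, _["identities"] = out_id,
    _["score"] = out_sc);
}
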